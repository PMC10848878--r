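#' Classify SV overlap with gene models
#'
#' Each variant is assigned to exactly one category, by priority:
#'
#' 1. `ENCLOSING` — the variant interval completely contains at least one
#'    gene span (inclusive at both ends);
#' 2. `PARTIAL_CDS` — it overlaps at least one coding base;
#' 3. `NONCODING` — it overlaps a gene but no CDS (introns, UTRs);
#' 4. `INTERGENIC` — it overlaps no gene.
#'
#' For load analyses, `ENCLOSING` and `PARTIAL_CDS` variants are treated
#' as putatively deleterious (an SV hitting coding sequence is very likely
#' to disrupt the reading frame or remove the product), while variants
#' confined to introns serve as the putatively neutral comparison class.
#'
#' @param x An [SVCohort-class].
#' @param geneModels A [GeneModelSet-class].
#' @return A `data.frame` with `variant_id`, `category` (factor with the
#'   four levels above) and `gene_ids` (comma-separated ids of the genes
#'   motivating the assigned category; `""` for intergenic variants).
#' @export
classifyGeneOverlap <- function(x, geneModels) {
  v <- SummarizedExperiment::rowRanges(x)
  genes <- geneSpans(geneModels)
  cds <- unlist(cdsIntervals(geneModels))
  cds_gene <- rep(names(cdsIntervals(geneModels)),
                  S4Vectors::elementNROWS(cdsIntervals(geneModels)))

  encl <- GenomicRanges::findOverlaps(genes, v, type = "within")
  part <- GenomicRanges::findOverlaps(v, cds)
  anyg <- GenomicRanges::findOverlaps(v, genes)

  # assign lowest-priority first so higher priorities overwrite
  lvls <- c("ENCLOSING", "PARTIAL_CDS", "NONCODING", "INTERGENIC")
  cat <- rep("INTERGENIC", length(v))
  cat[unique(S4Vectors::queryHits(anyg))] <- "NONCODING"
  cat[unique(S4Vectors::queryHits(part))] <- "PARTIAL_CDS"
  cat[unique(S4Vectors::subjectHits(encl))] <- "ENCLOSING"

  lev <- seq_along(v)
  encl_g <- split(names(genes)[S4Vectors::queryHits(encl)],
                  factor(S4Vectors::subjectHits(encl), levels = lev))
  part_g <- split(cds_gene[S4Vectors::subjectHits(part)],
                  factor(S4Vectors::queryHits(part), levels = lev))
  anyg_g <- split(names(genes)[S4Vectors::subjectHits(anyg)],
                  factor(S4Vectors::queryHits(anyg), levels = lev))
  ids <- vapply(lev, function(i) {
    g <- switch(cat[i], ENCLOSING = encl_g[[i]], PARTIAL_CDS = part_g[[i]],
                NONCODING = anyg_g[[i]], INTERGENIC = character(0))
    paste(sort(unique(g)), collapse = ",")
  }, character(1))
  data.frame(variant_id = variantIds(x),
             category = factor(cat, levels = lvls),
             gene_ids = ids, stringsAsFactors = FALSE)
}

#' Per-base repeat composition of SV loci
#'
#' Attributes every base of each variant to at most one repeat class.
#' Where repeat annotations overlap, the feature with the smaller start
#' wins (ties broken by lexicographic class name), a deterministic rule
#' that guarantees each base is counted exactly once.  Unattributed bases
#' are reported as `unannotated`; per-variant rows always sum to the
#' variant length.
#'
#' @param x An [SVCohort-class].
#' @param repeats A `GRanges` with a `repeat_class` metadata column (see
#'   [readRepeats()]).
#' @return An integer matrix, loci x (repeat classes + `unannotated`),
#'   with variant ids as rownames.
#' @export
repeatComposition <- function(x, repeats) {
  v <- SummarizedExperiment::rowRanges(x)
  classes <- sort(unique(S4Vectors::mcols(repeats)$repeat_class))
  out <- matrix(0L, length(v), length(classes) + 1L,
                dimnames = list(variantIds(x), c(classes, "unannotated")))
  hits <- GenomicRanges::findOverlaps(v, repeats)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  feats_by_v <- split(sh, factor(qh, levels = seq_along(v)))
  widths <- GenomicRanges::width(v)
  vstart <- GenomicRanges::start(v); vend <- GenomicRanges::end(v)
  rstart <- GenomicRanges::start(repeats)
  rend <- GenomicRanges::end(repeats)
  rcls <- S4Vectors::mcols(repeats)$repeat_class
  out[, "unannotated"] <- widths
  for (i in which(lengths(feats_by_v) > 0)) {
    feats <- feats_by_v[[i]]
    if (length(feats) == 1L) {       # common case: plain clipped overlap
      n <- min(rend[feats], vend[i]) - max(rstart[feats], vstart[i]) + 1L
      out[i, rcls[feats]] <- n
      out[i, "unannotated"] <- widths[i] - n
      next
    }
    fr <- feats[order(rstart[feats], rcls[feats])]
    covered <- IRanges::IRanges()
    vr <- IRanges::IRanges(vstart[i], vend[i])
    for (j in fr) {
      seg <- IRanges::intersect(IRanges::IRanges(rstart[j], rend[j]), vr)
      new <- IRanges::setdiff(seg, covered)
      if (length(new)) {
        out[i, rcls[j]] <- out[i, rcls[j]] + sum(IRanges::width(new))
        covered <- IRanges::union(covered, seg)
      }
    }
    out[i, "unannotated"] <-
      widths[i] - sum(out[i, colnames(out) != "unannotated"])
  }
  out
}

#' Length spectrum of SV loci
#'
#' Histogram of SV lengths per type, in half-open bins
#' `[k * binWidth, (k + 1) * binWidth)`.
#'
#' @param x An [SVCohort-class].
#' @param binWidth Bin width in bp (> 0; default 10).
#' @return A `data.frame` with `svtype`, `bin_lo`, `bin_hi` (half-open)
#'   and `count`; empty bins are omitted.
#' @export
lengthSpectrum <- function(x, binWidth = 10) {
  stopifnot(binWidth > 0)
  len <- svLen(x)
  bin <- floor(len / binWidth)
  df <- as.data.frame(table(svtype = svType(x), bin = bin),
                      stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  bin <- as.numeric(df$bin)
  out <- data.frame(svtype = df$svtype, bin_lo = bin * binWidth,
                    bin_hi = (bin + 1) * binWidth, count = df$Freq)
  out[order(out$svtype, out$bin_lo), ]
}

#' Repeat composition of a length-spectrum peak
#'
#' Restricts the cohort to one SV type and a closed length window (such as
#' the 180–200 bp deletion peak produced by SINE presence/absence
#' polymorphisms) and aggregates the per-base repeat composition over the
#' selected loci.
#'
#' @param x An [SVCohort-class].
#' @param repeats Repeat `GRanges` (see [repeatComposition()]).
#' @param window Closed length window `c(lo, hi)` in bp.
#' @param svtype SV type to restrict to (default `"DEL"`).
#' @return A list with `bases` (named base counts per class, plus
#'   `unannotated`), `proportions` (the same normalized to 1; all zero when
#'   no locus falls in the window) and `n_loci`.
#' @export
peakComposition <- function(x, repeats, window, svtype = "DEL") {
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- svType(x) == svtype & svLen(x) >= window[1] & svLen(x) <= window[2]
  classes <- c(sort(unique(S4Vectors::mcols(repeats)$repeat_class)),
               "unannotated")
  if (!any(sel)) {
    z <- stats::setNames(rep(0, length(classes)), classes)
    return(list(bases = z, proportions = z, n_loci = 0L))
  }
  comp <- repeatComposition(x[sel, ], repeats)
  bases <- colSums(comp)
  list(bases = bases, proportions = bases / sum(bases), n_loci = sum(sel))
}
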