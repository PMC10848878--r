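#' GeneModelSet: gene spans with CDS intervals
#'
#' Gene annotation container used for SV overlap classification.  `genes`
#' holds one range per gene (1-based inclusive, names = gene ids); `cds` is
#' a parallel [GenomicRanges::GRangesList] of coding-sequence intervals,
#' merged to disjoint ranges per gene and guaranteed to lie within the gene
#' span.
#'
#' @name GeneModelSet-class
#' @exportClass GeneModelSet
setClass("GeneModelSet",
         representation(genes = "GRanges", cds = "GRangesList"))

setValidity("GeneModelSet", function(object) {
  msg <- NULL
  if (length(object@genes) != length(object@cds))
    msg <- c(msg, "genes and cds must be parallel")
  if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
    msg <- c(msg, "gene ids must be present and unique")
  flat <- unlist(object@cds, use.names = FALSE)
  idx <- rep(seq_along(object@cds), S4Vectors::elementNROWS(object@cds))
  if (length(flat)) {
    g <- object@genes[idx]
    within <- all(
      as.character(GenomicRanges::seqnames(flat)) ==
        as.character(GenomicRanges::seqnames(g)) &
      GenomicRanges::start(flat) >= GenomicRanges::start(g) &
      GenomicRanges::end(flat) <= GenomicRanges::end(g))
    if (!within) msg <- c(msg, "cds intervals must lie within gene spans")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet Constructor; CDS intervals are merged
#'   (`reduce`d) to disjoint ranges per gene.
#' @param genes `GRanges` of gene spans, with names or a `gene_id` metadata
#'   column.
#' @param cds `GRangesList` (or list of `GRanges`) of CDS intervals, one
#'   element per gene.
#' @export
GeneModelSet <- function(genes, cds) {
  if (is.null(names(genes)) && !is.null(S4Vectors::mcols(genes)$gene_id))
    names(genes) <- S4Vectors::mcols(genes)$gene_id
  if (!methods::is(cds, "GRangesList")) {
    # flatten once instead of coercing element-wise (fast for many genes)
    nper <- vapply(cds, length, integer(1))
    flat <- if (any(nper > 0)) do.call(c, unname(cds[nper > 0]))
      else GenomicRanges::GRanges()
    idx <- factor(rep(seq_along(cds), nper), levels = seq_along(cds))
    cds <- S4Vectors::split(flat, idx)
  }
  cds <- GenomicRanges::reduce(cds)
  names(cds) <- names(genes)
  methods::new("GeneModelSet", genes = genes, cds = cds)
}

#' @describeIn GeneModelSet Gene spans (`GRanges`, names = gene ids).
#' @param x A `GeneModelSet`.
#' @export
geneSpans <- function(x) x@genes

#' @describeIn GeneModelSet CDS intervals per gene (`GRangesList`).
#' @export
cdsIntervals <- function(x) x@cds

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@genes), "genes,",
      sum(S4Vectors::elementNROWS(object@cds)), "CDS intervals\n")
})

#' Read gene models from GFF3 or BED12
#'
#' GFF3 input (1-based inclusive, imported with [rtracklayer::import]) uses
#' `type == "gene"` rows for spans and `type == "CDS"` rows, attached to a
#' gene via their `Parent` (or `gene_id`) attribute, for coding intervals.
#' BED12 input (0-based half-open, converted exactly at the boundary by
#' rtracklayer) uses the line span as the gene, and the intersection of the
#' exon blocks with the thick region as CDS.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` (BED12) file.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- S4Vectors::mcols(gr)$name
    if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
    blocks <- S4Vectors::mcols(gr)$blocks
    cds <- lapply(seq_along(gr), function(i) {
      thick <- S4Vectors::mcols(gr)$thick[i]
      if (is.null(blocks) || is.na(IRanges::start(thick)))
        return(GenomicRanges::GRanges())
      ex <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i],
                                   IRanges::shift(blocks[[i]],
                                                  GenomicRanges::start(gr)[i] - 1L))
      thick_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], thick)
      GenomicRanges::intersect(ex, thick_gr)
    })
    genes <- GenomicRanges::granges(gr)
    S4Vectors::mcols(genes) <- NULL
    names(genes) <- ids
    return(GeneModelSet(genes, cds))
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  mc <- S4Vectors::mcols(gr)
  genes <- gr[mc$type == "gene"]
  ids <- S4Vectors::mcols(genes)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) stop("GFF3 gene rows need an ID attribute")
  cds_all <- gr[mc$type == "CDS"]
  parent <- S4Vectors::mcols(cds_all)$Parent
  parent <- if (is.null(parent)) S4Vectors::mcols(cds_all)$gene_id else
    vapply(as.list(parent),
           function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  keep <- !is.na(parent) & parent %in% ids
  cds <- S4Vectors::split(GenomicRanges::granges(cds_all[keep]),
                          factor(parent[keep], levels = ids))
  genes <- GenomicRanges::granges(genes)
  names(genes) <- ids
  GeneModelSet(genes, cds)
}

#' Read repeat annotation from BED
#'
#' BED4/BED6 with the repeat class (e.g. `SINE`, `LINE`, `LTR`) in the name
#' column.  Intervals are converted from BED's 0-based half-open convention
#' to 1-based inclusive on import.
#'
#' @param path Path to a BED file.
#' @return A `GRanges` with a `repeat_class` metadata column.
#' @export
readRepeats <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  cls <- S4Vectors::mcols(gr)$name
  if (is.null(cls)) stop("repeat BED needs a name column with repeat classes")
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$repeat_class <- cls
  out
}

#' Write gene models / repeats (simulator output helpers)
#'
#' `writeGeneModelsGff3` emits `gene` and `CDS` rows (CDS `Parent` = gene
#' id); `writeRepeatsBed` emits BED4 with the class name.  Both are exact
#' inverses of the corresponding readers.
#'
#' @param x A [GeneModelSet-class] or repeat `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsGff3 <- function(x, path) {
  g <- geneSpans(x)
  lines <- c("##gff-version 3",
    paste(as.character(GenomicRanges::seqnames(g)), "svload", "gene",
          GenomicRanges::start(g), GenomicRanges::end(g), ".",
          ifelse(as.character(GenomicRanges::strand(g)) == "-", "-", "+"),
          ".", paste0("ID=", names(g)), sep = "\t"))
  for (i in seq_along(g)) {
    cds <- cdsIntervals(x)[[i]]
    if (!length(cds)) next
    lines <- c(lines,
      paste(as.character(GenomicRanges::seqnames(cds)), "svload", "CDS",
            GenomicRanges::start(cds), GenomicRanges::end(cds), ".",
            ifelse(as.character(GenomicRanges::strand(g)[i]) == "-", "-", "+"),
            "0", paste0("ID=", names(g)[i], ".cds;Parent=", names(g)[i]),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGeneModelsGff3
#' @export
writeRepeatsBed <- function(x, path) {
  writeLines(paste(as.character(GenomicRanges::seqnames(x)),
                   GenomicRanges::start(x) - 1L, GenomicRanges::end(x),
                   S4Vectors::mcols(x)$repeat_class, sep = "\t"), path)
  invisible(path)
}
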