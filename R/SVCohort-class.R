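#' SVCohort: structural-variant genotypes for a sample cohort
#'
#' `SVCohort` extends [SummarizedExperiment::RangedSummarizedExperiment] and
#' holds one structural-variant (SV) locus per row and one individual per
#' column.  The `"GT"` assay stores diploid genotypes as ALT-allele dosage:
#' `0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternative, `NA` = missing.  Row ranges are 1-based inclusive intervals
#' (VCF convention) carrying per-locus metadata:
#'
#' * `svtype`: one of `"DEL"`, `"DUP"`, `"INV"`;
#' * `svlen`: SV length in bp (`end - pos + 1` unless the caller reported
#'   `SVLEN` explicitly);
#' * `dhffc`: depth fold-change of the variant region relative to its flanks
#'   (duphold-style; low values support deletions, high values duplications;
#'   may be `NA` for inversions);
#' * `mshq`: mean genotype-quality ("smoove heterozygosity") score;
#' * `is_autosomal`, `is_biallelic`: logical flags used by the filter
#'   cascade.
#'
#' Column data holds per-sample metadata (`population`, `generation_class`,
#' `coverage`, pedigree links) as available.
#'
#' @seealso [readSVVcf()], [writeSVVcf()], [simulateCohort()],
#'   [filterCascade()]
#' @name SVCohort-class
#' @aliases SVCohort-class
#' @exportClass SVCohort
setClass("SVCohort", contains = "RangedSummarizedExperiment")

SV_TYPES <- c("DEL", "DUP", "INV")

.validSVCohort <- function(object) {
  msg <- NULL
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- SummarizedExperiment::assay(object, "GT")
    if (!all(gt %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  }
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
  needed <- c("svtype", "svlen", "dhffc", "mshq", "is_autosomal",
              "is_biallelic")
  miss <- setdiff(needed, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste("missing rowRanges metadata:",
                        paste(miss, collapse = ", ")))
  if ("svtype" %in% colnames(mc) && !all(mc$svtype %in% SV_TYPES))
    msg <- c(msg, "svtype must be one of DEL, DUP, INV")
  if ("svlen" %in% colnames(mc) && any(mc$svlen < 1, na.rm = TRUE))
    msg <- c(msg, "svlen must be >= 1")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "variant ids (rownames) must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("SVCohort", .validSVCohort)

#' Construct an SVCohort
#'
#' @param ranges A [GenomicRanges::GRanges] of SV loci (1-based inclusive)
#'   with metadata columns `svtype` and optionally `svlen`, `dhffc`, `mshq`,
#'   `is_autosomal`, `is_biallelic`.  Names are used as variant ids; unnamed
#'   loci get ids `sv1, sv2, ...`.
#' @param genotypes Integer matrix, loci x samples, ALT dosage coding
#'   (0/1/2/`NA`).  Column names are sample ids.
#' @param sampleData Optional `data.frame`/`DataFrame` of per-sample
#'   metadata, one row per genotype column.
#' @return An [SVCohort-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1189),
#'                              svtype = "DEL")
#' names(gr) <- "sv1"
#' gt <- matrix(c(0L, 1L), 1, 2, dimnames = list("sv1", c("a", "b")))
#' SVCohort(gr, gt)
#' @export
SVCohort <- function(ranges, genotypes, sampleData = NULL) {
  if (!is.matrix(genotypes))
    genotypes <- matrix(genotypes, nrow = length(ranges))
  storage.mode(genotypes) <- "integer"
  if (is.null(names(ranges)))
    names(ranges) <- paste0("sv", seq_along(ranges))
  mc <- S4Vectors::mcols(ranges)
  if (is.null(mc$svlen)) mc$svlen <- GenomicRanges::width(ranges)
  for (fld in c("dhffc", "mshq"))
    if (is.null(mc[[fld]])) mc[[fld]] <- NA_real_
  if (is.null(mc$is_autosomal)) mc$is_autosomal <- TRUE
  if (is.null(mc$is_biallelic)) mc$is_biallelic <- TRUE
  S4Vectors::mcols(ranges) <- mc
  rownames(genotypes) <- names(ranges)
  if (is.null(sampleData)) {
    if (is.null(colnames(genotypes)))
      colnames(genotypes) <- paste0("s", seq_len(ncol(genotypes)))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(genotypes))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if (is.null(rownames(sampleData)) && !is.null(sampleData$sample_id))
      rownames(sampleData) <- sampleData$sample_id
    if (is.null(colnames(genotypes)))
      colnames(genotypes) <- rownames(sampleData)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = genotypes), rowRanges = ranges, colData = sampleData)
  methods::new("SVCohort", se)
}

#' @describeIn SVCohort Genotype matrix (loci x samples, ALT dosage).
#' @param x An `SVCohort`.
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "GT")

#' @describeIn SVCohort SV type per locus (`DEL`/`DUP`/`INV`).
#' @export
svType <- function(x)
  as.character(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$svtype)

#' @describeIn SVCohort SV length in bp per locus.
#' @export
svLen <- function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$svlen

#' @describeIn SVCohort Depth fold-change (duphold DHFFC) per locus.
#' @export
dhffc <- function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$dhffc

#' @describeIn SVCohort Mean genotype-quality score (MSHQ) per locus.
#' @export
mshq <- function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$mshq

#' @describeIn SVCohort Variant identifiers.
#' @export
variantIds <- function(x) rownames(x)

#' @describeIn SVCohort Sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "SVCohort", function(object) {
  tab <- table(factor(svType(object), levels = SV_TYPES))
  cat("SVCohort with", nrow(object), "SV loci (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      ") x", ncol(object), "samples\n")
  gt <- genotypes(object)
  if (length(gt))
    cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(gt))))
  methods::callNextMethod()
})

# per-type locus counts incl. total, used by filter reports
countByType <- function(x) {
  tab <- table(factor(svType(x), levels = SV_TYPES))
  stats::setNames(c(as.vector(tab), sum(tab)), c(SV_TYPES, "Total"))
}
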