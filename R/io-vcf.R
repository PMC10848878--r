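#' Read a structural-variant VCF into an SVCohort
#'
#' Parses a multi-sample SV VCF (smoove/duphold dialect) via
#' [VariantAnnotation::readVcf] and returns an [SVCohort-class].  Records
#' whose `SVTYPE` is not `DEL`, `DUP` or `INV` (e.g. `BND`) are skipped with
#' a message.  Coordinates are kept 1-based inclusive; the locus end is
#' taken from `INFO/END` when present, otherwise computed from `SVLEN`.
#' SV length prefers `abs(SVLEN)` when present, else `END - POS + 1`.
#'
#' The quality annotations `DHFFC` (duphold depth fold-change) and `MSHQ`
#' (mean genotype-quality score) may live either in `INFO` (one value per
#' record) or in `FORMAT` (per sample); per-sample values are reduced to a
#' per-record mean, which is the scale on which the quality filters operate.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param qualitySource `"auto"` (default: prefer `INFO`, fall back to
#'   `FORMAT`), `"info"` or `"format"`.
#' @param autosomes Optional character vector naming the autosomal
#'   chromosomes.  By default every chromosome not matching common sex /
#'   mitochondrial names (`X`, `Y`, `Z`, `W`, `M`, `MT`, with or without a
#'   `chr` prefix) is treated as autosomal.
#' @return An [SVCohort-class]; sample order follows the VCF header.
#' @examples
#' sim <- simulateCohort(simulationConfig(n_loci_neutral = 20,
#'                                        n_loci_deleterious = 10, seed = 1))
#' f <- tempfile(fileext = ".vcf")
#' writeSVVcf(sim$cohort, f)
#' readSVVcf(f)
#' @export
readSVVcf <- function(path, qualitySource = c("auto", "info", "format"),
                      autosomes = NULL) {
  qualitySource <- match.arg(qualitySource)
  vcf <- VariantAnnotation::readVcf(path)
  inf <- VariantAnnotation::info(vcf)
  if (!"SVTYPE" %in% colnames(inf))
    stop("VCF lacks the INFO/SVTYPE key: ", path)
  svtype <- as.character(inf$SVTYPE)
  keep <- svtype %in% SV_TYPES
  if (any(!keep))
    message(sum(!keep), " record(s) with SVTYPE outside DEL/DUP/INV skipped")
  if (!any(keep)) stop("no DEL/DUP/INV records in ", path)
  vcf <- vcf[keep]
  inf <- VariantAnnotation::info(vcf)
  svtype <- as.character(inf$SVTYPE)

  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  endv <- .unlistInfo(inf$END, length(vcf))
  svlen <- .unlistInfo(inf$SVLEN, length(vcf))
  svlen <- ifelse(is.na(svlen), NA_real_, abs(svlen))
  if (all(is.na(endv)) && all(is.na(svlen)))
    stop("VCF provides neither INFO/END nor INFO/SVLEN")
  endv <- ifelse(is.na(endv), pos + svlen - 1, endv)
  svlen <- ifelse(is.na(svlen), endv - pos + 1, svlen)

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF lacks per-sample GT calls")
  dos <- .gtToDosage(gt, rownames(vcf))

  nalt <- lengths(VariantAnnotation::alt(vcf))
  multi <- nalt > 1 | apply(dos$extra_allele, 1, any)

  qual <- .readQuality(vcf, qualitySource)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  if (is.null(autosomes)) {
    sex_like <- grepl("^(chr)?(X|Y|Z|W|M|MT)$", chrom, ignore.case = TRUE)
    is_auto <- !sex_like
  } else is_auto <- chrom %in% autosomes

  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(pos, pmax(pos, endv)),
          svtype = svtype, svlen = as.numeric(svlen),
          dhffc = qual$dhffc, mshq = qual$mshq,
          is_autosomal = is_auto, is_biallelic = !multi)
  names(gr) <- rownames(vcf)
  SVCohort(gr, dos$dosage)
}

.unlistInfo <- function(x, n) {
  if (is.null(x)) return(rep(NA_real_, n))
  if (methods::is(x, "List") || is.list(x))
    x <- vapply(x, function(v) if (length(v)) as.numeric(v[1]) else NA_real_,
                numeric(1))
  as.numeric(x)
}

.gtToDosage <- function(gt, ids) {
  g <- gsub("\\|", "/", gt)
  g[g == "."] <- "./."
  toks <- strsplit(as.vector(g), "/", fixed = TRUE)
  npl <- lengths(toks)
  if (any(npl != 2)) {
    bad <- which(matrix(npl != 2, nrow(gt)), arr.ind = TRUE)[1, 1]
    stop("unsupported genotype ploidy at record '", ids[bad], "'")
  }
  a1 <- vapply(toks, `[`, character(1), 1)
  a2 <- vapply(toks, `[`, character(1), 2)
  suppressWarnings({
    n1 <- as.integer(a1); n2 <- as.integer(a2)
  })
  if (any(is.na(n1) != (a1 == ".")))
    stop("malformed GT allele in VCF")
  extra <- matrix(pmax(n1, n2, na.rm = FALSE) > 1, nrow(gt))
  extra[is.na(extra)] <- FALSE
  dos <- n1 + n2
  dos[!is.na(dos) & dos > 2] <- NA_integer_   # non-biallelic call
  list(dosage = matrix(as.integer(dos), nrow(gt), dimnames = dimnames(gt)),
       extra_allele = extra)
}

.readQuality <- function(vcf, source) {
  inf <- VariantAnnotation::info(vcf)
  gen <- VariantAnnotation::geno(vcf)
  n <- length(vcf)
  pick <- function(field) {
    in_info <- field %in% colnames(inf)
    in_geno <- field %in% names(gen)
    use <- switch(source,
      info = if (in_info) "info" else "none",
      format = if (in_geno) "geno" else "none",
      auto = if (in_info) "info" else if (in_geno) "geno" else "none")
    switch(use,
      info = .unlistInfo(inf[[field]], n),
      geno = rowMeans(matrix(as.numeric(gen[[field]]), n), na.rm = TRUE),
      none = rep(NA_real_, n))
  }
  list(dhffc = pick("DHFFC"), mshq = pick("MSHQ"))
}

#' Write an SVCohort as a VCF 4.2 file
#'
#' Emits one record per locus with symbolic ALT alleles (`<DEL>`, `<DUP>`,
#' `<INV>`), `INFO` keys `SVTYPE`, `END`, `SVLEN`, `DHFFC`, `MSHQ` (quality
#' keys omitted where `NA`) and per-sample `GT`.  Reading the file back
#' with [readSVVcf()] reproduces genotypes, coordinates, SV types and
#' quality values.
#'
#' @param x An [SVCohort-class].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
writeSVVcf <- function(x, path) {
  gr <- SummarizedExperiment::rowRanges(x)
  num <- function(v) sprintf("%.10g", v)
  info <- paste0("SVTYPE=", svType(x),
                 ";END=", GenomicRanges::end(gr),
                 ";SVLEN=", num(svLen(x)),
                 ifelse(is.na(dhffc(x)), "", paste0(";DHFFC=", num(dhffc(x)))),
                 ifelse(is.na(mshq(x)), "", paste0(";MSHQ=", num(mshq(x)))))
  gt <- genotypes(x)
  gtc <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow(gt))
  gtc[is.na(gt)] <- "./."
  chrom <- as.character(GenomicRanges::seqnames(gr))
  ctg_len <- tapply(GenomicRanges::end(gr), chrom, max)
  hdr <- c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(ctg_len), ",length=",
           format(ctg_len + 10000L, scientific = FALSE, trim = TRUE), ">"),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Float,Description=\"Length of the variant in bp\">",
    "##INFO=<ID=DHFFC,Number=1,Type=Float,Description=\"Duphold depth fold-change relative to flanks\">",
    "##INFO=<ID=MSHQ,Number=1,Type=Float,Description=\"Mean genotype heterozygosity quality score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(x)), collapse = "\t"))
  body <- paste(chrom, GenomicRanges::start(gr), variantIds(x), "N",
                paste0("<", svType(x), ">"), ".", "PASS", info, "GT",
                apply(gtc, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
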