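#' Derived allele frequency per locus
#'
#' For polarized loci, the derived allele is ALT when the ancestral state
#' is REF and vice versa.  The frequency denominator is twice the number
#' of non-missing individuals in the chosen subset, so loci with different
#' missingness remain comparable.
#'
#' @param x An [SVCohort-class].
#' @param polarized Output of [polarize()] for the same loci.
#' @param samples Sample ids to use (default: all).
#' @param strict When `TRUE` (default) an unpolarized locus or a locus
#'   with zero non-missing genotypes is an error; when `FALSE` such loci
#'   get `NA`.
#' @return Named numeric vector of derived-allele frequencies in `[0, 1]`.
#' @examples
#' # 4 derived alleles among 40 diploid individuals -> 0.05
#' @export
derivedAlleleFrequency <- function(x, polarized, samples = sampleIds(x),
                                   strict = TRUE) {
  gt <- genotypes(x)[, samples, drop = FALSE]
  anc <- polarized$ancestral[match(variantIds(x), polarized$variant_id)]
  n_called <- rowSums(!is.na(gt))
  if (strict) {
    if (any(anc == "UNPOLARIZED"))
      stop("unpolarized locus: ",
           variantIds(x)[which(anc == "UNPOLARIZED")[1]])
    if (any(n_called == 0))
      stop("locus with no non-missing genotypes: ",
           variantIds(x)[which(n_called == 0)[1]])
  }
  alt_freq <- rowSums(gt, na.rm = TRUE) / (2 * n_called)
  freq <- ifelse(anc == "REF", alt_freq, 1 - alt_freq)
  freq[anc == "UNPOLARIZED" | n_called == 0] <- NA_real_
  stats::setNames(freq, variantIds(x))
}

#' Site frequency spectrum from derived allele frequencies
#'
#' Bins polymorphic derived-allele frequencies into intervals of width
#' 0.05: `[0, 0.05), [0.05, 0.10), ..., [0.95, 1.0]` (last bin closed).
#' Monomorphic loci (frequency 0 or 1 in the subset) are excluded, as are
#' `NA` frequencies.
#'
#' @param freqs Numeric vector of derived allele frequencies.
#' @param classLabel `"DELETERIOUS"` or `"NEUTRAL"` (or any label).
#' @param nSamples Number of individuals behind the frequencies (recorded,
#'   not used in the computation).
#' @param binWidth Bin width on the frequency axis (default 0.05).
#' @return A list of class `SFS` with `bin_edges` (length bins + 1),
#'   `counts`, `n_loci` (= `sum(counts)`), `n_samples`, `class_label`.
#' @export
sfsFromFrequencies <- function(freqs, classLabel = "NEUTRAL",
                               nSamples = NA_integer_, binWidth = 0.05) {
  freqs <- freqs[!is.na(freqs) & freqs > 0 & freqs < 1]
  edges <- seq(0, 1, by = binWidth)
  bin <- pmin(floor(freqs / binWidth) + 1L, length(edges) - 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  if (!length(freqs))
    warning("empty spectrum for class ", classLabel)
  structure(list(bin_edges = edges, counts = counts,
                 n_loci = sum(counts), n_samples = nSamples,
                 class_label = classLabel),
            class = "SFS")
}

#' Unfolded SFS for a variant class
#'
#' Convenience wrapper selecting loci by gene-overlap class and length
#' window, computing derived frequencies on a sample subset, and binning
#' them.  The deleterious class comprises variants enclosing genes or
#' partially overlapping coding sequence; the neutral class comprises
#' variants overlapping only non-coding parts of genes.  Unpolarized loci
#' are dropped.  For rare-variant work this is typically run on the set
#' before the genotype-frequency filter, which would otherwise strip the
#' low-frequency bins.
#'
#' @param x An [SVCohort-class].
#' @param polarized Output of [polarize()].
#' @param overlap Output of [classifyGeneOverlap()].
#' @param samples Sample ids defining the frequency denominator.
#' @param classLabel `"DELETERIOUS"` (ENCLOSING + PARTIAL_CDS) or
#'   `"NEUTRAL"` (NONCODING).
#' @param svtypes Optional SV types to keep (e.g. `"DEL"`).
#' @param lengthWindow Optional closed length window in bp (e.g.
#'   `c(50, 10000)`).
#' @param binWidth Frequency bin width (default 0.05).
#' @return An `SFS` (see [sfsFromFrequencies()]).
#' @export
buildSFS <- function(x, polarized, overlap, samples = sampleIds(x),
                     classLabel = c("DELETERIOUS", "NEUTRAL"),
                     svtypes = NULL, lengthWindow = NULL, binWidth = 0.05) {
  classLabel <- match.arg(classLabel)
  cats <- if (classLabel == "DELETERIOUS")
    c("ENCLOSING", "PARTIAL_CDS") else "NONCODING"
  keep <- overlap$category[match(variantIds(x), overlap$variant_id)] %in% cats
  anc <- polarized$ancestral[match(variantIds(x), polarized$variant_id)]
  keep <- keep & anc != "UNPOLARIZED"
  if (!is.null(svtypes)) keep <- keep & svType(x) %in% svtypes
  if (!is.null(lengthWindow))
    keep <- keep & svLen(x) >= lengthWindow[1] & svLen(x) <= lengthWindow[2]
  sub <- x[keep, ]
  freqs <- if (nrow(sub)) derivedAlleleFrequency(sub, polarized, samples,
                                                 strict = FALSE)
    else numeric(0)
  sfsFromFrequencies(freqs, classLabel, length(samples), binWidth)
}

#' Chi-square goodness-of-fit between two spectra
#'
#' Tests whether the deleterious spectrum follows the bin proportions of
#' the neutral spectrum.  Expected counts are the neutral proportions
#' scaled to the deleterious total.  Bins are pooled from the right
#' (rightmost bin merged into its neighbour) until every expected count is
#' at least 5, standard Pearson practice; the statistic is
#' `sum((obs - exp)^2 / exp)` on `pooled bins - 1` degrees of freedom with
#' an upper-tail p-value.
#'
#' @param sfsDeleterious,sfsNeutral `SFS` objects on identical bins (see
#'   [sfsFromFrequencies()]), or plain count vectors of equal length.
#' @param minExpected Pooling threshold (default 5).
#' @return A list with `statistic`, `df`, `p.value`, and the pooled
#'   `observed` / `expected` counts.
#' @export
sfsGofTest <- function(sfsDeleterious, sfsNeutral, minExpected = 5) {
  obs <- if (inherits(sfsDeleterious, "SFS")) sfsDeleterious$counts
    else as.numeric(sfsDeleterious)
  neu <- if (inherits(sfsNeutral, "SFS")) sfsNeutral$counts
    else as.numeric(sfsNeutral)
  if (length(obs) != length(neu))
    stop("spectra must share the same bins")
  if (sum(neu) == 0) stop("neutral spectrum is empty")
  prop <- neu / sum(neu)
  exp_ <- prop * sum(obs)
  while (length(exp_) > 1 && any(exp_ < minExpected)) {
    k <- length(exp_)
    exp_ <- c(exp_[seq_len(k - 2)], exp_[k - 1] + exp_[k])
    obs <- c(obs[seq_len(k - 2)], obs[k - 1] + obs[k])
  }
  if (length(exp_) < 2 || any(exp_ < minExpected))
    stop("degenerate spectrum: fewer than 2 bins after pooling")
  stat <- sum((obs - exp_)^2 / exp_)
  df <- length(obs) - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = exp_)
}

#' Per-individual masked and realized genetic load
#'
#' Over the putatively deleterious loci at which the reference carries the
#' ancestral allele (so hom-ALT means homozygous derived), computes for
#' each individual the fraction of called loci that are heterozygous
#' (masked load: deleterious alleles hidden from selection if recessive)
#' and homozygous derived (realized load).  Missing genotypes are excluded
#' from the denominator.
#'
#' @param x An [SVCohort-class].
#' @param polarized Output of [polarize()].
#' @param overlap Output of [classifyGeneOverlap()].
#' @param samples Sample ids (default: all).
#' @param categories Gene-overlap categories defining the locus class
#'   (default `ENCLOSING` + `PARTIAL_CDS`, the deleterious class; use
#'   `"NONCODING"` for the neutral comparison).
#' @return A `data.frame` with one row per sample: `sample_id`,
#'   `n_loci_called`, `n_het`, `n_hom_derived`, `n_hom_ancestral`,
#'   `masked_load`, `realized_load` (loads `NA` when no locus was called).
#'   `n_het + n_hom_derived + n_hom_ancestral = n_loci_called` always.
#' @export
individualLoad <- function(x, polarized, overlap, samples = sampleIds(x),
                           categories = c("ENCLOSING", "PARTIAL_CDS")) {
  ref_anc <- referenceAncestralSubset(polarized)
  cat_ok <- overlap$variant_id[overlap$category %in% categories]
  loci <- intersect(intersect(variantIds(x), ref_anc), cat_ok)
  gt <- genotypes(x)[loci, samples, drop = FALSE]
  n_called <- colSums(!is.na(gt))
  n_het <- colSums(gt == 1L, na.rm = TRUE)
  n_hom_d <- colSums(gt == 2L, na.rm = TRUE)
  n_hom_a <- colSums(gt == 0L, na.rm = TRUE)
  data.frame(sample_id = samples,
             n_loci_called = n_called, n_het = n_het,
             n_hom_derived = n_hom_d, n_hom_ancestral = n_hom_a,
             masked_load = ifelse(n_called > 0, n_het / n_called, NA_real_),
             realized_load = ifelse(n_called > 0, n_hom_d / n_called,
                                    NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

GENERATION_CLASSES <- c(paste0("F", 1:6), paste0("L", 1:3))

#' Group-wise load summaries across generation classes
#'
#' Joins per-individual load summaries with sample metadata and summarizes
#' masked and realized load by group: the generation class (F1..F6 for
#' founder descendants, L1..L3 for immigrant descendants) when set,
#' otherwise the population label.  Groups are ordered F1..F6, L1..L3,
#' then remaining labels alphabetically.
#'
#' @param loads Output of [individualLoad()].
#' @param sampleInfo Sample metadata `data.frame` with `sample_id`,
#'   `population` and optional `generation_class`.
#' @return A `data.frame` with `group`, `n`, `mean_masked`, `sd_masked`,
#'   `mean_realized`, `sd_realized`.  Empty groups get `n = 0` and `NA`
#'   summaries.
#' @export
loadByGroup <- function(loads, sampleInfo) {
  m <- match(loads$sample_id, sampleInfo$sample_id)
  if (anyNA(m)) stop("samples without metadata: ",
                     paste(loads$sample_id[is.na(m)], collapse = ", "))
  gc <- sampleInfo$generation_class[m]
  grp <- ifelse(is.na(gc) | gc == "", sampleInfo$population[m], gc)
  lv <- c(GENERATION_CLASSES[GENERATION_CLASSES %in% grp],
          sort(setdiff(unique(grp), GENERATION_CLASSES)))
  grp <- factor(grp, levels = lv)
  agg <- function(v, f) tapply(v, grp, f, default = NA_real_)
  out <- data.frame(group = levels(grp),
                    n = as.integer(table(grp)),
                    mean_masked = as.numeric(agg(loads$masked_load,
                                                 function(z) mean(z, na.rm = TRUE))),
                    sd_masked = as.numeric(agg(loads$masked_load,
                                               function(z) stats::sd(z, na.rm = TRUE))),
                    mean_realized = as.numeric(agg(loads$realized_load,
                                                   function(z) mean(z, na.rm = TRUE))),
                    sd_realized = as.numeric(agg(loads$realized_load,
                                                 function(z) stats::sd(z, na.rm = TRUE))),
                    row.names = NULL)
  out
}

#' Two-sample Wilcoxon rank-sum comparison of load values
#'
#' Unpaired two-sided rank-sum test.  With no ties the exact null
#' distribution of the Mann-Whitney statistic is used; with ties the test
#' enumerates all assignments when the total sample size is at most
#' `enumLimit`, and otherwise uses the normal approximation with tie
#' correction.  When every value is tied across both groups the p-value
#' is 1.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param enumLimit Largest total sample size for full enumeration in the
#'   tied case (default 20).
#' @return A list with `statistic` (rank sum of `a`), `p.value` and
#'   `method`.
#' @export
compareGroups <- function(a, b, enumLimit = 20) {
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties) {
    u <- w - n1 * (n1 + 1) / 2
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (Mann-Whitney distribution)"
  } else if (n <= enumLimit) {
    combs <- utils::combn(n, n1)
    wall <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
    method <- "exact (enumeration, midranks)"
  } else {
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p.value = p, method = method)
}

#' Fixation and genetic-rescue accounting
#'
#' Counts, among polarized loci, those drifted to fixation for the derived
#' allele in a pre-immigration subset and how many of them regained the
#' ancestral allele after immigration.
#'
#' * `n_fixed_pre`: loci where every non-missing genotype in `preSamples`
#'   is homozygous derived and at least `minCalled` individuals are
#'   called (guards against spurious fixation from missingness);
#' * `n_regained`: of those, loci where at least one individual in
#'   `postSamples` carries at least one ancestral allele (heterozygous or
#'   homozygous ancestral);
#' * `n_founder_fixed`: loci with no heterozygote and no
#'   homozygous-ancestral genotype in the original population
#'   (`originalSamples`) — the pattern expected when all founders were
#'   homozygous derived;
#' * `n_founder_regained`: of those, regained in `postSamples`.
#'
#' @param x An [SVCohort-class].
#' @param polarized Output of [polarize()]; only polarized loci are
#'   considered.
#' @param preSamples,postSamples Sample-id vectors for the pre- and
#'   post-immigration subsets (both non-empty).
#' @param originalSamples Samples defining the founder-fixation rule
#'   (default `preSamples`).
#' @param minCalled Minimum called individuals for the fixation call
#'   (default 5).
#' @return A list of class `RescueReport` with the four counts and the
#'   corresponding variant-id vectors (`fixed_pre_ids`, `regained_ids`,
#'   `founder_fixed_ids`, `founder_regained_ids`).
#' @export
fixationAndRescue <- function(x, polarized, preSamples, postSamples,
                              originalSamples = preSamples, minCalled = 5) {
  if (!length(preSamples) || !length(postSamples))
    stop("pre- and post-immigration subsets must be non-empty")
  anc <- polarized$ancestral[match(variantIds(x), polarized$variant_id)]
  pol <- which(anc != "UNPOLARIZED")
  gt <- genotypes(x)
  # orient to derived dosage
  der <- gt[pol, , drop = FALSE]
  flip <- anc[pol] == "ALT"
  der[flip, ] <- 2L - der[flip, , drop = FALSE]
  ids <- variantIds(x)[pol]

  pre <- der[, preSamples, drop = FALSE]
  post <- der[, postSamples, drop = FALSE]
  orig <- der[, originalSamples, drop = FALSE]

  n_pre_called <- rowSums(!is.na(pre))
  fixed_pre <- n_pre_called >= minCalled &
    rowSums(pre != 2L, na.rm = TRUE) == 0
  regain <- rowSums(post <= 1L, na.rm = TRUE) > 0
  founder_fixed <- rowSums(!is.na(orig)) > 0 &
    rowSums(orig == 1L, na.rm = TRUE) == 0 &
    rowSums(orig == 0L, na.rm = TRUE) == 0
  structure(list(
    n_fixed_pre = sum(fixed_pre),
    n_regained = sum(fixed_pre & regain),
    n_founder_fixed = sum(founder_fixed),
    n_founder_regained = sum(founder_fixed & regain),
    fixed_pre_ids = ids[fixed_pre],
    regained_ids = ids[fixed_pre & regain],
    founder_fixed_ids = ids[founder_fixed],
    founder_regained_ids = ids[founder_fixed & regain]),
    class = "RescueReport")
}
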