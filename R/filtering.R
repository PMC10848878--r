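#' Quality-filter thresholds
#'
#' Thresholds for the SV quality filter, following the duphold/smoove
#' recommendations: deletions must show a depth drop (`DHFFC < 0.7`),
#' duplications a depth gain (`DHFFC > 1.3`), and all variants a mean
#' genotype-quality score `MSHQ >= 3`.  The strictness is exactly as
#' printed: the DHFFC bounds are strict inequalities, the MSHQ bound is
#' inclusive.  `min_per_genotype` is the genotype-frequency criterion
#' (at least this many individuals of each of the three genotypes).
#'
#' @param dhffc_del_max Deletions pass when `DHFFC < dhffc_del_max`
#'   (default 0.7).
#' @param dhffc_dup_min Duplications pass when `DHFFC > dhffc_dup_min`
#'   (default 1.3).
#' @param mshq_min All variants need `MSHQ >= mshq_min` (default 3).
#' @param min_per_genotype Minimum individuals per genotype class
#'   (default 2).
#' @return A named list of class `FilterThresholds`.
#' @export
filterThresholds <- function(dhffc_del_max = 0.7, dhffc_dup_min = 1.3,
                             mshq_min = 3, min_per_genotype = 2) {
  stopifnot(dhffc_del_max >= 0, dhffc_dup_min >= 0, mshq_min >= 0,
            min_per_genotype >= 0)
  structure(list(dhffc_del_max = dhffc_del_max,
                 dhffc_dup_min = dhffc_dup_min,
                 mshq_min = mshq_min,
                 min_per_genotype = min_per_genotype),
            class = "FilterThresholds")
}

#' Apply the quality filters
#'
#' Removes non-autosomal and non-biallelic loci, then applies the
#' type-specific thresholds: deletions pass iff
#' `DHFFC < dhffc_del_max & MSHQ >= mshq_min`, duplications iff
#' `DHFFC > dhffc_dup_min & MSHQ >= mshq_min`, inversions iff
#' `MSHQ >= mshq_min` (no depth expectation for a copy-neutral variant).
#'
#' @param x An [SVCohort-class].
#' @param thresholds A [filterThresholds()] object.
#' @param onMissingDhffc What to do with a DEL/DUP lacking a DHFFC value:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return A list with `cohort` (passing loci), `fate` (named character
#'   vector over input loci: `"pass"` or `"fail_quality"`), and `report`
#'   (a one-stage count table, see [filterCascade()]).
#' @export
applyQualityFilters <- function(x, thresholds = filterThresholds(),
                                onMissingDhffc = c("drop", "error")) {
  onMissingDhffc <- match.arg(onMissingDhffc)
  type <- svType(x)
  dh <- dhffc(x); ms <- mshq(x)
  needs_dh <- type %in% c("DEL", "DUP")
  if (any(needs_dh & is.na(dh))) {
    n_missing <- sum(needs_dh & is.na(dh))
    if (onMissingDhffc == "error")
      stop(n_missing, " DEL/DUP record(s) lack a DHFFC value")
    warning(n_missing, " DEL/DUP record(s) lack DHFFC and were dropped")
  }
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(x))
  ok_flags <- mc$is_autosomal & mc$is_biallelic
  ok_mshq <- !is.na(ms) & ms >= thresholds$mshq_min
  ok_depth <- rep(TRUE, nrow(x))
  ok_depth[type == "DEL"] <- !is.na(dh[type == "DEL"]) &
    dh[type == "DEL"] < thresholds$dhffc_del_max
  ok_depth[type == "DUP"] <- !is.na(dh[type == "DUP"]) &
    dh[type == "DUP"] > thresholds$dhffc_dup_min
  pass <- ok_flags & ok_mshq & ok_depth
  fate <- ifelse(pass, "pass", "fail_quality")
  names(fate) <- variantIds(x)
  list(cohort = x[pass, ], fate = fate,
       report = .stageReport(x, x[pass, ], "quality"))
}

#' Apply the genotype-frequency filter
#'
#' A locus passes when at least `minPerGenotype` individuals carry each of
#' the three genotypes (hom-ref, het, hom-alt).  Missing genotypes are not
#' counted.
#'
#' @param x An [SVCohort-class].
#' @param minPerGenotype Minimum count per genotype class (default 2).
#' @return As [applyQualityFilters()], with fate
#'   `"fail_genotype_frequency"` for removed loci.
#' @export
applyGenotypeFrequencyFilter <- function(x, minPerGenotype = 2) {
  gt <- genotypes(x)
  counts <- vapply(0:2, function(g) rowSums(gt == g, na.rm = TRUE),
                   numeric(nrow(gt)))
  if (nrow(gt) == 1L) counts <- matrix(counts, nrow = 1L)
  pass <- rowSums(counts >= minPerGenotype) == 3L
  fate <- ifelse(pass, "pass", "fail_genotype_frequency")
  names(fate) <- variantIds(x)
  list(cohort = x[pass, ], fate = fate,
       report = .stageReport(x, x[pass, ], "genotype_frequency"))
}

#' Apply curation decisions
#'
#' Keeps loci whose decision is `ACCEPT`.  Loci without a decision are
#' handled per `missingPolicy`: rejected (default, conservative), accepted,
#' or an error.
#'
#' @param x An [SVCohort-class].
#' @param decisions A `data.frame` with `variant_id` and `decision`
#'   (`ACCEPT`/`REJECT`), e.g. from [readCurationDecisions()], or `NULL`
#'   for no curation (all loci kept).
#' @param missingPolicy `"reject"`, `"accept"` or `"error"`.
#' @return As [applyQualityFilters()], with fate `"rejected_curation"`.
#' @export
applyCuration <- function(x, decisions,
                          missingPolicy = c("reject", "accept", "error")) {
  missingPolicy <- match.arg(missingPolicy)
  if (is.null(decisions)) {
    pass <- rep(TRUE, nrow(x))
  } else {
    if (anyDuplicated(decisions$variant_id))
      stop("duplicate decision for variant(s): ",
           paste(unique(decisions$variant_id[duplicated(decisions$variant_id)]),
                 collapse = ", "))
    dec <- decisions$decision[match(variantIds(x), decisions$variant_id)]
    if (any(is.na(dec)) && missingPolicy == "error")
      stop(sum(is.na(dec)), " variant(s) lack a curation decision")
    dec[is.na(dec)] <- if (missingPolicy == "accept") "ACCEPT" else "REJECT"
    pass <- dec == "ACCEPT"
  }
  fate <- ifelse(pass, "pass", "rejected_curation")
  names(fate) <- variantIds(x)
  list(cohort = x[pass, ], fate = fate,
       report = .stageReport(x, x[pass, ], "curation"))
}

.stageReport <- function(before, after, stage) {
  m <- rbind(countByType(before), countByType(after))
  df <- data.frame(stage = c(paste0("before_", stage), paste0("after_", stage)),
                   m)
  colnames(df) <- c("stage", SV_TYPES, "Total")
  df
}

#' Run the full filter cascade
#'
#' Applies, in order: quality thresholds, genotype-frequency filter,
#' curation decisions.  Genotype counts are computed on the post-quality
#' set, and curation sees only loci surviving both earlier stages, so
#' stage counts are non-increasing by construction.
#'
#' @param x An [SVCohort-class] of raw calls.
#' @param thresholds A [filterThresholds()] object.
#' @param decisions Optional curation decision `data.frame` (see
#'   [applyCuration()]).
#' @param missingPolicy Policy for loci without a curation decision
#'   (ignored when `decisions` is `NULL`).
#' @param onMissingDhffc Passed to [applyQualityFilters()].
#' @return A list with
#'   * `cohort`: the final [SVCohort-class];
#'   * `report`: a `data.frame` of per-type locus counts at each stage
#'     (`raw`, `after_quality`, `after_genotype_frequency`,
#'     `after_curation`) plus the per-type fraction of raw calls removed;
#'   * `fate`: named character vector over all input loci
#'     (`pass` / `fail_quality` / `fail_genotype_frequency` /
#'     `rejected_curation`).
#' @export
filterCascade <- function(x, thresholds = filterThresholds(),
                          decisions = NULL, missingPolicy = "reject",
                          onMissingDhffc = "drop") {
  q <- applyQualityFilters(x, thresholds, onMissingDhffc)
  g <- applyGenotypeFrequencyFilter(q$cohort, thresholds$min_per_genotype)
  cu <- applyCuration(g$cohort, decisions, missingPolicy)
  fate <- q$fate
  fate[names(g$fate)] <- g$fate
  fate[names(cu$fate)] <- cu$fate
  counts <- rbind(raw = countByType(x),
                  after_quality = countByType(q$cohort),
                  after_genotype_frequency = countByType(g$cohort),
                  after_curation = countByType(cu$cohort))
  report <- data.frame(stage = rownames(counts), counts, row.names = NULL)
  colnames(report) <- c("stage", SV_TYPES, "Total")
  removed <- 1 - counts["after_curation", ] /
    pmax(counts["raw", ], 1)
  removed[counts["raw", ] == 0] <- 0
  attr(report, "fraction_removed") <- removed
  list(cohort = cu$cohort, report = report, fate = fate)
}
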