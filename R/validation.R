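#' Mendelian consistency of a genotype trio
#'
#' A child genotype is consistent when it can be formed by one allele
#' transmitted from each parent.  With dosage coding (0/1/2 ALT alleles)
#' each parent transmits 1 ALT allele when homozygous ALT, 0 when
#' homozygous REF, and 0 or 1 when heterozygous, so the set of attainable
#' child dosages is the contiguous range
#' `[(father == 2) + (mother == 2), (father >= 1) + (mother >= 1)]`.
#'
#' @param father,mother,child Integer genotype vectors (0/1/2).  Missing
#'   values are an error; exclude them beforehand (see
#'   [trioConcordance()]).
#' @return Logical vector.
#' @examples
#' isMendelianConsistent(0L, 0L, 1L)  # FALSE
#' isMendelianConsistent(1L, 1L, 0:2) # all TRUE
#' @export
isMendelianConsistent <- function(father, mother, child) {
  if (anyNA(father) || anyNA(mother) || anyNA(child))
    stop("missing genotypes: exclude loci with MISSING calls first")
  stopifnot(all(father %in% 0:2), all(mother %in% 0:2), all(child %in% 0:2))
  cmin <- (father == 2L) + (mother == 2L)
  cmax <- (father >= 1L) + (mother >= 1L)
  child >= cmin & child <= cmax
}

#' Trio genotype concordance
#'
#' Fraction of loci at which the child genotype follows Mendelian
#' inheritance from the two parents.  Loci with a missing genotype in any
#' of the three individuals are excluded from the denominator.
#'
#' @param x An [SVCohort-class].
#' @param trios A `data.frame` with columns `child`, `father`, `mother`
#'   (e.g. from [readPedigree()]); one row per trio.
#' @return A `data.frame` with one row per trio: `child`, `father`,
#'   `mother`, `n_tested`, `n_consistent`, `concordance` (`NA` when no
#'   locus could be tested).
#' @export
trioConcordance <- function(x, trios) {
  .checkSampleIds(unique(unlist(trios[c("child", "father", "mother")])), x)
  gt <- genotypes(x)
  out <- lapply(seq_len(nrow(trios)), function(i) {
    gf <- gt[, trios$father[i]]
    gm <- gt[, trios$mother[i]]
    gc <- gt[, trios$child[i]]
    ok <- !is.na(gf) & !is.na(gm) & !is.na(gc)
    n_tested <- sum(ok)
    n_cons <- if (n_tested)
      sum(isMendelianConsistent(gf[ok], gm[ok], gc[ok])) else 0L
    data.frame(child = trios$child[i], father = trios$father[i],
               mother = trios$mother[i], n_tested = n_tested,
               n_consistent = n_cons,
               concordance = if (n_tested) n_cons / n_tested else NA_real_)
  })
  do.call(rbind, out)
}

#' PCA of SV genotype dosages
#'
#' Samples x loci dosage matrix (ALT-allele counts 0/1/2), missing values
#' imputed by the locus mean, loci mean-centered, then an
#' eigendecomposition of the sample covariance (via [stats::prcomp]).
#' Dosage is relative to the ALT allele, as in standard SNP tooling;
#' polarization is irrelevant for structure.
#'
#' @param x An [SVCohort-class] with at least 2 samples and 2 loci.
#' @param nComponents Number of components to return (default 20, capped
#'   at the matrix rank).
#' @return A list of class `PCAResult` with `scores` (samples x
#'   components), `explained_variance` (fraction per component, decreasing)
#'   and `n_components`.
#' @export
pcaGenotypes <- function(x, nComponents = 20) {
  stopifnot(ncol(x) >= 2, nrow(x) >= 2)
  m <- t(genotypes(x))                      # samples x loci
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2]]
  m <- sweep(m, 2, colMeans(m))
  if (all(abs(m) < 1e-12))
    stop("no variance: all genotypes constant")
  k <- min(nComponents, ncol(x) - 1L, nrow(x))
  pc <- stats::prcomp(m, center = FALSE, rank. = k)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained_variance = ev[seq_len(k)],
                 n_components = k),
            class = "PCAResult")
}

#' Silhouette-style separation of a two-group labelling on PC scores
#'
#' Mean silhouette width of the given grouping in the space of the first
#' `dims` principal components (Euclidean distance).  Positive values mean
#' the groups form separated clusters; values near zero or below mean the
#' labelling does not correspond to cluster structure.  Used to diagnose
#' sequencing-batch artifacts: rejected (false) SV calls tend to separate a
#' batch, curated calls do not.
#'
#' @param pca A `PCAResult` from [pcaGenotypes()].
#' @param groups Factor/character vector over samples (2+ levels).
#' @param dims Which components to use (default `1:2`).
#' @return Mean silhouette width (numeric scalar).
#' @export
groupSeparation <- function(pca, groups, dims = 1:2) {
  s <- pca$scores[, dims, drop = FALSE]
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(s), nlevels(groups) >= 2)
  d <- as.matrix(stats::dist(s))
  sil <- vapply(seq_len(nrow(s)), function(i) {
    own <- groups == groups[i]
    own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(levels(groups), as.character(groups[i])),
                    function(lv) mean(d[i, groups == lv]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
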