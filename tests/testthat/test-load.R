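polFor <- function(co, ancestral) {
  data.frame(variant_id = variantIds(co),
             ancestral = factor(ancestral,
                                levels = c("REF", "ALT", "UNPOLARIZED")),
             derived_is_reference = ancestral == "ALT",
             mutation_class = "TRUE_DELETION", stringsAsFactors = FALSE)
}

test_that("derived allele frequencies respect polarity and missingness", {
  gt <- rbind(c(rep(1L, 4), rep(0L, 36)),   # 4 derived alleles / 80
              rep(1L, 40),                  # all het
              rep(0L, 40))                  # ancestral = ALT: all derived
  co <- makeCohort(rep("DEL", 3), dhffc = 0.5, gt = gt)
  pol <- polFor(co, c("REF", "REF", "ALT"))
  f <- derivedAlleleFrequency(co, pol)
  expect_equal(unname(f), c(0.05, 0.5, 1.0))
  # missing genotypes shrink the denominator
  gt2 <- rbind(c(1L, 1L, NA, NA))
  co2 <- makeCohort("DEL", dhffc = 0.5, gt = gt2)
  expect_equal(unname(derivedAlleleFrequency(co2, polFor(co2, "REF"))), 0.5)
  # strict errors
  expect_error(derivedAlleleFrequency(co2, polFor(co2, "UNPOLARIZED")),
               "unpolarized")
  gt3 <- rbind(rep(NA_integer_, 4))
  co3 <- makeCohort("DEL", dhffc = 0.5, gt = gt3)
  expect_error(derivedAlleleFrequency(co3, polFor(co3, "REF")),
               "no non-missing")
})

test_that("SFS bins are 0.05-wide, polymorphic-only, and sum correctly", {
  sfs <- sfsFromFrequencies(c(0.04, 0.05, 0.93, 0, 1, NA))
  expect_equal(length(sfs$counts), 20L)
  expect_equal(sfs$counts[1], 1L)    # [0, 0.05)
  expect_equal(sfs$counts[2], 1L)    # [0.05, 0.10)
  expect_equal(sfs$counts[19], 1L)   # [0.90, 0.95)
  expect_equal(sfs$n_loci, 3L)       # fixed and NA loci excluded
  expect_equal(sum(sfs$counts), sfs$n_loci)
  # the last bin is closed at 1 but excludes fixed loci
  sfs2 <- sfsFromFrequencies(c(0.999, 1))
  expect_equal(sfs2$counts[20], 1L)
  expect_warning(sfsFromFrequencies(numeric(0)), "empty spectrum")
})

test_that("goodness-of-fit statistic matches hand computation", {
  # proportional spectra: statistic 0, p 1
  g0 <- sfsGofTest(c(10, 20, 30), c(100, 200, 300))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p.value, 1)
  # obs (10, 0) against equal proportions: ((10-5)^2 + (0-5)^2) / 5 = 10
  g1 <- sfsGofTest(c(10, 0), c(50, 50))
  expect_equal(g1$statistic, 10)
  expect_equal(g1$df, 1)
  expect_equal(g1$p.value, stats::pchisq(10, 1, lower.tail = FALSE))
  # pooling from the right until expected >= 5: (20,6,3,1) pools twice,
  # since 3 + 1 = 4 still falls short of the threshold
  g2 <- sfsGofTest(c(20, 6, 3, 1), c(200, 60, 30, 10))
  expect_equal(length(g2$expected), 2L)
  expect_true(all(g2$expected >= 5))
  expect_equal(sum(g2$observed), 30)
  # degenerate: everything pools into one bin
  expect_error(sfsGofTest(c(1, 1), c(1, 1)), "degenerate")
})

test_that("individual load partitions called loci", {
  gt <- matrix(c(rep(1L, 4), rep(2L, 3), rep(0L, 3)), 10, 1)
  co <- makeCohort(rep("DEL", 10), dhffc = 0.5, gt = gt, len = 2000)
  pol <- polFor(co, rep("REF", 10))
  ov <- data.frame(variant_id = variantIds(co), category = "PARTIAL_CDS")
  ld <- individualLoad(co, pol, ov)
  expect_equal(ld$masked_load, 0.4)
  expect_equal(ld$realized_load, 0.3)
  expect_equal(ld$n_het + ld$n_hom_derived + ld$n_hom_ancestral,
               ld$n_loci_called)
  # all hom-ancestral: both loads zero
  co0 <- makeCohort(rep("DEL", 5), dhffc = 0.5, gt = matrix(0L, 5, 1))
  ld0 <- individualLoad(co0, polFor(co0, rep("REF", 5)),
                        data.frame(variant_id = variantIds(co0),
                                   category = "ENCLOSING"))
  expect_equal(ld0$masked_load, 0)
  expect_equal(ld0$realized_load, 0)
  # ancestral-ALT and unpolarized loci are excluded from the locus set
  pol2 <- polFor(co, c(rep("REF", 5), rep("ALT", 3), "UNPOLARIZED",
                       "UNPOLARIZED"))
  ld2 <- individualLoad(co, pol2, ov)
  expect_equal(ld2$n_loci_called, 5L)
})

test_that("load partition identity holds for every simulated individual", {
  sim <- simulateCohort(smallConfig(seed = 31))
  res <- filterCascade(sim$cohort, decisions = truthDecisions(sim))
  co <- res$cohort
  pol <- polarize(co, sim$outgroups[, variantIds(co), drop = FALSE])
  ov <- classifyGeneOverlap(co, sim$geneModels)
  ld <- individualLoad(co, pol, ov)
  expect_equal(ld$n_het + ld$n_hom_derived + ld$n_hom_ancestral,
               ld$n_loci_called)
  ok <- ld$n_loci_called > 0
  expect_equal(ld$masked_load[ok] + ld$realized_load[ok] +
                 ld$n_hom_ancestral[ok] / ld$n_loci_called[ok],
               rep(1, sum(ok)))
})

test_that("group summaries order generation classes and handle ties", {
  ld <- data.frame(sample_id = c("a", "b", "c", "d"),
                   n_loci_called = 10L, n_het = 5L, n_hom_derived = 2L,
                   n_hom_ancestral = 3L, masked_load = 0.5,
                   realized_load = 0.2)
  si <- data.frame(sample_id = c("a", "b", "c", "d"),
                   population = c("SCAND_ORIGINAL", "SCAND_ORIGINAL",
                                  "SCAND_IMMIGRANT_DESC", "FINLAND"),
                   generation_class = c("F2", "F1", "L1", NA))
  grp <- loadByGroup(ld, si)
  expect_equal(grp$group, c("F1", "F2", "L1", "FINLAND"))
  expect_equal(grp$n, rep(1L, 4))
  # identical inputs give identical group means
  expect_true(all(grp$mean_masked == 0.5))
  expect_true(all(grp$mean_realized == 0.2))
})

test_that("rank-sum comparison is exact where enumeration is feasible", {
  # most extreme ranking of 3 vs 3: two-sided p = 2/20
  r <- compareGroups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p.value, 0.1)
  expect_equal(r$statistic, 6)
  # identical groups: all tied, p = 1
  expect_equal(compareGroups(rep(1, 5), rep(1, 7))$p.value, 1)
  # agreement with full enumeration for all partitions of <= 8 values
  set.seed(32)
  pools <- list(c(1.2, 3.4, 0.5, 2.2, 5.1, 4.4, 2.9, 1.1),   # no ties
                c(1, 1, 2, 2, 3, 3, 4, 5),                   # ties
                c(0, 0, 0, 1, 1, 2, 7, 7))                   # heavy ties
  for (vals in pools) {
    for (n1 in 1:7) {
      a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
      expect_equal(compareGroups(a, b)$p.value, enumRankSumP(a, b),
                   tolerance = 1e-12,
                   label = paste("split", n1, "of", length(vals)))
    }
  }
  # no-ties path agrees with the reference implementation
  for (i in 1:20) {
    a <- sample(1000, sample(2:10, 1))
    b <- sample(2000:3000, sample(2:10, 1))
    expect_equal(compareGroups(a, b)$p.value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large tied samples fall back to the tie-corrected normal approximation
  big_a <- rep(1:5, 6); big_b <- rep(2:6, 6)
  r2 <- compareGroups(big_a, big_b)
  expect_match(r2$method, "normal approximation")
  expect_true(r2$p.value > 0 && r2$p.value < 1)
})

test_that("fixation and rescue accounting matches the locus definitions", {
  # loci x samples: 6 pre, 4 post
  pre <- paste0("p", 1:6); post <- paste0("q", 1:4)
  gt <- rbind(
    c(rep(2L, 6), 1L, 2L, 2L, 2L),   # fixed pre, regained via one het
    c(rep(2L, 6), rep(2L, 4)),       # fixed pre, never regained
    c(2L, 2L, 1L, 2L, 2L, 2L, rep(2L, 4)),  # a single pre het: not fixed
    c(rep(2L, 4), NA, NA, rep(2L, 4)),      # only 4 called < minCalled
    c(rep(0L, 6), rep(0L, 4)))       # ancestral = ALT: hom-derived is 0
  colnames(gt) <- c(pre, post)
  co <- makeCohort(rep("DEL", 5), dhffc = 0.5, gt = gt)
  pol <- polFor(co, c(rep("REF", 4), "ALT"))
  rr <- fixationAndRescue(co, pol, pre, post, minCalled = 5)
  expect_equal(rr$n_fixed_pre, 3L)          # loci 1, 2 and 5
  expect_setequal(rr$fixed_pre_ids, c("v1", "v2", "v5"))
  expect_equal(rr$n_regained, 1L)
  expect_equal(rr$regained_ids, "v1")
  # founder-fixed (no het, no hom-ancestral among the original samples)
  # has no minimum-call requirement, so locus 4 also qualifies
  expect_equal(rr$n_founder_fixed, 4L)
  expect_setequal(rr$founder_fixed_ids, c("v1", "v2", "v4", "v5"))
  expect_true(rr$n_regained <= rr$n_fixed_pre)
  expect_error(fixationAndRescue(co, pol, character(0), post), "non-empty")
})

test_that("noise-free founder-fixed loci are recovered from truth", {
  sim <- simulateCohort(cleanConfig(seed = 33))
  co <- sim$cohort
  pol <- polarize(co, sim$outgroups)
  si <- sim$sample_info
  orig <- si$sample_id[si$population %in% c("FOUNDER", "SCAND_ORIGINAL")]
  post <- si$sample_id[si$population == "SCAND_IMMIGRANT_DESC"]
  pre <- si$sample_id[si$generation_class %in% c("F5", "F6")]
  rr <- fixationAndRescue(co, pol, pre, post, orig)
  # truth: founders all homozygous derived
  der <- sim$truth$genotypes
  flip <- sim$truth$ancestral == "ALT"
  der[flip, ] <- 2L - der[flip, ]
  founder_hom <- rownames(der)[rowSums(der[, c("FND1", "FND2", "FND3")]
                                       == 2L) == 3]
  polarizable <- pol$variant_id[pol$ancestral != "UNPOLARIZED"]
  expect_setequal(rr$founder_fixed_ids,
                  intersect(founder_hom, polarizable))
})
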