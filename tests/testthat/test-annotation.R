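makeGenes <- function(spans, cds) {
  g <- GenomicRanges::GRanges("chr1",
         IRanges::IRanges(vapply(spans, `[`, numeric(1), 1),
                          vapply(spans, `[`, numeric(1), 2)))
  names(g) <- paste0("g", seq_along(spans))
  GeneModelSet(g, lapply(cds, function(m)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(m[, 1], m[, 2]))))
}

test_that("gene overlap categories follow the stated priority", {
  gm <- makeGenes(list(c(200, 800), c(5100, 5900)),
                  list(rbind(c(200, 300)), rbind(c(5200, 5300))))
  co <- makeCohort(rep("DEL", 4), dhffc = 0.5,
                   start = c(100, 150, 5400, 9000),
                   len = c(901, 101, 101, 100))
  # [100,1000] contains gene1 [200,800]          -> ENCLOSING
  # [150,250] covers CDS bases of gene1          -> PARTIAL_CDS
  # [5400,5500] inside gene2, no CDS             -> NONCODING
  # [9000,9099] hits nothing                     -> INTERGENIC
  ov <- classifyGeneOverlap(co, gm)
  expect_equal(as.character(ov$category),
               c("ENCLOSING", "PARTIAL_CDS", "NONCODING", "INTERGENIC"))
  expect_equal(ov$gene_ids, c("g1", "g1", "g2", ""))
})

test_that("category assignment is invariant to gene input order", {
  set.seed(21)
  spans <- lapply(seq(1000, by = 4000, length.out = 12),
                  function(s) c(s, s + 2999))
  cds <- lapply(spans, function(sp) rbind(c(sp[1] + 500, sp[1] + 700)))
  gm1 <- makeGenes(spans, cds)
  perm <- sample(12)
  gm2 <- GeneModelSet(geneSpans(gm1)[perm], cdsIntervals(gm1)[perm])
  co <- makeCohort(rep("DEL", 30), dhffc = 0.5,
                   start = sample(1:48000, 30), len = sample(50:5000, 30))
  ov1 <- classifyGeneOverlap(co, gm1)
  ov2 <- classifyGeneOverlap(co, gm2)
  expect_equal(as.character(ov1$category), as.character(ov2$category))
  expect_equal(ov1$gene_ids, ov2$gene_ids)
})

test_that("an enclosing variant outranks its partial CDS overlap", {
  gm <- makeGenes(list(c(200, 800), c(900, 2000)),
                  list(rbind(c(250, 350)), rbind(c(950, 1050))))
  # encloses g1 completely and clips g2's CDS: ENCLOSING wins
  co <- makeCohort("DEL", dhffc = 0.5, start = 100, len = 901)
  ov <- classifyGeneOverlap(co, gm)
  expect_equal(as.character(ov$category), "ENCLOSING")
  expect_equal(ov$gene_ids, "g1")
})

test_that("repeat composition counts each base once", {
  rp <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(c(1010, 1050), c(1060, 1080)),
          repeat_class = c("SINE", "LINE"))
  co <- makeCohort("DEL", dhffc = 0.5, start = 1001, len = 100)
  comp <- repeatComposition(co, rp)
  # SINE [1010,1060] claims 51 bases; LINE keeps only [1061,1080]
  expect_equal(comp["v1", "SINE"], 51L)
  expect_equal(comp["v1", "LINE"], 20L)
  expect_equal(comp["v1", "unannotated"], 29L)
  expect_equal(sum(comp["v1", ]), 100L)

  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1060),
                                repeat_class = "SINE")
  comp1 <- repeatComposition(co, one)
  expect_equal(comp1["v1", "SINE"], 60L)
  expect_equal(comp1["v1", "unannotated"], 40L)

  none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10),
                                 repeat_class = "SINE")
  comp0 <- repeatComposition(co, none)
  expect_equal(comp0["v1", "unannotated"], 100L)
})

test_that("repeat attribution matches per-base brute force on random layouts", {
  set.seed(22)
  for (rep_i in 1:40) {
    vstart <- sample(1000:2000, 1)
    vlen <- sample(20:200, 1)
    n_feat <- sample(0:6, 1)
    rstart <- sample(900:2300, max(n_feat, 1))[seq_len(n_feat)]
    rend <- rstart + sample(10:150, n_feat, replace = TRUE)
    rclass <- sample(c("SINE", "LINE", "LTR"), n_feat, replace = TRUE)
    rp <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(if (n_feat) rstart else 1,
                             if (n_feat) rend else 1),
            repeat_class = if (n_feat) rclass else "SINE")
    co <- makeCohort("DEL", dhffc = 0.5, start = vstart, len = vlen)
    comp <- repeatComposition(co, rp)
    bf <- bruteForceComposition(vstart, vstart + vlen - 1,
                                if (n_feat) rstart else integer(0),
                                if (n_feat) rend else integer(0),
                                if (n_feat) rclass else character(0))
    expect_equal(comp["v1", names(bf)], bf, ignore_attr = TRUE)
    expect_equal(sum(comp["v1", ]), vlen)
  }
})

test_that("length spectra bin half-open and peaks aggregate repeats", {
  co <- makeCohort(rep("DEL", 3), dhffc = 0.5, len = c(190, 190, 500))
  ls <- lengthSpectrum(co, 10)
  expect_equal(ls$count[ls$bin_lo == 190], 2)
  expect_equal(ls$count[ls$bin_lo == 500], 1)
  expect_error(lengthSpectrum(co, 0))

  sim <- simulateCohort(smallConfig(seed = 23))
  pk <- peakComposition(sim$cohort, sim$repeats, c(180, 200), "DEL")
  expect_gt(pk$proportions["SINE"], 0.8)
  # a window with no variants yields a zero composition, not an error
  pk0 <- peakComposition(sim$cohort, sim$repeats, c(2e7, 3e7), "DEL")
  expect_equal(pk0$n_loci, 0L)
  expect_true(all(pk0$proportions == 0))
})

test_that("polarization requires two concordant homozygous outgroups", {
  co <- makeCohort(c("DEL", "DEL", "DEL", "DEL", "DEL", "DUP", "INV"),
                   dhffc = c(rep(0.5, 5), 1.5, NA))
  og <- rbind(c(0L, 2L, 0L, 1L, NA, 2L, 0L),
              c(0L, 2L, 2L, 0L, 0L, 2L, 0L))
  pol <- polarize(co, og)
  expect_equal(as.character(pol$ancestral),
               c("REF", "ALT", "UNPOLARIZED", "UNPOLARIZED", "UNPOLARIZED",
                 "ALT", "REF"))
  expect_equal(pol$mutation_class,
               c("TRUE_DELETION", "INSERTION", "UNPOLARIZED", "UNPOLARIZED",
                 "UNPOLARIZED", "COPY_LOSS_IN_REFERENCE",
                 "INVERSION_DERIVED"))
  expect_equal(pol$derived_is_reference,
               c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # symmetric under outgroup exchange
  pol2 <- polarize(co, og[2:1, ])
  expect_identical(pol, pol2)
  expect_error(polarize(co, og[1, , drop = FALSE]), "two outgroup")
})

test_that("reference-ancestral subset picks exactly ancestral-REF loci", {
  pol <- data.frame(variant_id = c("a", "b", "c"),
                    ancestral = factor(c("REF", "ALT", "UNPOLARIZED"),
                                       levels = c("REF", "ALT",
                                                  "UNPOLARIZED")))
  expect_equal(referenceAncestralSubset(pol), "a")
  expect_length(referenceAncestralSubset(pol[0, ]), 0L)
})
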