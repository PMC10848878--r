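test_that("VCF records map to 1-based loci with END-derived lengths", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=2000000>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=DHFFC,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MSHQ,Number=1,Type=Float,Description=\"m\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "1000", "d1", "N", "<DEL>", ".", "PASS",
          "SVTYPE=DEL;END=1189;DHFFC=0.5;MSHQ=4", "GT", "0/1", "./.",
          sep = "\t"),
    paste("chr1", "5000", "b1", "N", "N[chr2:100[", ".", "PASS",
          "SVTYPE=BND;END=5001", "GT", "0/0", "0/1", sep = "\t"),
    paste("chrX", "9000", "i1", "N", "<INV>", ".", "PASS",
          "SVTYPE=INV;END=9099;MSHQ=7", "GT", "1/1", "0|1", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  expect_message(co <- readSVVcf(f), "skipped")
  expect_equal(nrow(co), 2L)        # BND dropped
  expect_equal(svLen(co)[1], 190)   # END - POS + 1
  expect_equal(genotypes(co)["d1", ], c(s1 = 1L, s2 = NA_integer_))
  expect_equal(genotypes(co)["i1", ], c(s1 = 2L, s2 = 1L))  # phased sep
  expect_equal(dhffc(co), c(0.5, NA))
  expect_equal(mshq(co), c(4, 7))
  expect_false(S4Vectors::mcols(
    SummarizedExperiment::rowRanges(co))$is_autosomal[2])   # chrX
})

test_that("SVLEN is preferred over END-POS arithmetic when present", {
  co <- makeCohort("DEL", dhffc = 0.4, start = 1000, len = 250)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(co))$svlen <- 250
  f <- tempfile(fileext = ".vcf")
  writeSVVcf(co, f)
  # corrupt END so only SVLEN carries the length
  txt <- readLines(f)
  txt <- sub("END=1249", "END=1000", txt)
  writeLines(txt, f)
  co2 <- readSVVcf(f)
  expect_equal(svLen(co2), 250)
})

test_that("write -> read round trip preserves the cohort", {
  sim <- simulateCohort(smallConfig(seed = 42))
  f <- tempfile(fileext = ".vcf")
  writeSVVcf(sim$cohort, f)
  co2 <- readSVVcf(f)
  co <- sim$cohort
  expect_identical(variantIds(co2), variantIds(co))
  expect_identical(sampleIds(co2), sampleIds(co))
  expect_identical(genotypes(co2), genotypes(co))
  expect_identical(svType(co2), svType(co))
  expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(co2)),
               GenomicRanges::start(SummarizedExperiment::rowRanges(co)))
  expect_equal(GenomicRanges::end(SummarizedExperiment::rowRanges(co2)),
               GenomicRanges::end(SummarizedExperiment::rowRanges(co)))
  expect_equal(dhffc(co2), dhffc(co), tolerance = 1e-8)
  expect_equal(mshq(co2), mshq(co), tolerance = 1e-8)
})

test_that("malformed genotype ploidy is reported with the offending record", {
  co <- makeCohort(c("DEL", "DUP"), dhffc = c(0.4, 1.5))
  f <- tempfile(fileext = ".vcf")
  writeSVVcf(co, f)
  txt <- readLines(f)
  txt[length(txt)] <- sub("0/0\t0/0\t0/0\t0/0", "0/0\t0\t0/0\t0/0",
                          txt[length(txt)])
  writeLines(txt, f)
  expect_error(readSVVcf(f), "ploidy.*v2")
})

test_that("BED repeats convert exactly from 0-based half-open", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t199\tSINE", "chr1\t300\t450\tLINE"), f)
  rp <- readRepeats(f)
  expect_equal(GenomicRanges::start(rp), c(100, 301))
  expect_equal(GenomicRanges::end(rp), c(199, 450))
  expect_equal(GenomicRanges::width(rp), c(100, 150))
  expect_equal(S4Vectors::mcols(rp)$repeat_class, c("SINE", "LINE"))
})

test_that("GFF3 gene models keep 1-based CDS and merge overlaps", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tsrc\tgene\t100\t900\t.\t+\t.\tID=g1",
    "chr1\tsrc\tCDS\t200\t800\t.\t+\t0\tID=c1;Parent=g1",
    "chr1\tsrc\tCDS\t700\t900\t.\t+\t0\tID=c2;Parent=g1"), f)
  gm <- readGeneModels(f)
  expect_equal(GenomicRanges::start(geneSpans(gm)), 100)
  cds <- cdsIntervals(gm)[["g1"]]
  # merged to one disjoint interval equal to the per-base union
  expect_equal(length(cds), 1L)
  union_bases <- union(200:800, 700:900)
  expect_equal(GenomicRanges::start(cds), min(union_bases))
  expect_equal(GenomicRanges::end(cds), max(union_bases))
  expect_equal(sum(GenomicRanges::width(cds)), length(union_bases))
})

test_that("BED12 genes derive CDS from blocks clipped to the thick region", {
  f <- tempfile(fileext = ".bed")
  writeLines(paste("chr1", 99, 999, "g1", 0, "+", 199, 899, "0", 2,
                   "200,200", "0,700", sep = "\t"), f)
  gm <- readGeneModels(f)
  expect_equal(GenomicRanges::start(geneSpans(gm)), 100)
  expect_equal(GenomicRanges::end(geneSpans(gm)), 999)
  cds <- cdsIntervals(gm)[["g1"]]
  expect_equal(GenomicRanges::start(cds), c(200, 800))
  expect_equal(GenomicRanges::end(cds), c(299, 899))
})

test_that("sample, pedigree and decision tables are validated", {
  co <- makeCohort("DEL", dhffc = 0.4,
                   gt = matrix(0L, 1, 3,
                               dimnames = list(NULL, c("c", "f", "m"))))
  s <- tempfile(); p <- tempfile(); d <- tempfile()
  writeTsv(data.frame(sample_id = c("c", "f", "m"),
                      population = "FINLAND"), s)
  expect_silent(si <- readSampleInfo(s, co))
  expect_equal(nrow(si), 3L)

  writeTsv(data.frame(sample_id = c("c", "c"), population = "FINLAND"), s)
  expect_error(readSampleInfo(s), "duplicated sample_id")

  writeTsv(data.frame(child = "c", father = "f", mother = "m"), p)
  expect_silent(readPedigree(p, co))
  writeTsv(data.frame(child = "c", father = "ghost", mother = "m"), p)
  expect_error(readPedigree(p, co), "ghost")
  writeTsv(data.frame(child = "c", father = "c", mother = "m"), p)
  expect_error(readPedigree(p), "non-distinct")

  writeTsv(data.frame(variant_id = c("a", "a"),
                      decision = c("ACCEPT", "REJECT")), d)
  expect_error(readCurationDecisions(d), "duplicate decision")
  writeTsv(data.frame(variant_id = "a", decision = "MAYBE"), d)
  expect_error(readCurationDecisions(d), "unknown decision")
})
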