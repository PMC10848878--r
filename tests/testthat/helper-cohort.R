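# fixture builders shared across test files; everything is generated in code

# minimal cohort: one row per element of svtype
makeCohort <- function(svtype, dhffc = NA_real_, mshq = 5,
                       gt = NULL, start = NULL, len = 100,
                       chrom = "chr1", autosomal = TRUE, biallelic = TRUE,
                       ids = NULL) {
  n <- length(svtype)
  if (is.null(start)) start <- seq(1000, by = 100000, length.out = n)
  len <- rep_len(len, n)
  if (is.null(gt)) gt <- matrix(0L, n, 4)
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
          IRanges::IRanges(start, width = len),
          svtype = svtype, svlen = as.numeric(len),
          dhffc = rep_len(dhffc, n), mshq = rep_len(mshq, n),
          is_autosomal = rep_len(autosomal, n),
          is_biallelic = rep_len(biallelic, n))
  names(gr) <- if (is.null(ids)) paste0("v", seq_len(n)) else ids
  SVCohort(gr, gt)
}

# scaled-down simulation for fast unit tests
smallConfig <- function(...) {
  args <- list(n_loci_neutral = 300, n_loci_deleterious = 100, seed = 1)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulationConfig, args)
}

# noise-free study conditions (truth-level guarantees apply exactly)
cleanConfig <- function(...) {
  smallConfig(genotyping_error_rate = 0, missing_rate = 0,
              artifact_fraction = 0, ...)
}

# per-base brute-force repeat attribution: smallest start wins, ties by
# class name; independent oracle for repeatComposition
bruteForceComposition <- function(vstart, vend, rstart, rend, rclass) {
  classes <- c(sort(unique(rclass)), "unannotated")
  counts <- stats::setNames(rep(0L, length(classes)), classes)
  for (b in vstart:vend) {
    cover <- which(rstart <= b & rend >= b)
    if (!length(cover)) {
      counts["unannotated"] <- counts["unannotated"] + 1L
    } else {
      pick <- cover[order(rstart[cover], rclass[cover])][1]
      counts[rclass[pick]] <- counts[rclass[pick]] + 1L
    }
  }
  counts
}

# exhaustive two-sided rank-sum p-value by direct enumeration (midranks)
enumRankSumP <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  wall <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(wall - mu) >= abs(w - mu) - 1e-9)
}
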