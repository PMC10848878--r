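#' Configuration for the synthetic SV cohort generator
#'
#' Defines the study conditions emulated by [simulateCohort()]: a small
#' population founded by three individuals and inbred for several
#' generations in closed full-sib lines, a large source population, a
#' late immigration event whose offspring form the L1 class, two outgroup
#' individuals for polarization, and a configurable spike of low-quality
#' false calls sharing a sequencing batch.
#'
#' Defaults: 400 putatively deleterious loci (derived founder frequencies
#' Beta(1.5, 8.5), mean 0.15) overlapping coding sequence and 1600 neutral
#' intronic loci (Beta(1.5, 4.5), mean 0.25); SV type mix 80% DEL / 10%
#' DUP / 10% INV; six inbreeding generations of 3 breeding pairs x 7
#' offspring (21 individuals per generation class F1..F6); 2 reproducing
#' immigrants x 7 offspring (14 L1 individuals); 26 + 14 source samples;
#' 60% of loci polarizable; 50% of loci with the reference allele
#' ancestral; deletion lengths with a point mass near 190 bp (SINE
#' presence/absence) and duplications near 160 bp (LINE), both with a
#' lognormal tail.
#'
#' @param n_loci_neutral,n_loci_deleterious Locus counts per class.
#' @param sv_type_mix Named proportions over `DEL`, `DUP`, `INV`
#'   (must sum to 1).
#' @param founder_freq_params_neutral,founder_freq_params_deleterious
#'   `c(shape1, shape2)` of the Beta law for derived allele frequencies in
#'   the source population; the deleterious law is shifted toward 0.
#' @param n_source_finland,n_source_russia Source-population sample sizes.
#' @param n_generations Inbreeding generations after the three-founder
#'   bottleneck.
#' @param lines_per_generation Breeding pairs per generation.
#' @param offspring_per_pair Offspring per breeding pair.
#' @param mating `"sibline"` (default): each line continues by full-sib
#'   mating, giving deterministic per-generation inbreeding;
#'   `"random"`: pairs drawn uniformly from the previous generation.
#' @param immigrant_generation Generation whose individuals the
#'   reproducing immigrants mate with (their offspring are class L1);
#'   must be at least 1.
#' @param n_immigrants_reproducing,n_immigrants_nonreproducing Immigrant
#'   counts.
#' @param offspring_per_immigrant Offspring per reproducing immigrant.
#' @param genotyping_error_rate Probability a genotype is miscalled (the
#'   miscall is uniform over the two other genotypes).
#' @param missing_rate Probability a genotype is missing.
#' @param artifact_fraction Extra false loci injected, as a fraction of
#'   the true locus count.
#' @param batch_fraction Fraction of samples forming the shared
#'   sequencing batch at artifact loci.
#' @param polarizable_fraction Fraction of loci at which both outgroups
#'   are homozygous ancestral (polarizable).
#' @param ref_ancestral_fraction Fraction of loci at which the reference
#'   allele is the ancestral allele.
#' @param length_model List with `del_peak`, `dup_peak`, `peak_sd`,
#'   `peak_weight`, `tail_meanlog`, `tail_sdlog`, `min_len`, `max_len`.
#' @param seed Integer seed; the whole simulation is deterministic given
#'   the configuration.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    n_loci_neutral = 1600, n_loci_deleterious = 400,
    sv_type_mix = c(DEL = 0.8, DUP = 0.1, INV = 0.1),
    founder_freq_params_neutral = c(1.5, 4.5),
    founder_freq_params_deleterious = c(1.5, 8.5),
    n_source_finland = 26, n_source_russia = 14,
    n_generations = 6, lines_per_generation = 3, offspring_per_pair = 7,
    mating = c("sibline", "random"),
    immigrant_generation = 5,
    n_immigrants_reproducing = 2, n_immigrants_nonreproducing = 4,
    offspring_per_immigrant = 7,
    genotyping_error_rate = 0.02, missing_rate = 0.02,
    artifact_fraction = 0.1, batch_fraction = 0.4,
    polarizable_fraction = 0.6, ref_ancestral_fraction = 0.5,
    length_model = list(del_peak = 190, dup_peak = 160, peak_sd = 4,
                        peak_weight = 0.5, tail_meanlog = log(1200),
                        tail_sdlog = 0.9, min_len = 50, max_len = 10000),
    seed = 1) {
  mating <- match.arg(mating)
  cfg <- as.list(environment())
  stopifnot(n_loci_neutral > 0, n_loci_deleterious > 0,
            all(sv_type_mix >= 0), all(sv_type_mix <= 1),
            n_generations >= 1, lines_per_generation >= 1,
            offspring_per_pair >= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            artifact_fraction >= 0,
            polarizable_fraction >= 0, polarizable_fraction <= 1,
            ref_ancestral_fraction >= 0, ref_ancestral_fraction <= 1)
  if (abs(sum(sv_type_mix) - 1) > 1e-8)
    stop("sv_type_mix must sum to 1")
  if (!setequal(names(sv_type_mix), SV_TYPES))
    stop("sv_type_mix must be named DEL, DUP, INV")
  if (immigrant_generation < 1)
    stop("impossible pedigree: immigrants cannot breed at generation 0")
  if (immigrant_generation > n_generations)
    stop("immigrant_generation must be <= n_generations")
  structure(cfg, class = "SimulationConfig")
}

#' Gene dropping down a pedigree
#'
#' Simulates Mendelian transmission: each offspring receives, at every
#' locus independently, one uniformly chosen allele from each parent.
#' Founders (rows with missing parents) must have genotypes supplied.
#'
#' @param pedigree A `data.frame` with columns `id`, `father`, `mother`
#'   (`NA` parents mark founders).  Any order; a cyclic pedigree is an
#'   error.
#' @param founderGenotypes Integer matrix, loci x founders (ALT dosage
#'   0/1/2), with column names matching the founder ids.
#' @return Integer matrix, loci x all pedigree individuals.
#' @examples
#' ped <- data.frame(id = c("f", "m", "c"), father = c(NA, NA, "f"),
#'                   mother = c(NA, NA, "m"))
#' fg <- matrix(c(2L, 0L), 1, 2, dimnames = list(NULL, c("f", "m")))
#' geneDrop(ped, fg)  # child is always heterozygous
#' @export
geneDrop <- function(pedigree, founderGenotypes) {
  is_founder <- is.na(pedigree$father) & is.na(pedigree$mother)
  if (any(is.na(pedigree$father) != is.na(pedigree$mother)))
    stop("individuals must have either two parents or none")
  miss <- setdiff(pedigree$id[is_founder], colnames(founderGenotypes))
  if (length(miss))
    stop("founder genotypes missing for: ", paste(miss, collapse = ", "))
  L <- nrow(founderGenotypes)
  gt <- matrix(NA_integer_, L, nrow(pedigree),
               dimnames = list(rownames(founderGenotypes), pedigree$id))
  if (any(is_founder))
    gt[, pedigree$id[is_founder]] <-
      founderGenotypes[, pedigree$id[is_founder], drop = FALSE]
  done <- is_founder
  while (!all(done)) {
    ready <- !done & pedigree$father %in% pedigree$id[done] &
      pedigree$mother %in% pedigree$id[done]
    if (!any(ready))
      stop("cyclic or incomplete pedigree: cannot resolve ",
           paste(utils::head(pedigree$id[!done], 3), collapse = ", "))
    for (i in which(ready)) {
      gf <- gt[, pedigree$father[i]]
      gm <- gt[, pedigree$mother[i]]
      gt[, i] <- stats::rbinom(L, 1L, gf / 2) + stats::rbinom(L, 1L, gm / 2)
    }
    done <- done | ready
  }
  gt
}

#' Inject false-positive SV loci with batch-correlated genotypes
#'
#' Appends `round(artifact_fraction * nrow(x))` spurious loci emulating
#' the false calls shared by samples sequenced together.  Injected
#' deletions carry a depth fold-change of at least 0.7 (no depth drop, so
#' they fail the deletion quality threshold); injected duplications and
#' inversions either fail the MSHQ threshold or pass all quality
#' thresholds and are only caught by curation.  Genotypes at injected
#' loci are heterozygote-enriched within the batch subset and mostly
#' hom-ref outside it.  With `artifact_fraction = 0` the cohort is
#' returned unchanged.
#'
#' Uses the current RNG state ([simulateCohort()] calls it under the
#' configured seed).
#'
#' @param x An [SVCohort-class].
#' @param config A [simulationConfig()].
#' @param batchSamples Sample ids forming the batch; default: the first
#'   `batch_fraction` of samples.
#' @return A list with `cohort` (augmented), `artifact_ids` (ids of the
#'   injected loci) and `batch_samples`.
#' @export
injectArtifacts <- function(x, config, batchSamples = NULL) {
  n_art <- round(config$artifact_fraction * nrow(x))
  if (n_art == 0)
    return(list(cohort = x, artifact_ids = character(0),
                batch_samples = character(0)))
  if (is.null(batchSamples))
    batchSamples <- sampleIds(x)[seq_len(ceiling(
      config$batch_fraction * ncol(x)))]
  lm <- config$length_model
  type <- sample(names(config$sv_type_mix), n_art, replace = TRUE,
                 prob = config$sv_type_mix)
  len <- pmin(pmax(round(stats::rlnorm(n_art, lm$tail_meanlog,
                                       lm$tail_sdlog)), lm$min_len),
              lm$max_len)
  # place after the last occupied slot
  gr0 <- SummarizedExperiment::rowRanges(x)
  offset <- max(GenomicRanges::end(gr0)) + 50000 *
    (seq_len(n_art))
  start <- offset + 1000
  dh <- rep(NA_real_, n_art)
  ms <- stats::runif(n_art, 3, 12)
  flavour <- sample(c("bad_mshq", "pass_all"), n_art, replace = TRUE)
  dh[type == "DEL"] <- stats::runif(sum(type == "DEL"), 0.7, 1.2)
  dup_bad <- type == "DUP" & flavour == "bad_mshq"
  dh[dup_bad] <- stats::runif(sum(dup_bad), 1.4, 2.5)
  dup_pass <- type == "DUP" & flavour == "pass_all"
  dh[dup_pass] <- stats::runif(sum(dup_pass), 1.4, 2.5)
  bad_ms <- type != "DEL" & flavour == "bad_mshq"
  ms[bad_ms] <- stats::runif(sum(bad_ms), 0.5, 2.9)

  n_s <- ncol(x)
  in_batch <- sampleIds(x) %in% batchSamples
  gt <- matrix(0L, n_art, n_s, dimnames = list(NULL, sampleIds(x)))
  gt[, in_batch] <- sample(c(0L, 1L, 2L), n_art * sum(in_batch),
                           replace = TRUE, prob = c(0.1, 0.8, 0.1))
  gt[, !in_batch] <- sample(c(0L, 1L), n_art * sum(!in_batch),
                            replace = TRUE, prob = c(0.95, 0.05))
  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(start, width = len),
          svtype = type, svlen = as.numeric(len), dhffc = dh, mshq = ms,
          is_autosomal = TRUE, is_biallelic = TRUE)
  ids <- paste0("art", seq_len(n_art))
  names(gr) <- ids
  art <- SVCohort(gr, gt,
                  SummarizedExperiment::colData(x))
  combined <- SVCohort(
    c(gr0, gr),
    rbind(genotypes(x), genotypes(art)),
    SummarizedExperiment::colData(x))
  list(cohort = combined, artifact_ids = ids, batch_samples = batchSamples)
}

#' Simulate a pedigree-structured SV cohort with known truth
#'
#' Generates, deterministically for a given configuration:
#'
#' * per-locus derived allele frequencies from the class-specific Beta
#'   laws, with random ancestral orientation (REF or ALT ancestral);
#' * source-population, founder and immigrant genotypes under
#'   Hardy-Weinberg;
#' * an inbred population descending from three founders by gene dropping
#'   (full-sib lines by default, see [simulationConfig()]), with
#'   generation classes F1..Fn and immigrant offspring L1;
#' * gene models placed so that deleterious loci overlap coding sequence
#'   (partially, or enclosing a small gene when the variant is long) and
#'   neutral loci fall inside introns;
#' * a repeat annotation coupling the deletion length peak to SINE
#'   elements and the duplication peak to LINE elements;
#' * two outgroup individuals, homozygous ancestral at the configured
#'   fraction of loci and heterozygous/discordant/missing at the rest;
#' * injected low-quality artifact loci with batch-correlated genotypes
#'   ([injectArtifacts()]);
#' * genotyping errors and missingness applied to the emitted (not the
#'   truth) genotypes.
#'
#' @param config A [simulationConfig()].
#' @return A list of class `SimulatedCohort`:
#'   * `cohort`: [SVCohort-class] of observed genotypes (all loci
#'     including artifacts, all samples);
#'   * `truth`: list with `genotypes` (pre-error ALT dosage),
#'     `deleterious`, `ancestral`, `artifact`, `derived_freq` (per locus),
#'     `pedigree`, `batch_samples`;
#'   * `trios`: seven child/father/mother rows;
#'   * `sample_info`: per-sample metadata `data.frame`;
#'   * `geneModels`: [GeneModelSet-class]; `repeats`: repeat `GRanges`;
#'   * `outgroups`: 2 x loci matrix of outgroup ALT dosages.
#' @examples
#' sim <- simulateCohort(simulationConfig(n_loci_neutral = 50,
#'                                        n_loci_deleterious = 20, seed = 7))
#' sim$cohort
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n_del <- config$n_loci_deleterious
  n_neu <- config$n_loci_neutral
  L <- n_del + n_neu
  deleterious <- c(rep(TRUE, n_del), rep(FALSE, n_neu))

  type <- sample(names(config$sv_type_mix), L, replace = TRUE,
                 prob = config$sv_type_mix)
  len <- .simLengths(type, config$length_model)
  anc <- ifelse(stats::runif(L) < config$ref_ancestral_fraction,
                "REF", "ALT")
  p_der <- numeric(L)
  fp <- config$founder_freq_params_deleterious
  np <- config$founder_freq_params_neutral
  p_der[deleterious] <- stats::rbeta(n_del, fp[1], fp[2])
  p_der[!deleterious] <- stats::rbeta(n_neu, np[1], np[2])

  layout <- .simLayout(type, len, deleterious)

  ped <- .simPedigree(config)
  hw <- function(n) matrix(stats::rbinom(L * n, 2L, p_der), L, n)
  founder_ids <- ped$id[is.na(ped$father)]
  founder_der <- hw(length(founder_ids))
  colnames(founder_der) <- founder_ids
  der <- geneDrop(ped, founder_der)

  src_ids <- c(sprintf("FIN%02d", seq_len(config$n_source_finland)),
               sprintf("RUS%02d", seq_len(config$n_source_russia)))
  src_der <- hw(length(src_ids))
  colnames(src_der) <- src_ids

  der_all <- cbind(der, src_der)
  alt <- der_all
  flip <- anc == "ALT"
  alt[flip, ] <- 2L - alt[flip, , drop = FALSE]

  sample_info <- .simSampleInfo(ped, src_ids, config)
  sample_info$coverage <- pmax(stats::rnorm(nrow(sample_info), 28.4, 5), 8)
  alt <- alt[, sample_info$sample_id, drop = FALSE]

  dh <- rep(NA_real_, L)
  dh[type == "DEL"] <- stats::runif(sum(type == "DEL"), 0.15, 0.6)
  dh[type == "DUP"] <- stats::runif(sum(type == "DUP"), 1.4, 2.5)
  ms <- stats::runif(L, 3, 12)

  gr <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(layout$start, width = len),
          svtype = type, svlen = as.numeric(len), dhffc = dh, mshq = ms,
          is_autosomal = TRUE, is_biallelic = TRUE)
  names(gr) <- sprintf("sv%04d", seq_len(L))
  cohort <- SVCohort(gr, alt, sample_info)

  inj <- injectArtifacts(cohort, config)
  cohort <- inj$cohort
  n_all <- nrow(cohort)
  artifact <- c(rep(FALSE, L), rep(TRUE, n_all - L))
  truth_gt <- genotypes(cohort)

  # outgroups (ALT dosage); artifacts behave like unpolarizable junk
  og <- .simOutgroups(c(anc, rep("REF", n_all - L)),
                      c(rep(TRUE, L), rep(FALSE, n_all - L)),
                      config$polarizable_fraction)
  colnames(og) <- variantIds(cohort)

  obs <- .applyNoise(truth_gt, config$genotyping_error_rate,
                     config$missing_rate)
  SummarizedExperiment::assay(cohort, "GT") <- obs

  trios <- .simTrios(ped, config)
  structure(list(
    cohort = cohort,
    truth = list(genotypes = truth_gt, deleterious = c(deleterious,
                   rep(FALSE, n_all - L)),
                 ancestral = c(anc, rep(NA_character_, n_all - L)),
                 artifact = artifact,
                 derived_freq = c(p_der, rep(NA_real_, n_all - L)),
                 pedigree = ped, batch_samples = inj$batch_samples),
    trios = trios,
    sample_info = sample_info,
    geneModels = layout$geneModels,
    repeats = layout$repeats,
    outgroups = og),
    class = "SimulatedCohort")
}

.simLengths <- function(type, lm) {
  L <- length(type)
  len <- pmin(pmax(round(stats::rlnorm(L, lm$tail_meanlog, lm$tail_sdlog)),
                   lm$min_len), lm$max_len)
  peak <- stats::runif(L) < lm$peak_weight
  del_pk <- peak & type == "DEL"
  dup_pk <- peak & type == "DUP"
  len[del_pk] <- pmax(round(stats::rnorm(sum(del_pk), lm$del_peak,
                                         lm$peak_sd)), lm$min_len)
  len[dup_pk] <- pmax(round(stats::rnorm(sum(dup_pk), lm$dup_peak,
                                         lm$peak_sd)), lm$min_len)
  len
}

# gene/repeat layout: one 50 kb slot per locus on chr1.
# deleterious: compact gene, variant hits CDS (or, when long enough,
# a small gene fully inside the variant -> ENCLOSING).
# neutral: long-intron gene, variant strictly intronic.
.simLayout <- function(type, len, deleterious) {
  L <- length(type)
  o <- 50000 * (seq_len(L) - 1)
  start <- integer(L)
  g_lo <- integer(L); g_hi <- integer(L)
  # deleterious, long: variant encloses a small single-exon gene
  encl <- deleterious & len >= 1500
  start[encl] <- o[encl] + 8000
  g_lo[encl] <- start[encl] + 100
  g_hi[encl] <- start[encl] + len[encl] - 100
  # deleterious, short: variant partially covers exon 2 of a 5-exon gene
  part <- deleterious & !encl
  start[part] <- o[part] + 10150
  g_lo[part] <- o[part] + 5000
  g_hi[part] <- o[part] + 24999
  # neutral: variant deep in the single long intron
  neu <- !deleterious
  start[neu] <- o[neu] + 15000
  g_lo[neu] <- o[neu] + 2000
  g_hi[neu] <- o[neu] + 45000

  cds_gene <- c(which(encl),
                rep(which(part), each = 5),
                rep(which(neu), each = 2))
  cds_lo <- c(g_lo[encl],
              as.vector(t(outer(o[part] + 6000, 4000 * (0:4), "+"))),
              as.vector(rbind(g_lo[neu], g_hi[neu] - 300)))
  cds_hi <- c(pmin(g_lo[encl] + 199, g_hi[encl]),
              as.vector(t(outer(o[part] + 6299, 4000 * (0:4), "+"))),
              as.vector(rbind(g_lo[neu] + 299, g_hi[neu] - 1)))
  cds_flat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(cds_lo, cds_hi))
  cds <- S4Vectors::split(cds_flat, factor(cds_gene, levels = seq_len(L)))
  gene_gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(g_lo, g_hi))
  names(gene_gr) <- sprintf("gene%04d", seq_len(L))

  # repeat coupling for the length peaks; background repeats elsewhere
  end_ <- start + len - 1
  is_sine <- type == "DEL" & len >= 180 & len <= 200
  is_line <- type == "DUP" & len >= 140 & len <= 180
  bg <- !is_sine & !is_line & (seq_len(L) %% 5 == 0)
  rep_start <- c(start[is_sine], start[is_line], start[bg])
  rep_end <- c(end_[is_sine], end_[is_line],
               start[bg] + pmax(1L, floor(len[bg] / 2)) - 1L)
  rep_cls <- c(rep("SINE", sum(is_sine)), rep("LINE", sum(is_line)),
               c("LTR", "DNA", "Simple", "Unknown")[
                 (which(bg) / 5) %% 4 + 1])
  repeats <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(rep_start, rep_end), repeat_class = rep_cls)
  list(start = start,
       geneModels = GeneModelSet(gene_gr, cds),
       repeats = repeats)
}

.simPedigree <- function(config) {
  n_gen <- config$n_generations
  n_lines <- config$lines_per_generation
  off <- config$offspring_per_pair
  ped <- data.frame(id = c("FND1", "FND2", "FND3"),
                    father = NA_character_, mother = NA_character_,
                    sex = c("M", "F", "M"), generation = 0L,
                    class = NA_character_, stringsAsFactors = FALSE)
  # generation 1: founder pairs (FND1 x FND2), (FND3 x FND2), cycling
  prev <- list()
  for (ln in seq_len(n_lines)) {
    fa <- if (ln %% 2 == 1) "FND1" else "FND3"
    ids <- sprintf("F1_L%d_%02d", ln, seq_len(off))
    ped <- rbind(ped, data.frame(id = ids, father = fa, mother = "FND2",
                                 sex = rep_len(c("M", "F"), off),
                                 generation = 1L, class = "F1",
                                 stringsAsFactors = FALSE))
    prev[[ln]] <- ids
  }
  for (g in 2:n_gen) {
    if (n_gen < 2) break
    cur <- list()
    all_prev <- unlist(prev)
    for (ln in seq_len(n_lines)) {
      pool <- if (config$mating == "sibline") prev[[ln]] else all_prev
      sexes <- ped$sex[match(pool, ped$id)]
      fa <- sample(pool[sexes == "M"], 1)
      mo <- sample(pool[sexes == "F"], 1)
      ids <- sprintf("F%d_L%d_%02d", g, ln, seq_len(off))
      ped <- rbind(ped, data.frame(id = ids, father = fa, mother = mo,
                                   sex = rep_len(c("M", "F"), off),
                                   generation = g, class = paste0("F", g),
                                   stringsAsFactors = FALSE))
      cur[[ln]] <- ids
    }
    prev <- cur
  }
  # immigrants breed with individuals of immigrant_generation
  ig <- config$immigrant_generation
  mates <- ped$id[ped$generation == ig & ped$sex == "F"]
  for (k in seq_len(config$n_immigrants_reproducing)) {
    imm <- sprintf("IMR%d", k)
    ped <- rbind(ped, data.frame(id = imm, father = NA_character_,
                                 mother = NA_character_, sex = "M",
                                 generation = NA_integer_,
                                 class = NA_character_,
                                 stringsAsFactors = FALSE))
    mo <- mates[(k - 1) %% length(mates) + 1]
    ids <- sprintf("L1_I%d_%02d", k, seq_len(config$offspring_per_immigrant))
    ped <- rbind(ped, data.frame(id = ids, father = imm, mother = mo,
                                 sex = rep_len(c("M", "F"),
                                               config$offspring_per_immigrant),
                                 generation = ig + 1L, class = "L1",
                                 stringsAsFactors = FALSE))
  }
  for (k in seq_len(config$n_immigrants_nonreproducing)) {
    ped <- rbind(ped, data.frame(id = sprintf("IMN%d", k),
                                 father = NA_character_,
                                 mother = NA_character_, sex = "M",
                                 generation = NA_integer_,
                                 class = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  ped
}

.simSampleInfo <- function(ped, src_ids, config) {
  pop <- character(nrow(ped))
  pop[grepl("^FND", ped$id)] <- "FOUNDER"
  pop[grepl("^F\\d", ped$id)] <- "SCAND_ORIGINAL"
  pop[grepl("^L1_", ped$id)] <- "SCAND_IMMIGRANT_DESC"
  pop[grepl("^IMR", ped$id)] <- "IMMIGRANT_R"
  pop[grepl("^IMN", ped$id)] <- "IMMIGRANT_NR"
  df <- data.frame(sample_id = ped$id, population = pop,
                   generation_class = ped$class, sex = ped$sex,
                   father = ped$father, mother = ped$mother,
                   stringsAsFactors = FALSE)
  src <- data.frame(sample_id = src_ids,
                    population = ifelse(grepl("^FIN", src_ids),
                                        "FINLAND", "RUSSIA"),
                    generation_class = NA_character_, sex = NA_character_,
                    father = NA_character_, mother = NA_character_,
                    stringsAsFactors = FALSE)
  rbind(df, src)
}

.simTrios <- function(ped, config) {
  last <- max(ped$generation, na.rm = TRUE)
  f_children <- ped$id[!is.na(ped$class) & ped$class == paste0("F", last)]
  l_children <- ped$id[!is.na(ped$class) & ped$class == "L1"]
  kids <- c(utils::head(f_children, 5), utils::head(l_children, 2))
  kids <- kids[!is.na(kids)]
  data.frame(child = kids,
             father = ped$father[match(kids, ped$id)],
             mother = ped$mother[match(kids, ped$id)],
             stringsAsFactors = FALSE)
}

.simOutgroups <- function(anc, polarizable_eligible, polarizable_fraction) {
  L <- length(anc)
  hom_anc <- ifelse(anc == "ALT", 2L, 0L)
  og <- matrix(NA_integer_, 2, L, dimnames = list(c("OUT1", "OUT2"), NULL))
  polarizable <- polarizable_eligible &
    stats::runif(L) < polarizable_fraction
  og[1, polarizable] <- hom_anc[polarizable]
  og[2, polarizable] <- hom_anc[polarizable]
  rest <- which(!polarizable)
  mode <- sample(c("discordant", "het", "missing"), length(rest),
                 replace = TRUE)
  og[1, rest[mode == "discordant"]] <- 0L
  og[2, rest[mode == "discordant"]] <- 2L
  og[1, rest[mode == "het"]] <- 1L
  og[2, rest[mode == "het"]] <- hom_anc[rest[mode == "het"]]
  og[1, rest[mode == "missing"]] <- NA_integer_
  og[2, rest[mode == "missing"]] <- hom_anc[rest[mode == "missing"]]
  og
}

.applyNoise <- function(gt, error_rate, missing_rate) {
  if (error_rate > 0) {
    err <- which(matrix(stats::runif(length(gt)) < error_rate, nrow(gt)))
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      gt[err] <- (gt[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0)
    gt[matrix(stats::runif(length(gt)) < missing_rate, nrow(gt))] <-
      NA_integer_
  storage.mode(gt) <- "integer"
  gt
}

#' Truth-based curation decisions for a simulated cohort
#'
#' `ACCEPT` for every true locus, `REJECT` for every injected artifact —
#' the decision file a perfectly accurate curator would produce.
#'
#' @param sim A `SimulatedCohort` from [simulateCohort()].
#' @return A `data.frame` with `variant_id` and `decision`.
#' @export
truthDecisions <- function(sim) {
  data.frame(variant_id = variantIds(sim$cohort),
             decision = ifelse(sim$truth$artifact, "REJECT", "ACCEPT"),
             stringsAsFactors = FALSE)
}

#' Write all simulated inputs to a directory
#'
#' Emits exactly the formats the readers consume: `cohort.vcf`,
#' `outgroups.vcf`, `samples.tsv`, `trios.tsv`, `genes.gff3`,
#' `repeats.bed`, `decisions.tsv` (truth-based) and `truth.tsv`.
#'
#' @param sim A `SimulatedCohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSVVcf(sim$cohort, file.path(dir, "cohort.vcf"))
  og <- SVCohort(SummarizedExperiment::rowRanges(sim$cohort),
                 t(sim$outgroups))
  writeSVVcf(og, file.path(dir, "outgroups.vcf"))
  writeTsv(sim$sample_info, file.path(dir, "samples.tsv"))
  writeTsv(sim$trios, file.path(dir, "trios.tsv"))
  writeGeneModelsGff3(sim$geneModels, file.path(dir, "genes.gff3"))
  writeRepeatsBed(sim$repeats, file.path(dir, "repeats.bed"))
  writeTsv(truthDecisions(sim), file.path(dir, "decisions.tsv"))
  writeTsv(data.frame(variant_id = variantIds(sim$cohort),
                      deleterious = sim$truth$deleterious,
                      ancestral = sim$truth$ancestral,
                      artifact = sim$truth$artifact,
                      derived_freq = sim$truth$derived_freq),
           file.path(dir, "truth.tsv"))
  invisible(dir)
}
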