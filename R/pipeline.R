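#' Run the full SV analysis pipeline
#'
#' Orchestrates the fixed stage order
#' simulate/read -> filter -> validate -> annotate -> load, writing
#' per-stage TSV outputs and a machine-readable run summary.  In
#' self-test mode (`simulate = TRUE`, the default when no VCF path is
#' given) the inputs are generated by [simulateCohort()], written to disk
#' in their standard formats, and read back through the same readers used
#' for real data, so the whole I/O surface is exercised.
#'
#' Every output TSV starts with comment lines recording the package
#' version, a hash of the configuration and the seed; the run summary
#' (`run_summary.yaml`) contains per-stage locus counts and headline
#' statistics.  A failing stage aborts with an error naming the stage.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   * `out_dir` (required): output directory;
#'   * `simulate`: logical, self-test mode (default `TRUE` when no
#'     `vcf` entry is present);
#'   * `simulation`: arguments for [simulationConfig()] (self-test mode);
#'   * `vcf`, `samples`, `pedigree`, `genes`, `repeats`, `outgroups`,
#'     `decisions`: input paths (real-data mode; `decisions` optional);
#'   * `thresholds`: arguments for [filterThresholds()];
#'   * `pca_components` (default 20), `min_called` (default 5);
#'   * `sfs_samples`: sample ids for the SFS panel (default: source
#'     populations + immigrants + founder female, mirroring an unrelated
#'     set);
#'   * `seed`: integer (default 1).
#' @return Invisibly, a list with the run summary and the main result
#'   objects (`filter`, `trios`, `pca`, `overlap`, `polarized`, `sfs`,
#'   `loads`, `group_loads`, `rescue`).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stamp <- .runStamp(config, seed)
  summary <- list(package = "svload",
                  version = as.character(utils::packageVersion("svload")),
                  seed = seed, config_hash = stamp$hash)
  simulate <- if (!is.null(config$simulate)) isTRUE(config$simulate)
    else is.null(config$vcf)

  inputs <- .stage("simulate", {
    if (simulate) {
      sim_args <- config$simulation
      sim_args$seed <- seed
      sim <- simulateCohort(do.call(simulationConfig, as.list(sim_args)))
      in_dir <- file.path(config$out_dir, "inputs")
      writeCohort(sim, in_dir)
      list(dir = in_dir, decisions = file.path(in_dir, "decisions.tsv"))
    } else {
      list(vcf = config$vcf, samples = config$samples,
           pedigree = config$pedigree, genes = config$genes,
           repeats = config$repeats, outgroups = config$outgroups,
           decisions = config$decisions)
    }
  })
  if (simulate)
    inputs <- c(inputs, list(
      vcf = file.path(inputs$dir, "cohort.vcf"),
      samples = file.path(inputs$dir, "samples.tsv"),
      pedigree = file.path(inputs$dir, "trios.tsv"),
      genes = file.path(inputs$dir, "genes.gff3"),
      repeats = file.path(inputs$dir, "repeats.bed"),
      outgroups = file.path(inputs$dir, "outgroups.vcf")))

  for (f in c("vcf", "samples", "pedigree", "genes", "repeats",
              "outgroups"))
    if (!file.exists(inputs[[f]]))
      stop("stage read failed: missing input file '", inputs[[f]], "'")

  read <- .stage("read", {
    cohort <- readSVVcf(inputs$vcf)
    list(cohort = cohort,
         sample_info = readSampleInfo(inputs$samples, cohort),
         trios = readPedigree(inputs$pedigree, cohort),
         genes = readGeneModels(inputs$genes),
         repeats = readRepeats(inputs$repeats),
         outgroups = t(genotypes(readSVVcf(inputs$outgroups))),
         decisions = if (!is.null(inputs$decisions) &&
                           file.exists(inputs$decisions))
           readCurationDecisions(inputs$decisions) else NULL)
  })

  filt <- .stage("filter", {
    thr <- do.call(filterThresholds, as.list(config$thresholds))
    filterCascade(read$cohort, thr, read$decisions)
  })
  .writeStamped(filt$report, file.path(config$out_dir, "filter_report.tsv"),
                stamp)
  summary$filter <- stats::setNames(
    as.list(filt$report$Total),
    filt$report$stage)

  val <- .stage("validate", {
    pcs <- if (is.null(config$pca_components)) 20 else config$pca_components
    list(trios = trioConcordance(filt$cohort, read$trios),
         pca = pcaGenotypes(filt$cohort, pcs))
  })
  .writeStamped(val$trios, file.path(config$out_dir, "trio_concordance.tsv"),
                stamp)
  .writeStamped(data.frame(sample_id = rownames(val$pca$scores),
                           val$pca$scores),
                file.path(config$out_dir, "pca_scores.tsv"), stamp)
  summary$mean_trio_concordance <- mean(val$trios$concordance, na.rm = TRUE)

  ann <- .stage("annotate", {
    overlap <- classifyGeneOverlap(filt$cohort, read$genes)
    polarized <- polarize(filt$cohort,
                          read$outgroups[, variantIds(filt$cohort),
                                         drop = FALSE])
    list(overlap = overlap, polarized = polarized,
         composition = repeatComposition(filt$cohort, read$repeats))
  })
  .writeStamped(merge(ann$overlap, ann$polarized, by = "variant_id"),
                file.path(config$out_dir, "annotation.tsv"), stamp)
  summary$overlap_categories <- as.list(table(ann$overlap$category))
  summary$polarized_fraction <-
    mean(ann$polarized$ancestral != "UNPOLARIZED")

  loads <- .stage("load", {
    si <- read$sample_info
    sfs_samples <- config$sfs_samples
    if (is.null(sfs_samples))
      sfs_samples <- si$sample_id[si$population %in%
        c("FINLAND", "RUSSIA", "IMMIGRANT_R", "IMMIGRANT_NR") |
        (si$population == "FOUNDER" & !is.na(si$sex) & si$sex == "F")]
    sfs_samples <- intersect(sfs_samples, sampleIds(read$cohort))
    # SFS on the pre-genotype-frequency set to keep rare variants
    pre_gf <- applyQualityFilters(read$cohort,
      do.call(filterThresholds, as.list(config$thresholds)))$cohort
    pol_pre <- polarize(pre_gf,
                        read$outgroups[, variantIds(pre_gf), drop = FALSE])
    ov_pre <- classifyGeneOverlap(pre_gf, read$genes)
    sfs_del <- buildSFS(pre_gf, pol_pre, ov_pre, sfs_samples,
                        "DELETERIOUS", svtypes = "DEL",
                        lengthWindow = c(50, 10000))
    sfs_neu <- buildSFS(pre_gf, pol_pre, ov_pre, sfs_samples,
                        "NEUTRAL", svtypes = "DEL",
                        lengthWindow = c(50, 10000))
    gof <- tryCatch(sfsGofTest(sfs_del, sfs_neu),
                    error = function(e) list(statistic = NA_real_,
                                             df = NA, p.value = NA_real_))
    ind <- individualLoad(filt$cohort, ann$polarized, ann$overlap)
    grp <- loadByGroup(ind, si)
    # fixation is assessed in the latest pre-immigration generations
    # (alleles drifted to fixation by then); the founder-fixed rule uses
    # the whole original population
    pre_ids <- config$pre_samples
    if (is.null(pre_ids)) {
      fgen <- grep("^F\\d+$", unique(si$generation_class), value = TRUE)
      late <- utils::tail(fgen[order(as.integer(sub("F", "", fgen)))], 2)
      pre_ids <- si$sample_id[si$generation_class %in% late]
    }
    orig_ids <- si$sample_id[si$population %in%
                               c("FOUNDER", "SCAND_ORIGINAL")]
    post_ids <- config$post_samples
    if (is.null(post_ids))
      post_ids <- si$sample_id[si$population == "SCAND_IMMIGRANT_DESC"]
    minc <- if (is.null(config$min_called)) 5 else config$min_called
    rescue <- if (length(pre_ids) && length(post_ids))
      fixationAndRescue(filt$cohort, ann$polarized,
                        intersect(pre_ids, sampleIds(filt$cohort)),
                        intersect(post_ids, sampleIds(filt$cohort)),
                        intersect(orig_ids, sampleIds(filt$cohort)),
                        minCalled = minc) else NULL
    list(sfs_del = sfs_del, sfs_neu = sfs_neu, gof = gof, individual = ind,
         by_group = grp, rescue = rescue)
  })
  .writeStamped(loads$individual,
                file.path(config$out_dir, "individual_load.tsv"), stamp)
  .writeStamped(loads$by_group,
                file.path(config$out_dir, "load_by_group.tsv"), stamp)
  .writeStamped(data.frame(bin_lo = utils::head(loads$sfs_del$bin_edges, -1),
                           bin_hi = utils::tail(loads$sfs_del$bin_edges, -1),
                           deleterious = loads$sfs_del$counts,
                           neutral = loads$sfs_neu$counts),
                file.path(config$out_dir, "sfs.tsv"), stamp)
  summary$sfs_gof_p <- loads$gof$p.value
  if (!is.null(loads$rescue)) {
    .writeStamped(data.frame(
      n_fixed_pre = loads$rescue$n_fixed_pre,
      n_regained = loads$rescue$n_regained,
      n_founder_fixed = loads$rescue$n_founder_fixed,
      n_founder_regained = loads$rescue$n_founder_regained),
      file.path(config$out_dir, "rescue.tsv"), stamp)
    summary$rescue <- loads$rescue[c("n_fixed_pre", "n_regained",
                                     "n_founder_fixed",
                                     "n_founder_regained")]
  }
  yaml::write_yaml(summary, file.path(config$out_dir, "run_summary.yaml"))
  invisible(list(summary = summary, filter = filt, trios = val$trios,
                 pca = val$pca, overlap = ann$overlap,
                 polarized = ann$polarized, sfs = loads[c("sfs_del",
                                                          "sfs_neu", "gof")],
                 loads = loads$individual, group_loads = loads$by_group,
                 rescue = loads$rescue))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

# polynomial rolling hash over the serialized configuration: cheap, stable
# run identifier (kept below 2^31 so integer arithmetic stays exact)
.confHash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.runStamp <- function(config, seed) {
  hash <- .confHash(paste(utils::capture.output(utils::str(config)),
                          collapse = "\n"))
  list(hash = hash, seed = seed,
       header = c(
         paste0("# svload ", utils::packageVersion("svload")),
         paste0("# config_hash=", hash, " seed=", seed)))
}

.writeStamped <- function(df, path, stamp) {
  con <- file(path, "w")
  writeLines(stamp$header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}
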