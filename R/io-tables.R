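#' Read sample metadata
#'
#' Tab-separated table with a header; required columns `sample_id` and
#' `population`, optional `generation_class` (F1..F6 / L1..L3 for
#' population-born individuals), `coverage` and pedigree links.  Sample ids
#' must be unique and, when a cohort is supplied, match its samples.
#'
#' @param path Path to a TSV file.
#' @param cohort Optional [SVCohort-class] used for referential-integrity
#'   checks.
#' @return A `data.frame` of sample metadata.
#' @export
readSampleInfo <- function(path, cohort = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  if (!is.null(cohort)) .checkSampleIds(df$sample_id, cohort)
  if (!"generation_class" %in% colnames(df)) df$generation_class <- NA_character_
  df$generation_class[df$generation_class %in% c("", "NA")] <- NA_character_
  df
}

#' Read a pedigree / trio table
#'
#' Tab-separated with header columns `child`, `father`, `mother`.  All three
#' ids per row must be distinct and present in the cohort (or supplied
#' sample-id vector).
#'
#' @param path Path to a TSV file.
#' @param cohort An [SVCohort-class] or a character vector of valid sample
#'   ids (optional).
#' @return A `data.frame` of trios.
#' @export
readPedigree <- function(path, cohort = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("child", "father", "mother")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("pedigree table lacks column(s): ", paste(miss, collapse = ", "))
  same <- df$child == df$father | df$child == df$mother |
    df$father == df$mother
  if (any(same))
    stop("trio with non-distinct ids: ", df$child[which(same)[1]])
  if (!is.null(cohort))
    .checkSampleIds(unique(unlist(df[need])), cohort)
  df
}

.checkSampleIds <- function(ids, cohort) {
  valid <- if (methods::is(cohort, "SVCohort")) sampleIds(cohort) else cohort
  unknown <- setdiff(ids, valid)
  if (length(unknown))
    stop("sample id(s) not in cohort: ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Read a curation decision file
#'
#' Tab-separated with header columns `variant_id` and `decision`
#' (`ACCEPT` or `REJECT`), as produced by an image-review round (samplot /
#' plotcritic style scoring externalized to a file).  Duplicate decisions
#' for one variant are an error.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with columns `variant_id`, `decision`.
#' @export
readCurationDecisions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "decision")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("decision table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$variant_id))
    stop("duplicate decision for variant(s): ",
         paste(unique(df$variant_id[duplicated(df$variant_id)]),
               collapse = ", "))
  bad <- setdiff(unique(df$decision), c("ACCEPT", "REJECT"))
  if (length(bad))
    stop("unknown decision value(s): ", paste(bad, collapse = ", "))
  df
}

#' Write simple TSV tables (samples, trios, decisions, truth)
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
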