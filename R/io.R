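# Readers and writers for the pipeline's tabular interchange formats.
# Delimiters are auto-detected (comma or tab); numeric round trips are
# lossless at full double precision via readr.

detect_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a transition-level peak-area table
#'
#' Reads a long-form transition export (one row per transition per run)
#' with mandatory columns `protein`, `peptide`, `transition`, `subject`,
#' `replicate`, `intensity`. The delimiter (comma or tab) is detected from
#' the header; unknown columns are preserved.
#'
#' @param path File path.
#' @return Transition table (tibble) on the raw intensity scale.
#' @export
read_transition_table <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  assert_columns(df, transition_cols, what = path)
  df$replicate <- as.integer(df$replicate)
  dup <- df |>
    dplyr::count(.data$transition, .data$subject, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate rows for transition %s in run %s",
                 dup$transition[1], run_id(dup$subject[1],
                                           dup$replicate[1])),
         call. = FALSE)
  }
  set_transition_scale(df, "raw")
}

#' Write a transition table
#' @param transitions Transition table.
#' @param path Output path (`.tsv` extension writes tab-delimited).
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(transitions, path) {
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(transitions, path)
  invisible(path)
}

#' Read / write a protein eigengene matrix
#'
#' The on-disk layout is one row per protein with subjects in columns.
#' @param path File path.
#' @return Tibble with `protein` column followed by subject columns.
#' @export
read_protein_matrix <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  assert_columns(df, "protein", what = path)
  df
}

#' @rdname read_protein_matrix
#' @param protein_matrix Tibble from [summarize_proteins()].
#' @export
write_protein_matrix <- function(protein_matrix, path) {
  readr::write_csv(protein_matrix, path)
  invisible(path)
}

#' Read / write a tidy ROI table
#'
#' Accepts either the tidy layout (`subject`, `roi`, `metric`, `value`) or
#' a wide layout with one `roi@metric` column per cell, which is pivoted.
#' @param path File path.
#' @return Tidy ROI tibble.
#' @export
read_roi_table <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  if (!all(roi_cols %in% names(df))) {
    assert_columns(df, "subject", what = path)
    df <- tidyr::pivot_longer(df, -"subject",
                              names_to = c("roi", "metric"), names_sep = "@",
                              values_to = "value")
  }
  df[, roi_cols]
}

#' @rdname read_roi_table
#' @param roi_data Tidy ROI tibble.
#' @export
write_roi_table <- function(roi_data, path) {
  readr::write_csv(roi_data[, roi_cols], path)
  invisible(path)
}

#' Read / write a cohort covariate table
#' @param path File path.
#' @return Cohort tibble with `group` as a factor (Control, MA, MAP) and
#'   `gender` as a factor (F, M).
#' @export
read_cohort_table <- function(path) {
  df <- readr::read_delim(path, delim = detect_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("subject", "group"), what = path)
  df$group <- factor(df$group, levels = c("Control", "MA", "MAP"))
  if ("gender" %in% names(df)) {
    df$gender <- factor(df$gender, levels = c("F", "M"))
  }
  df
}

#' @rdname read_cohort_table
#' @param cohort Cohort tibble.
#' @export
write_cohort_table <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits the four interchange tables (`transitions.csv`, `cohort.csv`,
#' `roi.csv`, `psychometrics.csv`) plus `ground_truth.json`.
#'
#' @param cohort_data `srmdti_cohort` object from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort_data, dir) {
  stopifnot(inherits(cohort_data, "srmdti_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transition_table(cohort_data$transitions,
                         file.path(dir, "transitions.csv"))
  write_cohort_table(cohort_data$cohort, file.path(dir, "cohort.csv"))
  write_roi_table(cohort_data$roi, file.path(dir, "roi.csv"))
  readr::write_csv(cohort_data$psychometrics,
                   file.path(dir, "psychometrics.csv"))
  truth <- cohort_data$truth
  truth$protein_signals <- NULL  # tabular truth kept small; signals are wide
  readr::write_csv(cohort_data$truth$protein_signals,
                   file.path(dir, "protein_signals.csv"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
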