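# Transition-level SRM preprocessing: log2 transform, between-run median
# normalization, interference and CV filters, eigengene summarisation and
# subject-level outlier screening.
#
# Stage order is enforced through table attributes: log2 -> normalize ->
# interference filter -> CV filter -> eigengene. Re-running the transform
# on its own output is rejected; normalization is idempotent.

transition_cols <- c("protein", "peptide", "transition", "subject",
                     "replicate", "intensity")

#' Impute missing transition intensities
#'
#' Transitions absent (or NA) in more than `max_missing_fraction` of runs
#' are dropped; the remaining missing values are imputed as the run's
#' peptide mean on the current intensity scale. Every action is recorded in
#' the attached `imputation_log` attribute.
#'
#' @param transitions Transition table (long form).
#' @param max_missing_fraction Drop threshold on the per-transition missing
#'   run fraction (default 0.2).
#' @return The completed transition table with attribute `imputation_log`
#'   (tibble of dropped transitions and imputed cells).
#' @export
impute_missing <- function(transitions, max_missing_fraction = 0.2) {
  assert_columns(transitions, transition_cols)
  full <- tidyr::expand_grid(
    dplyr::distinct(transitions, .data$protein, .data$peptide,
                    .data$transition),
    dplyr::distinct(transitions, .data$subject, .data$replicate)
  ) |>
    dplyr::left_join(transitions,
                     by = c("protein", "peptide", "transition", "subject",
                            "replicate"))
  n_runs <- nrow(dplyr::distinct(full, .data$subject, .data$replicate))
  miss <- full |>
    dplyr::group_by(.data$transition) |>
    dplyr::summarise(missing_fraction = mean(is.na(.data$intensity)),
                     .groups = "drop")
  dropped <- miss$transition[miss$missing_fraction > max_missing_fraction]
  full <- dplyr::filter(full, !.data$transition %in% dropped)
  imputed <- full |>
    dplyr::group_by(.data$peptide, .data$subject, .data$replicate) |>
    dplyr::mutate(.pepmean = mean(.data$intensity, na.rm = TRUE)) |>
    dplyr::ungroup()
  cells <- imputed |>
    dplyr::filter(is.na(.data$intensity)) |>
    dplyr::select("transition", "subject", "replicate",
                  imputed_value = ".pepmean")
  if (any(is.na(cells$imputed_value))) {
    bad <- cells[is.na(cells$imputed_value), ]
    stop(sprintf(
      "cannot impute transition %s in run %s: whole peptide missing",
      bad$transition[1], run_id(bad$subject[1], bad$replicate[1])),
      call. = FALSE)
  }
  out <- imputed |>
    dplyr::mutate(intensity = dplyr::coalesce(.data$intensity,
                                              .data$.pepmean)) |>
    dplyr::select(dplyr::all_of(transition_cols))
  out <- set_transition_scale(out, transition_scale(transitions))
  attr(out, "imputation_log") <- list(
    dropped_transitions = dropped,
    imputed_cells = cells,
    n_runs = n_runs
  )
  out
}

#' Log2-transform transition intensities
#'
#' Replaces every peak area by its base-2 logarithm to stabilise variance.
#' Record structure is unchanged. Non-positive intensities are rejected
#' with a record-identifying message; tables already on the log2 scale are
#' rejected (the transform is not meant to be applied twice).
#'
#' @param transitions Raw-scale transition table.
#' @return The table with `intensity` on the log2 scale.
#' @export
log2_transform <- function(transitions) {
  assert_columns(transitions, transition_cols)
  if (transition_scale(transitions) == "log2") {
    stop("transition table is already log2-transformed", call. = FALSE)
  }
  bad <- which(!is.finite(transitions$intensity) | transitions$intensity <= 0)
  if (length(bad) > 0) {
    b <- transitions[bad[1], ]
    stop(sprintf(
      "non-positive intensity for transition %s, run %s (%d offending rows)",
      b$transition, run_id(b$subject, b$replicate), length(bad)),
      call. = FALSE)
  }
  transitions$intensity <- log2(transitions$intensity)
  set_transition_scale(transitions, "log2")
}

#' Equalize run medians
#'
#' Removes systematic between-run bias by shifting every run (one
#' subject-by-replicate injection) so that its median log2 intensity equals
#' the global median of run medians. Rank order within each run is
#' preserved and the operation is idempotent.
#'
#' @param transitions Log2-scale transition table.
#' @return Normalized table (attribute `srm_normalized` set); the per-run
#'   shifts are attached as attribute `run_shifts`.
#' @export
normalize_runs <- function(transitions) {
  assert_columns(transitions, transition_cols)
  if (transition_scale(transitions) != "log2") {
    stop("normalize_runs expects a log2-scale table; run log2_transform first",
         call. = FALSE)
  }
  usable <- dplyr::filter(transitions, is.finite(.data$intensity))
  runs_all <- dplyr::distinct(transitions, .data$subject, .data$replicate)
  runs_ok <- dplyr::distinct(usable, .data$subject, .data$replicate)
  empty <- dplyr::anti_join(runs_all, runs_ok, by = c("subject", "replicate"))
  if (nrow(empty) > 0) {
    stop(sprintf("run %s has no usable transitions",
                 run_id(empty$subject[1], empty$replicate[1])), call. = FALSE)
  }
  med <- usable |>
    dplyr::group_by(.data$subject, .data$replicate) |>
    dplyr::summarise(run_median = median(.data$intensity), .groups = "drop")
  target <- median(med$run_median)
  med$shift <- target - med$run_median
  out <- transitions |>
    dplyr::left_join(med, by = c("subject", "replicate")) |>
    dplyr::mutate(intensity = .data$intensity + .data$shift) |>
    dplyr::select(dplyr::all_of(transition_cols))
  out <- set_transition_scale(out, "log2")
  attr(out, "srm_normalized") <- TRUE
  attr(out, "run_shifts") <- dplyr::select(med, "subject", "replicate",
                                           "run_median", "shift")
  out
}

# Interference scores for every transition: the Pearson correlation, across
# runs, between a transition's log2 intensity and the per-run mean of its
# peptide's other transitions (leave-one-out reference). Peptides with a
# single transition have no reference and score NA.
compute_interference_scores <- function(transitions) {
  dat <- transitions |>
    dplyr::group_by(.data$peptide, .data$subject, .data$replicate) |>
    dplyr::mutate(.n_pep = dplyr::n(),
                  .loo_mean = (sum(.data$intensity) - .data$intensity) /
                    pmax(.data$.n_pep - 1, 1)) |>
    dplyr::ungroup()
  dat |>
    dplyr::group_by(.data$protein, .data$peptide, .data$transition) |>
    dplyr::summarise(
      n_runs = sum(is.finite(.data$intensity) & is.finite(.data$.loo_mean)),
      score = {
        has_ref <- all(.data$.n_pep >= 2)
        if (!has_ref) {
          NA_real_
        } else if (dplyr::n() < 3) {
          stop("interference score needs at least 3 paired runs",
               call. = FALSE)
        } else if (sd(.data$intensity) == 0 || sd(.data$.loo_mean) == 0) {
          0  # zero-variance series: fail-safe worst score
        } else {
          cor(.data$intensity, .data$.loo_mean)
        }
      },
      .groups = "drop"
    )
}

#' Between-run interference score of one transition
#'
#' Correlation, across runs, between the transition's log2 intensity and
#' the per-run mean intensity of the other transitions of the same peptide.
#' Transitions tracking their peptide's consensus profile score near 1;
#' interfered transitions (coeluting contaminant signal uncorrelated with
#' the peptide) score low. A zero-variance series yields a defined score of
#' 0 (fail-safe: such transitions are excluded downstream).
#'
#' @param transitions Normalized log2-scale transition table.
#' @param transition Transition identifier.
#' @return A single correlation in `[-1, 1]`.
#' @export
interference_score <- function(transitions, transition) {
  assert_columns(transitions, transition_cols)
  row <- transitions[transitions$transition == transition, ]
  if (nrow(row) == 0) stop("unknown transition: ", transition, call. = FALSE)
  pep <- transitions[transitions$peptide == row$peptide[1], ]
  if (dplyr::n_distinct(pep$transition) < 2) {
    stop(sprintf("peptide %s has a single transition; no reference profile",
                 row$peptide[1]), call. = FALSE)
  }
  n_runs <- nrow(dplyr::distinct(pep, .data$subject, .data$replicate))
  if (n_runs < 3) {
    stop("interference score needs at least 3 paired runs", call. = FALSE)
  }
  scores <- compute_interference_scores(pep)
  scores$score[scores$transition == transition]
}

#' Exclude transitions with between-run interference
#'
#' Removes every transition whose interference score falls below
#' `threshold` (default 0.8). Single-transition peptides have no reference
#' and are retained with an NA score. Peptides or proteins losing all
#' transitions are recorded in the report.
#'
#' @param transitions Normalized log2-scale transition table.
#' @param threshold Exclusion threshold on the score (default 0.8).
#' @return List with `transitions` (filtered table) and `report` (tibble of
#'   per-transition scores with an `excluded` flag, plus attributes
#'   `dropped_peptides` / `dropped_proteins`).
#' @export
filter_interference <- function(transitions, threshold = 0.8) {
  assert_columns(transitions, transition_cols)
  if (!is_normalized(transitions)) {
    stop("filter_interference expects a normalized table; run normalize_runs",
         call. = FALSE)
  }
  if (isTRUE(attr(transitions, "srm_interference_filtered"))) {
    stop("interference filter has already been applied to this table",
         call. = FALSE)
  }
  scores <- compute_interference_scores(transitions)
  scores$excluded <- !is.na(scores$score) & scores$score < threshold
  keep <- scores$transition[!scores$excluded]
  out <- dplyr::filter(transitions, .data$transition %in% keep)
  dropped_pep <- setdiff(unique(transitions$peptide), unique(out$peptide))
  dropped_prot <- setdiff(unique(transitions$protein), unique(out$protein))
  if (length(dropped_prot) > 0) {
    warning("protein(s) lost all transitions to the interference filter: ",
            paste(dropped_prot, collapse = ", "), call. = FALSE)
  }
  out <- set_transition_scale(out, "log2")
  attr(out, "srm_normalized") <- TRUE
  attr(out, "run_shifts") <- attr(transitions, "run_shifts")
  attr(out, "srm_interference_filtered") <- TRUE
  report <- scores
  attr(report, "threshold") <- threshold
  attr(report, "dropped_peptides") <- dropped_pep
  attr(report, "dropped_proteins") <- dropped_prot
  list(transitions = out, report = report)
}

#' Exclude transitions with poor duplicate-injection repeatability
#'
#' For each transition and subject, the coefficient of variation (CV =
#' sd/mean) of the raw-scale (unlogged) replicate intensities is computed;
#' a transition is excluded when the fraction of subjects with CV above
#' `cv_threshold` exceeds `run_fraction` (default: over 10% CV in over 10%
#' of subjects). CV is a raw-scale repeatability measure, so on a
#' normalized table the per-run normalization shifts are undone before
#' back-transforming (otherwise the sampling noise of the run-median
#' estimates would contaminate every transition's CV).
#'
#' @param transitions Normalized log2-scale transition table with at least
#'   two injection replicates per subject.
#' @param cv_threshold Per-subject CV threshold (default 0.10).
#' @param run_fraction Maximum tolerated fraction of failing subjects
#'   (default 0.10).
#' @return List with `transitions` (filtered) and `report` (per-transition
#'   fail fractions with an `excluded` flag).
#' @export
cv_filter <- function(transitions, cv_threshold = 0.10, run_fraction = 0.10) {
  assert_columns(transitions, transition_cols)
  if (isTRUE(attr(transitions, "srm_cv_filtered"))) {
    stop("CV filter has already been applied to this table", call. = FALSE)
  }
  nrep <- transitions |>
    dplyr::count(.data$transition, .data$subject) |>
    dplyr::pull(.data$n)
  if (any(nrep < 2)) {
    stop("CV filtering requires duplicate injections for every subject",
         call. = FALSE)
  }
  on_log2 <- transition_scale(transitions) == "log2"
  shifts <- attr(transitions, "run_shifts")
  work <- transitions
  if (on_log2 && !is.null(shifts)) {
    work <- work |>
      dplyr::left_join(shifts[, c("subject", "replicate", "shift")],
                       by = c("subject", "replicate")) |>
      dplyr::mutate(intensity = .data$intensity -
                      dplyr::coalesce(.data$shift, 0)) |>
      dplyr::select(-"shift")
  }
  cvs <- work |>
    dplyr::mutate(raw = if (on_log2) 2^.data$intensity else
      .data$intensity) |>
    dplyr::group_by(.data$protein, .data$transition, .data$subject) |>
    dplyr::summarise(cv = sd(.data$raw) / mean(.data$raw), .groups = "drop")
  report <- cvs |>
    dplyr::group_by(.data$protein, .data$transition) |>
    dplyr::summarise(cv_fail_fraction = mean(.data$cv > cv_threshold),
                     .groups = "drop") |>
    dplyr::mutate(excluded = .data$cv_fail_fraction > run_fraction)
  out <- dplyr::filter(transitions,
                       !.data$transition %in%
                         report$transition[report$excluded])
  for (a in c("srm_scale", "srm_normalized", "srm_interference_filtered")) {
    attr(out, a) <- attr(transitions, a)
  }
  attr(out, "srm_cv_filtered") <- TRUE
  dropped_prot <- setdiff(unique(transitions$protein), unique(out$protein))
  if (length(dropped_prot) > 0) {
    warning("protein(s) lost all transitions to the CV filter: ",
            paste(dropped_prot, collapse = ", "), call. = FALSE)
  }
  attr(report, "dropped_proteins") <- dropped_prot
  list(transitions = out, report = report)
}

# Replicate-averaged, row-standardized transition x subject matrix for one
# protein.
protein_matrix_rows <- function(transitions, protein) {
  sub <- transitions[transitions$protein == protein, ]
  if (nrow(sub) == 0) stop("unknown protein: ", protein, call. = FALSE)
  wide <- sub |>
    dplyr::group_by(.data$transition, .data$subject) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "subject", values_from = "intensity")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$transition
  m
}

#' Eigengene summary of one protein
#'
#' Summarises a protein's surviving transitions as an eigengene: replicate
#' injections are first averaged per subject, each transition profile is
#' standardized across subjects, and the first right singular vector of the
#' transition-by-subject matrix, scaled by its singular value, is returned.
#' The sign is fixed so that the eigengene correlates positively with the
#' mean standardized transition profile. A single-transition protein
#' returns that transition's standardized profile.
#'
#' @param transitions Post-QC log2-scale transition table.
#' @param protein Protein identifier.
#' @return Tibble with columns `subject` and `eigengene`.
#' @export
protein_eigengene <- function(transitions, protein) {
  assert_columns(transitions, transition_cols)
  m <- protein_matrix_rows(transitions, protein)
  sds <- apply(m, 1, sd)
  if (all(sds == 0)) {
    stop(sprintf("protein %s has zero variance across subjects", protein),
         call. = FALSE)
  }
  if (any(sds == 0)) m <- m[sds > 0, , drop = FALSE]
  z <- t(scale(t(m)))
  if (nrow(z) == 1) {
    e <- as.numeric(z[1, ])
  } else {
    sv <- svd(z)
    e <- sv$d[1] * sv$v[, 1]
    ref <- colMeans(z)
    # SVD sign is arbitrary; orient along the mean transition profile.
    if (sum((e - mean(e)) * (ref - mean(ref))) < 0) e <- -e
  }
  tibble::tibble(subject = colnames(m), eigengene = e)
}

#' Summarise all proteins as an eigengene matrix
#'
#' Applies [protein_eigengene()] to every protein in the table and returns
#' the protein-by-subject abundance matrix in tidy wide form (one row per
#' protein, one column per subject).
#'
#' @param transitions Post-QC log2-scale transition table.
#' @return Tibble with a `protein` column followed by subject columns.
#' @export
summarize_proteins <- function(transitions) {
  assert_columns(transitions, transition_cols)
  proteins <- sort(unique(transitions$protein))
  rows <- purrr::map(proteins, function(p) {
    eg <- protein_eigengene(transitions, p)
    tibble::tibble(protein = p, subject = eg$subject, value = eg$eigengene)
  })
  dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "subject", values_from = "value")
}

# Long (subject rows) view of a protein matrix.
protein_matrix_long <- function(protein_matrix) {
  assert_columns(protein_matrix, "protein")
  tidyr::pivot_longer(protein_matrix, -"protein", names_to = "subject",
                      values_to = "abundance")
}

#' Screen a protein matrix for outlying subjects
#'
#' Reports (never removes) subjects that fall outside two standard
#' deviations from the cohort average on either of two criteria: the
#' subject's mean Pearson correlation to all other subjects, or its score
#' on the first two principal components of the protein matrix.
#'
#' @param protein_matrix Tibble as returned by [summarize_proteins()].
#' @param n_sd Flagging threshold in SD units (default 2).
#' @return Tibble with per-subject diagnostics (`mean_cor`, `pc1`, `pc2`)
#'   and logical flags `flag_cor`, `flag_pca`, `flagged`.
#' @export
outlier_screen <- function(protein_matrix, n_sd = 2) {
  long <- protein_matrix_long(protein_matrix)
  m <- long |>
    tidyr::pivot_wider(names_from = "subject", values_from = "abundance")
  x <- as.matrix(m[, -1])  # proteins x subjects
  if (ncol(x) < 3) stop("outlier screen needs at least 3 subjects",
                        call. = FALSE)
  cc <- cor(x)
  diag(cc) <- NA
  mean_cor <- colMeans(cc, na.rm = TRUE)
  pc <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flag_beyond <- function(v) {
    s <- sd(v)
    if (s == 0) rep(FALSE, length(v)) else abs(v - mean(v)) > n_sd * s
  }
  flag_cor <- flag_beyond(mean_cor)
  flag_pca <- flag_beyond(scores[, 1])
  if (k == 2) flag_pca <- flag_pca | flag_beyond(scores[, 2])
  tibble::tibble(
    subject = colnames(x),
    mean_cor = mean_cor,
    pc1 = scores[, 1],
    pc2 = if (k == 2) scores[, 2] else NA_real_,
    flag_cor = flag_cor,
    flag_pca = flag_pca,
    flagged = flag_cor | flag_pca
  )
}

#' Run the full SRM preprocessing stage
#'
#' Chains the canonical order: missing-value handling, log2 transform,
#' between-run median normalization, interference filter, duplicate-CV
#' filter, eigengene summarisation and subject outlier screen.
#'
#' @param transitions Raw-scale transition table.
#' @param interference_threshold Interference-score exclusion threshold.
#' @param cv_threshold,cv_run_fraction Duplicate-CV rule parameters.
#' @param max_missing_fraction Missing-run drop threshold.
#' @return List of class `srmdti_preprocess` with `protein_matrix`,
#'   `transitions` (post-QC), and `qc` (interference report, CV report,
#'   outlier screen, imputation log).
#' @export
preprocess_srm <- function(transitions,
                           interference_threshold = 0.8,
                           cv_threshold = 0.10,
                           cv_run_fraction = 0.10,
                           max_missing_fraction = 0.2) {
  imp <- impute_missing(transitions,
                        max_missing_fraction = max_missing_fraction)
  lg <- log2_transform(imp)
  nm <- normalize_runs(lg)
  fi <- filter_interference(nm, threshold = interference_threshold)
  fc <- cv_filter(fi$transitions, cv_threshold = cv_threshold,
                  run_fraction = cv_run_fraction)
  pm <- summarize_proteins(fc$transitions)
  outliers <- outlier_screen(pm)
  structure(list(
    protein_matrix = pm,
    transitions = fc$transitions,
    qc = list(interference = fi$report,
              cv = fc$report,
              outliers = outliers,
              imputation = attr(imp, "imputation_log"))
  ), class = "srmdti_preprocess")
}

#' @export
print.srmdti_preprocess <- function(x, ...) {
  cat("SRM preprocessing result\n")
  cat("  proteins kept:      ", nrow(x$protein_matrix), "\n")
  cat("  transitions kept:   ",
      dplyr::n_distinct(x$transitions$transition), "\n")
  cat("  interference excl.: ", sum(x$qc$interference$excluded), "\n")
  cat("  CV excl.:           ", sum(x$qc$cv$excluded), "\n")
  cat("  flagged subjects:   ", sum(x$qc$outliers$flagged), "\n")
  invisible(x)
}
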