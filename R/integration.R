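# Cross-modal protein x DTI correlation screen, leave-one-out influence
# diagnostics, hierarchical p-value stratification and the sign-test
# comparison of association counts between scopes.

scope_subjects <- function(cohort, scope) {
  mask <- scope_mask(scope, cohort$group)
  cohort$subject[mask]
}

#' Protein-by-ROI correlation screen
#'
#' Computes the Pearson correlation (exact-t two-sided p) of every protein
#' eigengene with every (ROI, metric) value over the subjects of one scope
#' (`"all"`, a single group, or `"MA+MAP"` for the pooled patient groups).
#' Associations are flagged at the nominal (p < 0.05) and study-wise
#' Bonferroni (p < 0.001, 0.05 over 48 ROIs) thresholds. When
#' `influence = TRUE`, each pair is additionally screened by leave-one-out
#' recomputation: `influence_flag` marks nominally significant pairs whose
#' significance is destroyed by removing a single subject, and
#' `r_loo_extreme` records the most attenuating leave-one-out coefficient.
#'
#' @param protein_matrix Tibble from [summarize_proteins()].
#' @param roi_data Tidy ROI table.
#' @param cohort Cohort table with `subject` and `group`.
#' @param scope Subject scope (default `"all"`).
#' @param nominal_alpha,bonferroni_alpha Flag thresholds (0.05, 0.001).
#' @param influence Run the leave-one-out screen (default TRUE).
#' @param min_n Minimum subjects in scope (default 5).
#' @return A tibble of class `srmdti_assoc`: one row per protein x ROI x
#'   metric with `r`, `p`, `n`, `nominal`, `bonferroni`, `influence_flag`,
#'   `r_loo_extreme`.
#' @export
crossmodal_correlate <- function(protein_matrix, roi_data, cohort,
                                 scope = "all",
                                 nominal_alpha = 0.05,
                                 bonferroni_alpha = 0.001,
                                 influence = TRUE,
                                 min_n = 5) {
  assert_columns(roi_data, roi_cols)
  subjects <- intersect(scope_subjects(cohort, scope),
                        setdiff(names(protein_matrix), "protein"))
  subjects <- intersect(subjects, unique(roi_data$subject))
  n <- length(subjects)
  if (n < min_n) {
    stop(sprintf("scope '%s' has %d subjects; need at least %d",
                 scope, n, min_n), call. = FALSE)
  }
  X <- t(as.matrix(protein_matrix[, subjects]))  # subjects x proteins
  colnames(X) <- protein_matrix$protein
  Yw <- roi_data |>
    dplyr::filter(.data$subject %in% subjects) |>
    tidyr::pivot_wider(names_from = c("roi", "metric"),
                       values_from = "value", names_sep = "@")
  Y <- as.matrix(Yw[match(subjects, Yw$subject), -1])
  const_x <- apply(X, 2, sd) == 0
  const_y <- apply(Y, 2, sd) == 0
  if (any(const_x) || any(const_y)) {
    warning("skipping constant vector(s): ",
            paste(c(colnames(X)[const_x], colnames(Y)[const_y]),
                  collapse = ", "), call. = FALSE)
    X <- X[, !const_x, drop = FALSE]
    Y <- Y[, !const_y, drop = FALSE]
  }
  r <- cor(X, Y)
  p <- pearson_p(r, n)
  grid <- tibble::as_tibble(r, rownames = "protein") |>
    tidyr::pivot_longer(-"protein", names_to = "cell", values_to = "r") |>
    tidyr::separate_wider_delim("cell", delim = "@",
                                names = c("roi", "metric"))
  grid$p <- as.vector(t(p))
  grid$n <- n
  grid$scope <- scope
  grid$nominal <- grid$p < nominal_alpha
  grid$bonferroni <- grid$p < bonferroni_alpha
  if (influence) {
    r_min <- r
    kill <- matrix(FALSE, nrow(r), ncol(r))
    for (i in seq_len(n)) {
      ri <- cor(X[-i, , drop = FALSE], Y[-i, , drop = FALSE])
      smaller <- abs(ri) < abs(r_min)
      r_min[smaller] <- ri[smaller]
      kill <- kill | (pearson_p(ri, n - 1) >= nominal_alpha)
    }
    grid$influence_flag <- as.vector(t((p < nominal_alpha) & kill))
    grid$r_loo_extreme <- as.vector(t(r_min))
  } else {
    grid$influence_flag <- NA
    grid$r_loo_extreme <- NA_real_
  }
  grid <- grid[, c("protein", "roi", "metric", "scope", "r", "p", "n",
                   "nominal", "bonferroni", "influence_flag",
                   "r_loo_extreme")]
  class(grid) <- c("srmdti_assoc", class(grid))
  grid
}

#' Leave-one-out influence screen for one correlation
#'
#' Recomputes the Pearson correlation of a pair of vectors with each point
#' left out in turn. The pair is flagged when it is significant at `alpha`
#' on the full data but some single removal pushes the p-value to or above
#' `alpha` (the association hinges on one observation).
#'
#' @param x,y Paired numeric vectors (n >= 5).
#' @param alpha Significance threshold (default 0.05).
#' @return One-row tibble: `r`, `p`, `n`, `influence_flag`,
#'   `r_loo_extreme` (the leave-one-out coefficient of smallest
#'   magnitude).
#' @export
influence_screen <- function(x, y, alpha = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("influence screen needs at least 5 paired points",
                  call. = FALSE)
  r <- cor(x, y)
  p <- pearson_p(r, n)
  loo <- vapply(seq_len(n), function(i) cor(x[-i], y[-i]), numeric(1))
  loo_p <- pearson_p(loo, n - 1)
  tibble::tibble(
    r = r, p = p, n = n,
    influence_flag = (p < alpha) && any(loo_p >= alpha),
    r_loo_extreme = loo[which.min(abs(loo))]
  )
}

#' Stratify associations by a hierarchical p-value cut-off scheme
#'
#' Counts, per scope, how many associations fall below each cutoff of a
#' nested cut-off scheme (default 0.05 > 0.01 > 0.001); counts are
#' monotone non-increasing with stricter cutoffs.
#'
#' @param grid Association grid from [crossmodal_correlate()] (rows from
#'   several scopes may be bound together).
#' @param cutoffs Numeric cutoffs; sorted decreasing (with a warning) if
#'   supplied unsorted.
#' @return Tibble: `scope`, `cutoff`, `count`.
#' @export
stratify_pvalues <- function(grid, cutoffs = c(0.05, 0.01, 0.001)) {
  if (is.unsorted(rev(cutoffs))) {
    warning("cutoffs were not sorted; sorting in decreasing order",
            call. = FALSE)
    cutoffs <- sort(cutoffs, decreasing = TRUE)
  }
  scopes <- if (nrow(grid) > 0) unique(grid$scope) else NA_character_
  tidyr::expand_grid(scope = scopes, cutoff = cutoffs) |>
    dplyr::rowwise() |>
    dplyr::mutate(count = if (nrow(grid) == 0) 0L else
      sum(grid$p < .data$cutoff & grid$scope == .data$scope)) |>
    dplyr::ungroup()
}

#' Sign-test comparison of nominal association counts between two scopes
#'
#' Counts nominally significant associations in two association grids over
#' the same protein x ROI x metric universe, forms paired counting units
#' (default: one pair per protein), scores each unit by which grid has
#' more nominal associations (ties dropped), and returns the exact
#' two-tailed binomial sign-test p-value.
#'
#' @param grid_control,grid_patient Association grids from
#'   [crossmodal_correlate()] for the two scopes being compared.
#' @param pairing_unit `"protein"` (default), `"roi"` or
#'   `"protein_metric"`.
#' @param alpha Nominal threshold applied to both grids (default 0.05).
#' @return List of class `srmdti_signtest`: total counts `n_control` /
#'   `n_patient`, unit wins and ties, the exact `p`, and the per-unit
#'   `pairs` tibble.
#' @export
compare_association_counts <- function(grid_control, grid_patient,
                                       pairing_unit = c("protein", "roi",
                                                        "protein_metric"),
                                       alpha = 0.05) {
  pairing_unit <- match.arg(pairing_unit)
  key <- c("protein", "roi", "metric")
  u1 <- dplyr::distinct(grid_control[, key])
  u2 <- dplyr::distinct(grid_patient[, key])
  if (nrow(u1) != nrow(u2) || nrow(dplyr::anti_join(u1, u2, by = key)) > 0) {
    stop("association grids cover different protein x ROI x metric universes",
         call. = FALSE)
  }
  unit_of <- function(g) {
    switch(pairing_unit,
           protein = g$protein,
           roi = g$roi,
           protein_metric = paste(g$protein, g$metric, sep = ":"))
  }
  count_by <- function(g) {
    tibble::tibble(unit = unit_of(g), hit = g$p < alpha) |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(count = sum(.data$hit), .groups = "drop")
  }
  pairs <- dplyr::full_join(count_by(grid_control), count_by(grid_patient),
                            by = "unit", suffix = c("_control", "_patient"))
  pairs$winner <- dplyr::case_when(
    pairs$count_control > pairs$count_patient ~ "control",
    pairs$count_control < pairs$count_patient ~ "patient",
    TRUE ~ "tie"
  )
  wins_control <- sum(pairs$winner == "control")
  wins_patient <- sum(pairs$winner == "patient")
  m <- wins_control + wins_patient
  if (m == 0) {
    warning("all paired units are ties; sign test undefined (p = 1)",
            call. = FALSE)
    p <- 1
  } else {
    p <- binom.test(wins_control, m, p = 0.5,
                    alternative = "two.sided")$p.value
  }
  structure(list(
    n_control = sum(grid_control$p < alpha),
    n_patient = sum(grid_patient$p < alpha),
    wins_control = wins_control,
    wins_patient = wins_patient,
    ties = sum(pairs$winner == "tie"),
    p = p,
    pairing_unit = pairing_unit,
    pairs = pairs
  ), class = "srmdti_signtest")
}

#' @export
print.srmdti_signtest <- function(x, ...) {
  cat("Sign test on nominal association counts (unit:", x$pairing_unit,
      ")\n")
  cat(sprintf("  totals: control %d vs patient %d\n", x$n_control,
              x$n_patient))
  cat(sprintf("  units:  %d control / %d patient / %d ties; p = %.4g\n",
              x$wins_control, x$wins_patient, x$ties, x$p))
  invisible(x)
}
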