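# ROI-wise diffusion statistics: covariate-adjusted group comparisons per
# (ROI, metric) cell, clustering of the resulting p-value matrix, and a
# tensor-metric consistency check.

roi_cols <- c("subject", "roi", "metric", "value")

#' Covariate-adjusted group comparison for every ROI and metric
#'
#' Applies the same linear-model-plus-Tukey machinery as
#' [differential_abundance()] to each (ROI, metric) response vector.
#' Reports, per cell: the omnibus group F-test p, the three Tukey-adjusted
#' pairwise contrasts, the strict elevation flag `map_elevated` (the MAP
#' group exceeds both other groups at adjusted p below `alpha`), the
#' direction indicator `map_directional` (both MAP contrast estimates
#' positive), and across-cell Bonferroni gates on the omnibus p (within
#' the metric's 48 cells, and globally across all cells).
#'
#' @param roi_data Tidy ROI table (`subject`, `roi`, `metric`, `value`).
#' @param cohort Cohort table with `subject`, `group` and covariates.
#' @param covariates Covariate names (see [default_covariates()]).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return Object of class `srmdti_roianova`: list with `cells` (per-cell
#'   summary), `contrasts` (tidy per-cell-per-contrast tibble),
#'   `covariates_used`, `alpha`.
#' @export
roi_group_anova <- function(roi_data, cohort,
                            covariates = default_covariates(),
                            alpha = 0.05) {
  assert_columns(roi_data, roi_cols)
  missing_subj <- setdiff(unique(roi_data$subject), cohort$subject)
  if (length(missing_subj) > 0) {
    stop("subjects absent from cohort table: ",
         paste(head(missing_subj, 5), collapse = ", "), call. = FALSE)
  }
  covariates <- usable_covariates(cohort, covariates)
  dat <- dplyr::inner_join(roi_data, cohort, by = "subject")
  const <- dat |>
    dplyr::group_by(.data$roi, .data$metric) |>
    dplyr::summarise(v = var(.data$value), .groups = "drop") |>
    dplyr::filter(.data$v == 0)
  if (nrow(const) > 0) {
    stop(sprintf("constant response for ROI %s metric %s",
                 const$roi[1], const$metric[1]), call. = FALSE)
  }
  contrasts <- dat |>
    dplyr::group_by(roi = .data$roi, metric = .data$metric) |>
    dplyr::group_modify(function(d, key) {
      d$response <- d$value
      fit_group_tukey(d, covariates)
    }) |>
    dplyr::ungroup()
  cells <- contrasts |>
    tidyr::pivot_wider(id_cols = c("roi", "metric", "omnibus_p"),
                       names_from = "contrast",
                       values_from = c("estimate", "p_adj")) |>
    dplyr::mutate(
      map_elevated = .data$`estimate_MAP-Control` > 0 &
        .data$`estimate_MAP-MA` > 0 &
        .data$`p_adj_MAP-Control` < alpha & .data$`p_adj_MAP-MA` < alpha,
      map_directional = .data$`estimate_MAP-Control` > 0 &
        .data$`estimate_MAP-MA` > 0,
      omnibus_significant = .data$omnibus_p < alpha
    )
  n_per_metric <- dplyr::count(cells, .data$metric, name = "n_cells")
  cells <- cells |>
    dplyr::left_join(n_per_metric, by = "metric") |>
    dplyr::mutate(
      bonferroni_metric = .data$omnibus_p < alpha / .data$n_cells,
      bonferroni_global = .data$omnibus_p < alpha / nrow(cells)
    ) |>
    dplyr::select(-"n_cells")
  structure(list(cells = cells, contrasts = contrasts,
                 covariates_used = covariates, alpha = alpha),
            class = "srmdti_roianova")
}

#' @export
print.srmdti_roianova <- function(x, ...) {
  cat("ROI group comparison:", nrow(x$cells), "cells;",
      sum(x$cells$omnibus_significant), "omnibus-significant;",
      sum(x$cells$map_elevated), "with MAP elevated over both groups\n")
  invisible(x)
}

# Pure R average-linkage (UPGMA) agglomeration is delegated to hclust;
# this helper prepares the correlation-distance matrix.
correlation_distance <- function(m) {
  1 - cor(t(m))
}

#' Hierarchically cluster the omnibus p-value matrix
#'
#' Clusters ROI rows of the ROI-by-metric omnibus p-value matrix using
#' one-minus-Pearson-correlation distance and average linkage, mirroring
#' the usual heat-map presentation in which bilaterally symmetric effects
#' appear as adjacent left/right leaves. Rows with zero variance have no
#' defined correlation; they are excluded from the tree and appended after
#' the ordered leaves with a warning.
#'
#' @param anova_result An `srmdti_roianova` object, or a tibble with
#'   columns `roi`, `metric`, `omnibus_p`.
#' @param value `"p"` (default) clusters raw p-values; `"neglog"` clusters
#'   -log10(p).
#' @return Object of class `srmdti_pcluster`: list with `hclust` (the
#'   fitted tree), `order` (leaf order including appended constant rows),
#'   `heights` (merge heights), `matrix` (the clustered matrix with
#'   hemisphere labels), `constant_rows`.
#' @export
pvalue_cluster <- function(anova_result, value = c("p", "neglog")) {
  value <- match.arg(value)
  cells <- if (inherits(anova_result, "srmdti_roianova")) {
    anova_result$cells
  } else {
    anova_result
  }
  assert_columns(cells, c("roi", "metric", "omnibus_p"))
  wide <- cells |>
    dplyr::select("roi", "metric", "omnibus_p") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "omnibus_p")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$roi
  if (value == "neglog") m <- -log10(m)
  sds <- apply(m, 1, sd)
  constant <- rownames(m)[sds == 0]
  if (length(constant) > 0) {
    warning("row(s) with undefined correlation placed last: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  active <- m[sds > 0, , drop = FALSE]
  if (nrow(active) < 2) {
    stop("need at least two non-constant rows to cluster", call. = FALSE)
  }
  hc <- hclust(as.dist(correlation_distance(active)), method = "average")
  atlas <- jhu_atlas()
  ord <- c(rownames(active)[hc$order], constant)
  out_m <- m[ord, , drop = FALSE]
  structure(list(
    hclust = hc,
    order = ord,
    heights = hc$height,
    matrix = out_m,
    hemisphere = atlas$hemisphere[match(ord, atlas$roi)],
    constant_rows = constant,
    value = value
  ), class = "srmdti_pcluster")
}

#' @export
print.srmdti_pcluster <- function(x, ...) {
  cat("P-value clustering:", nrow(x$matrix), "rows,",
      length(x$heights), "merges; leaf order:\n")
  cat(" ", paste(head(x$order, 12), collapse = ", "),
      if (length(x$order) > 12) "..." else "", "\n")
  invisible(x)
}

#' Check tensor-metric consistency of an ROI table
#'
#' Verifies, per subject and ROI, the eigenvalue identities of the
#' diffusion tensor summaries: MD = (AD + 2 RD) / 3 (mean of the three
#' eigenvalues with the radial pair averaged), AD >= RD, and FA inside
#' [0, 1]. Reporting only; nothing is removed.
#'
#' @param roi_data Tidy ROI table.
#' @param tolerance Relative tolerance on the MD identity (default 1e-6).
#' @return List with `violations` (tibble of offending cells and rule),
#'   `n_checked`, `ok`.
#' @export
validate_tensor_metrics <- function(roi_data, tolerance = 1e-6) {
  assert_columns(roi_data, roi_cols)
  wide <- roi_data |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value")
  md_bad <- abs(wide$MD - (wide$AD + 2 * wide$RD) / 3) >
    tolerance * pmax(abs(wide$MD), .Machine$double.eps)
  fa_bad <- wide$FA < 0 | wide$FA > 1
  order_bad <- wide$AD < wide$RD
  violations <- dplyr::bind_rows(
    wide[md_bad, c("subject", "roi")] |> dplyr::mutate(rule = "md_identity"),
    wide[fa_bad, c("subject", "roi")] |> dplyr::mutate(rule = "fa_range"),
    wide[order_bad, c("subject", "roi")] |>
      dplyr::mutate(rule = "ad_ge_rd")
  )
  list(violations = violations, n_checked = nrow(wide),
       ok = nrow(violations) == 0)
}
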