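# ggplot2 displays for the main result types.

#' Plot differential-abundance contrasts
#'
#' Estimate-versus-significance panel per group contrast; proteins crossing
#' the adjusted-significance threshold are labelled.
#'
#' @param object `srmdti_diffabund` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srmdti_diffabund <- function(object, ...) {
  d <- object$contrasts |>
    dplyr::mutate(significant = .data$p_adj < object$alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = -log10(.data$p_adj),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$contrast)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "contrast estimate (eigengene units)",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "adjusted p < alpha") +
    ggplot2::theme_minimal()
}

#' Heat map of the clustered omnibus p-value matrix
#'
#' ROI rows in clustered leaf order, one column per metric, hemisphere
#' shown in the row labels so bilateral symmetry is visible.
#'
#' @param object `srmdti_pcluster` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.srmdti_pcluster <- function(object, ...) {
  m <- object$matrix
  d <- tibble::as_tibble(m, rownames = "roi") |>
    tidyr::pivot_longer(-"roi", names_to = "metric", values_to = "value") |>
    dplyr::mutate(roi = factor(.data$roi, levels = rev(rownames(m))))
  lab <- if (object$value == "p") "omnibus p" else "-log10 omnibus p"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$roi,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = if (object$value == "p") -1
                                  else 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = lab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Bar chart of the hierarchical p-value stratification
#'
#' @param stratification Tibble from [stratify_pvalues()].
#' @return A ggplot object.
#' @export
plot_stratification <- function(stratification) {
  ggplot2::ggplot(stratification,
                  ggplot2::aes(x = factor(.data$cutoff),
                               y = .data$count, fill = .data$scope)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "p-value cutoff", y = "associations below cutoff",
                  fill = "scope") +
    ggplot2::theme_minimal()
}
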