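# broom-style accessors for the fitted result objects.

#' @describeIn differential_abundance Tidy per-contrast results.
#' @param x Result object.
#' @param ... Unused.
#' @export
tidy.srmdti_diffabund <- function(x, ...) x$contrasts

#' @describeIn differential_abundance One-row fit summary.
#' @export
glance.srmdti_diffabund <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$proteins),
    n_significant = sum(x$proteins$significant),
    alpha = x$alpha,
    covariates = paste(x$covariates_used, collapse = "+")
  )
}

#' @describeIn roi_group_anova Tidy per-contrast results.
#' @param x Result object.
#' @param ... Unused.
#' @export
tidy.srmdti_roianova <- function(x, ...) x$contrasts

#' @describeIn roi_group_anova One-row fit summary.
#' @export
glance.srmdti_roianova <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_omnibus_significant = sum(x$cells$omnibus_significant),
    n_map_elevated = sum(x$cells$map_elevated),
    alpha = x$alpha
  )
}

#' @describeIn compare_association_counts Tidy per-unit counts.
#' @param x Result object.
#' @param ... Unused.
#' @export
tidy.srmdti_signtest <- function(x, ...) x$pairs

#' @describeIn compare_association_counts One-row test summary.
#' @export
glance.srmdti_signtest <- function(x, ...) {
  tibble::tibble(
    n_control = x$n_control, n_patient = x$n_patient,
    wins_control = x$wins_control, wins_patient = x$wins_patient,
    ties = x$ties, p = x$p, pairing_unit = x$pairing_unit
  )
}
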