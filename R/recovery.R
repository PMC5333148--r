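# Pipeline-level parameter-recovery harness: generate a synthetic cohort
# with planted structure, run the analysis stages, and score how much of
# the planted truth is recovered. This is the package's main end-to-end
# self-check.

#' Score planted-effect recovery for one synthetic cohort
#'
#' Generates a cohort with [generate_cohort()], runs preprocessing,
#' differential abundance, the radial-diffusivity ROI comparison and the
#' control-versus-patient cross-modal screens, and scores recovery of the
#' planted structure:
#' \describe{
#'   \item{protein_hit}{both planted differential apolipoproteins (APOC2
#'     up, APOH down) show both psychosis-group Tukey contrasts at
#'     adjusted p below `alpha`.}
#'   \item{rd_tracts_recovered}{number of planted tracts whose RD omnibus
#'     group test is significant with the psychosis group estimated
#'     highest.}
#'   \item{interference_sensitivity}{fraction of planted interfered
#'     transitions removed by the interference filter.}
#'   \item{control_excess}{whether the control scope yields more nominal
#'     protein-DTI associations than the pooled patient scope.}
#' }
#'
#' @param seed Integer seed for the cohort.
#' @param config Generator configuration.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with the scores above plus the raw counts.
#' @seealso [signals_as_protein_matrix()] to analyse the generator's true
#'   signals directly (e.g. for type-I-error suites).
#' @export
evaluate_recovery <- function(seed, config = generator_config(),
                              alpha = 0.05) {
  ch <- generate_cohort(config, seed = seed)
  pre <- suppressWarnings(preprocess_srm(ch$transitions))
  pm <- pre$protein_matrix

  set.seed(seed)  # fixes the quasi-random Tukey integration
  da <- suppressWarnings(differential_abundance(pm, ch$cohort,
                                                alpha = alpha))
  ct <- da$contrasts
  map_hits <- function(p) {
    d <- ct[ct$protein == p & ct$contrast %in% c("MAP-Control", "MAP-MA"), ]
    nrow(d) == 2 && all(d$p_adj < alpha)
  }
  protein_hit <- map_hits("APOC2") && map_hits("APOH")

  rd <- suppressWarnings(roi_group_anova(
    dplyr::filter(ch$roi, .data$metric == "RD"), ch$cohort, alpha = alpha))
  planted <- unique(ch$truth$affected_roi_cells$roi)
  cells <- rd$cells[rd$cells$roi %in% planted, ]
  rd_rec <- sum(cells$omnibus_p < alpha & cells$map_directional)

  qc <- pre$qc$interference
  planted_tr <- ch$truth$interfered_transitions
  sens <- if (length(planted_tr) == 0) NA_real_ else {
    sum(qc$excluded & qc$transition %in% planted_tr) / length(planted_tr)
  }

  g_ctl <- crossmodal_correlate(pm, ch$roi, ch$cohort, scope = "Control",
                                nominal_alpha = alpha, influence = FALSE)
  g_pat <- crossmodal_correlate(pm, ch$roi, ch$cohort, scope = "MA+MAP",
                                nominal_alpha = alpha, influence = FALSE)
  st <- compare_association_counts(g_ctl, g_pat, alpha = alpha)

  tibble::tibble(
    seed = seed,
    protein_hit = protein_hit,
    rd_tracts_recovered = rd_rec,
    rd_tracts_planted = length(planted),
    interference_sensitivity = sens,
    nominal_control = st$n_control,
    nominal_patient = st$n_patient,
    control_excess = st$n_control > st$n_patient,
    sign_test_p = st$p
  )
}

#' Convert generator truth signals to a protein-matrix layout
#'
#' Reshapes the `protein_signals` ground-truth table of a synthetic cohort
#' (one row per subject, one column per protein) into the
#' protein-by-subject layout used by the analysis functions, so the true
#' signals can be fed through [differential_abundance()] or
#' [crossmodal_correlate()] directly, bypassing the measurement layer.
#'
#' @param signals The `truth$protein_signals` tibble of a cohort.
#' @return Tibble with a `protein` column followed by subject columns.
#' @export
signals_as_protein_matrix <- function(signals) {
  proteins <- setdiff(names(signals), "subject")
  out <- tibble::as_tibble(cbind(
    data.frame(protein = proteins),
    as.data.frame(t(as.matrix(signals[, proteins])))))
  names(out)[-1] <- signals$subject
  out
}
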