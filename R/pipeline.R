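# End-to-end orchestration: preprocess -> differential abundance -> ROI
# statistics -> cross-modal integration, with a machine-readable report.

#' Build a pipeline configuration
#'
#' Collects the thresholds of every stage in one place. All thresholds can
#' be overridden; defaults are the pipeline's canonical operating point
#' (interference 0.8, CV 10%/10%, alpha 0.05, Bonferroni 0.01 for the
#' three psychometric scales and 0.001 for the 48-ROI screen).
#'
#' @param interference_threshold,cv_threshold,cv_run_fraction SRM QC
#'   thresholds.
#' @param alpha Significance level for adjusted p-values.
#' @param psychometric_bonferroni,dti_bonferroni Study-wise thresholds.
#' @param covariates Adjustment covariates.
#' @param pairing_unit Sign-test pairing unit.
#' @param seed Seed forwarded to stochastic steps.
#' @return List of class `srmdti_pipeline_config`.
#' @export
pipeline_config <- function(interference_threshold = 0.8,
                            cv_threshold = 0.10,
                            cv_run_fraction = 0.10,
                            alpha = 0.05,
                            psychometric_bonferroni = 0.01,
                            dti_bonferroni = 0.001,
                            covariates = default_covariates(),
                            pairing_unit = "protein",
                            seed = 1) {
  stopifnot(interference_threshold <= 1,
            cv_threshold > 0, cv_run_fraction > 0, cv_run_fraction <= 1,
            alpha > 0, alpha <= 1)
  structure(list(interference_threshold = interference_threshold,
                 cv_threshold = cv_threshold,
                 cv_run_fraction = cv_run_fraction,
                 alpha = alpha,
                 psychometric_bonferroni = psychometric_bonferroni,
                 dti_bonferroni = dti_bonferroni,
                 covariates = covariates,
                 pairing_unit = pairing_unit,
                 seed = seed),
            class = "srmdti_pipeline_config")
}

#' Run the full multi-modal pipeline
#'
#' Executes preprocessing, differential abundance, ROI statistics and
#' cross-modal integration on in-memory tables (typically a
#' [generate_cohort()] object or tables read with the `read_*` functions),
#' returning every stage result plus a summary report. Identical inputs
#' and configuration give identical output.
#'
#' @param transitions Raw transition table.
#' @param cohort Cohort covariate table.
#' @param roi_data Tidy ROI table.
#' @param config [pipeline_config()].
#' @param outdir Optional directory; when given, every intermediate table
#'   and the JSON report are persisted there.
#' @return List of class `srmdti_run` with `preprocess`, `diffabund`,
#'   `varfrac`, `psychometric`, `dti`, `pcluster`, `associations` (one
#'   grid per scope: all, Control, MA+MAP), `signtest`, `stratification`
#'   and `report`.
#' @export
run_pipeline <- function(transitions, cohort, roi_data,
                         config = pipeline_config(), outdir = NULL) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  pre <- stage("preprocess", preprocess_srm(
    transitions,
    interference_threshold = config$interference_threshold,
    cv_threshold = config$cv_threshold,
    cv_run_fraction = config$cv_run_fraction))
  da <- stage("diffabund", differential_abundance(
    pre$protein_matrix, cohort, covariates = config$covariates,
    alpha = config$alpha))
  vf <- stage("diffabund", variance_fractions(
    pre$protein_matrix, cohort, covariates = config$covariates))
  psy <- stage("diffabund", psychometric_correlation(
    pre$protein_matrix, cohort,
    bonferroni_alpha = config$psychometric_bonferroni))
  dti <- stage("dti", roi_group_anova(
    roi_data, cohort, covariates = config$covariates,
    alpha = config$alpha))
  pcl <- stage("dti", pvalue_cluster(dti))
  assoc <- stage("integrate", {
    scopes <- c("all", "Control", "MA+MAP")
    setNames(lapply(scopes, function(s) {
      crossmodal_correlate(pre$protein_matrix, roi_data, cohort, scope = s,
                           nominal_alpha = config$alpha,
                           bonferroni_alpha = config$dti_bonferroni)
    }), scopes)
  })
  st <- stage("integrate", compare_association_counts(
    assoc[["Control"]], assoc[["MA+MAP"]],
    pairing_unit = config$pairing_unit, alpha = config$alpha))
  strat <- stage("integrate", stratify_pvalues(
    dplyr::bind_rows(assoc[c("Control", "MA+MAP")])))
  report <- list(
    schema_version = "1.0",
    config = unclass(config),
    counts = list(
      transitions_in = dplyr::n_distinct(transitions$transition),
      transitions_kept = dplyr::n_distinct(pre$transitions$transition),
      excluded_interference = sum(pre$qc$interference$excluded),
      excluded_cv = sum(pre$qc$cv$excluded),
      proteins = nrow(pre$protein_matrix),
      flagged_subjects = sum(pre$qc$outliers$flagged)
    ),
    findings = list(
      significant_proteins =
        pre$protein_matrix$protein[match(
          da$proteins$protein[da$proteins$significant],
          pre$protein_matrix$protein)],
      map_elevated_cells = nrow(dplyr::filter(dti$cells,
                                              .data$map_elevated)),
      nominal_associations_control = st$n_control,
      nominal_associations_patient = st$n_patient,
      sign_test_p = st$p
    ),
    wall_clock_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  res <- structure(list(preprocess = pre, diffabund = da, varfrac = vf,
                        psychometric = psy, dti = dti, pcluster = pcl,
                        associations = assoc, signtest = st,
                        stratification = strat, report = report),
                   class = "srmdti_run")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_protein_matrix(pre$protein_matrix,
                         file.path(outdir, "protein_matrix.csv"))
    readr::write_csv(da$contrasts, file.path(outdir, "diffabund.csv"))
    readr::write_csv(vf, file.path(outdir, "variance_fractions.csv"))
    readr::write_csv(psy, file.path(outdir, "psychometric.csv"))
    readr::write_csv(dti$cells, file.path(outdir, "roi_anova.csv"))
    readr::write_csv(dplyr::bind_rows(assoc),
                     file.path(outdir, "associations.csv"))
    readr::write_csv(strat, file.path(outdir, "stratification.csv"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.srmdti_run <- function(x, ...) {
  r <- x$report
  cat("Multi-modal pipeline run\n")
  cat("  transitions kept:", r$counts$transitions_kept, "of",
      r$counts$transitions_in, "\n")
  cat("  significant proteins:",
      paste(r$findings$significant_proteins, collapse = ", "), "\n")
  cat("  MAP-elevated ROI cells:", r$findings$map_elevated_cells, "\n")
  cat(sprintf("  nominal associations: control %d vs patient %d (p = %.3g)\n",
              r$findings$nominal_associations_control,
              r$findings$nominal_associations_patient,
              r$findings$sign_test_p))
  invisible(x)
}
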