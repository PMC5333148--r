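# Covariate-adjusted group statistics: per-feature linear models with
# single-step Tukey contrasts, variance-fraction attribution, and the
# demographic/clinical cohort tests.

default_covariates <- function() {
  c("age", "gender", "nicotine", "cannabis", "alcohol", "mandrax")
}

# Drop covariates that cannot enter the design (constant in the cohort).
usable_covariates <- function(data, covariates) {
  ok <- vapply(covariates, function(cv) {
    v <- data[[cv]]
    !is.null(v) && dplyr::n_distinct(v[!is.na(v)]) >= 2
  }, logical(1))
  dropped <- covariates[!ok]
  if (length(dropped) > 0) {
    warning("dropping constant/absent covariate(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  covariates[ok]
}

# One covariate-adjusted fit: omnibus group F-test plus the three pairwise
# Tukey (single-step max-|t|) contrasts from the same model.
fit_group_tukey <- function(data, covariates) {
  data$group <- droplevels(factor(data$group))
  fml <- reformulate(c("group", covariates), response = "response")
  fit <- lm(fml, data = data)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    bad <- covariates[vapply(covariates, function(cv) {
      any(startsWith(aliased, cv))
    }, logical(1))]
    warning("dropping rank-deficient covariate(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    covariates <- setdiff(covariates, bad)
    fit <- lm(reformulate(c("group", covariates), response = "response"),
              data = data)
  }
  reduced <- lm(reformulate(if (length(covariates) > 0) covariates else "1",
                            response = "response"), data = data)
  omnibus_p <- anova(reduced, fit)[2, "Pr(>F)"]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  adj <- summary(gl)$test
  raw <- summary(gl, test = multcomp::adjusted("none"))$test
  tibble::tibble(
    contrast = gsub(" ", "", names(adj$coefficients)),
    estimate = as.numeric(adj$coefficients),
    se = as.numeric(adj$sigma),
    statistic = as.numeric(adj$tstat),
    p_raw = as.numeric(raw$pvalues),
    p_adj = as.numeric(adj$pvalues),
    omnibus_p = omnibus_p
  )
}

#' Covariate-adjusted differential protein abundance
#'
#' Fits, per protein, `abundance ~ group + covariates` and reports the
#' omnibus group F-test together with the three pairwise group contrasts
#' (MA-Control, MAP-Control, MAP-MA) under single-step Tukey (max-|t|)
#' familywise adjustment, all from the same fitted model.
#'
#' @param protein_matrix Tibble from [summarize_proteins()] (one row per
#'   protein, one column per subject).
#' @param cohort Cohort table with `subject`, `group` and the covariates.
#' @param covariates Covariate names (default: age, gender and the four
#'   binary substance indicators).
#' @param alpha Significance level on the adjusted p-values (default 0.05).
#' @return Object of class `srmdti_diffabund`: list with `contrasts` (tidy
#'   per-protein-per-contrast tibble), `proteins` (per-protein omnibus
#'   summary with a `significant` flag: any adjusted p below `alpha`),
#'   `covariates_used` and `alpha`.
#' @export
differential_abundance <- function(protein_matrix, cohort,
                                   covariates = default_covariates(),
                                   alpha = 0.05) {
  long <- protein_matrix_long(protein_matrix)
  missing_subj <- setdiff(unique(long$subject), cohort$subject)
  if (length(missing_subj) > 0) {
    stop("subjects absent from cohort table: ",
         paste(head(missing_subj, 5), collapse = ", "), call. = FALSE)
  }
  covariates <- usable_covariates(cohort, covariates)
  dat <- dplyr::inner_join(long, cohort, by = "subject")
  contrasts <- dat |>
    dplyr::group_by(protein = .data$protein) |>
    dplyr::group_modify(function(d, key) {
      d$response <- d$abundance
      fit_group_tukey(d, covariates)
    }) |>
    dplyr::ungroup()
  proteins <- contrasts |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(omnibus_p = .data$omnibus_p[1],
                     min_p_adj = min(.data$p_adj),
                     significant = any(.data$p_adj < alpha),
                     .groups = "drop")
  structure(list(contrasts = contrasts, proteins = proteins,
                 covariates_used = covariates, alpha = alpha),
            class = "srmdti_diffabund")
}

#' @export
print.srmdti_diffabund <- function(x, ...) {
  cat("Differential abundance:", nrow(x$proteins), "proteins;",
      sum(x$proteins$significant), "with adjusted p <", x$alpha, "\n")
  cat("Covariates:", paste(x$covariates_used, collapse = ", "), "\n")
  invisible(x)
}

#' Per-protein variance-fraction attribution
#'
#' Attributes the variance of each protein's abundance to the covariates:
#' categorical terms enter a mixed model as random intercepts and
#' contribute their estimated variance components, age contributes the
#' variance of its fixed-effect prediction, and the remainder is residual.
#' Fractions are normalized to sum to one. When a mixed fit fails, a
#' sequential sum-of-squares partial R-squared decomposition is used
#' instead and noted in the `method` column.
#'
#' @inheritParams differential_abundance
#' @return Tibble with columns `protein`, `term`, `fraction`, `method`.
#' @export
variance_fractions <- function(protein_matrix, cohort,
                               covariates = default_covariates()) {
  covariates <- usable_covariates(cohort, covariates)
  categorical <- setdiff(covariates, "age")
  long <- protein_matrix_long(protein_matrix)
  dat <- dplyr::inner_join(long, cohort, by = "subject")
  one_protein <- function(d) {
    terms <- c(intersect(covariates, "age"), categorical, "residual")
    mixed <- try(silent = TRUE, {
      rand <- paste0("(1|", categorical, ")")
      fml <- stats::as.formula(paste(
        "abundance ~", paste(c(intersect(covariates, "age"), rand),
                             collapse = " + ")))
      fit <- suppressMessages(suppressWarnings(lme4::lmer(
        fml, data = d, REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE,
                                    check.conv.singular = "ignore"))))
      vc <- as.data.frame(lme4::VarCorr(fit))
      comp <- setNames(vc$vcov, ifelse(is.na(vc$grp) | vc$grp == "Residual",
                                       "residual", vc$grp))
      out <- setNames(numeric(length(terms)), terms)
      out["residual"] <- comp[["residual"]]
      for (tm in categorical) {
        out[tm] <- if (tm %in% names(comp)) comp[[tm]] else 0
      }
      if ("age" %in% terms) {
        out["age"] <- var(lme4::fixef(fit)[["age"]] * d$age)
      }
      out
    })
    if (inherits(mixed, "try-error")) {
      # sequential sum-of-squares fallback
      fml <- reformulate(covariates, response = "abundance")
      d2 <- d
      for (tm in categorical) d2[[tm]] <- factor(d2[[tm]])
      av <- anova(lm(fml, data = d2))
      ss <- setNames(av$`Sum Sq`, rownames(av))
      out <- setNames(numeric(length(terms)), terms)
      for (tm in setdiff(terms, "residual")) {
        out[tm] <- if (tm %in% names(ss)) ss[[tm]] else 0
      }
      out["residual"] <- ss[["Residuals"]]
      method <- "sequential_ss"
    } else {
      out <- mixed
      method <- "variance_components"
    }
    tibble::tibble(term = names(out), fraction = out / sum(out),
                   method = method)
  }
  dat |>
    dplyr::group_by(protein = .data$protein) |>
    dplyr::group_modify(~ one_protein(.x)) |>
    dplyr::ungroup()
}

#' Normality-gated omnibus group test for a continuous variable
#'
#' Runs a Shapiro-Wilk test on the residuals of the one-way group model; if
#' normality is not rejected (p >= `shapiro_alpha`) a one-way ANOVA is
#' used, otherwise a tie-corrected Kruskal-Wallis test.
#'
#' @param values Numeric vector (one value per subject).
#' @param groups Group labels aligned with `values`.
#' @param shapiro_alpha Normality gate (default 0.05).
#' @return One-row tibble: `method` ("anova" or "kruskal"), `statistic`,
#'   `df`, `p`, `shapiro_p`.
#' @export
demographic_group_test <- function(values, groups, shapiro_alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2 || length(values) < 3) {
    stop("need at least 2 groups and 3 values", call. = FALSE)
  }
  if (var(values) == 0) stop("values are constant", call. = FALSE)
  res <- stats::residuals(lm(values ~ groups))
  shapiro_p <- shapiro.test(res)$p.value
  if (shapiro_p >= shapiro_alpha) {
    av <- anova(lm(values ~ groups))
    tibble::tibble(method = "anova", statistic = av$`F value`[1],
                   df = av$Df[1], p = av$`Pr(>F)`[1], shapiro_p = shapiro_p)
  } else {
    kw <- kruskal.test(values, groups)
    tibble::tibble(method = "kruskal",
                   statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p = kw$p.value,
                   shapiro_p = shapiro_p)
  }
}

#' Group test for a binary trait
#'
#' Compares a binary trait across groups. The default statistic is
#' H = ((N-1)/N) x Pearson chi-squared on the groups-by-trait contingency
#' table, which is identically the tie-corrected Kruskal-Wallis statistic
#' computed on the 0/1 indicator; p-values come from the chi-squared
#' distribution with (groups - 1) degrees of freedom. `method = "chisq"`
#' returns the plain Pearson chi-squared instead.
#'
#' @param counts Either a groups-by-2 contingency matrix (trait-positive
#'   counts in the first column) or a vector of trait-positive counts per
#'   group (then `totals` is required).
#' @param totals Per-group totals when `counts` is a vector.
#' @param method `"indicator_kw"` (default) or `"chisq"`.
#' @return One-row tibble: `statistic`, `df`, `p`, `method`.
#' @export
#' @examples
#' # trait present in 5/16, 2/14 and 1/12 subjects
#' categorical_group_test(c(5, 2, 1), totals = c(16, 14, 12))
categorical_group_test <- function(counts, totals = NULL,
                                   method = c("indicator_kw", "chisq")) {
  method <- match.arg(method)
  if (is.matrix(counts)) {
    tab <- counts
  } else {
    if (is.null(totals)) {
      stop("totals required when counts is a vector", call. = FALSE)
    }
    tab <- cbind(yes = counts, no = totals - counts)
  }
  if (any(tab < 0) || any(rowSums(tab) <= 0)) {
    stop("invalid contingency table", call. = FALSE)
  }
  df <- nrow(tab) - 1
  if (any(colSums(tab) == 0)) {
    warning("trait is constant across the cohort; statistic set to 0",
            call. = FALSE)
    return(tibble::tibble(statistic = 0, df = df, p = 1, method = method))
  }
  statistic <- categorical_statistic(tab, scaled = method == "indicator_kw")
  tibble::tibble(statistic = statistic, df = df,
                 p = pchisq(statistic, df, lower.tail = FALSE),
                 method = method)
}

# Bare statistic: Pearson chi-squared, optionally scaled by (N-1)/N (the
# tie-corrected Kruskal-Wallis identity on a binary indicator).
categorical_statistic <- function(tab, scaled = TRUE) {
  N <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / N
  chi2 <- sum((tab - expected)^2 / expected)
  if (scaled) (N - 1) / N * chi2 else chi2
}

#' Spearman screen of protein abundance against psychometric scores
#'
#' Correlates each protein with each psychometric score (Spearman), within
#' an optional group scope, and flags nominal (p < `nominal_alpha`) and
#' Bonferroni-significant (p < `bonferroni_alpha`, the study-wise threshold
#' for three psychometric scales) associations.
#'
#' @inheritParams differential_abundance
#' @param scores Psychometric column names in `cohort`.
#' @param scope `"all"` or one group level (e.g. `"MAP"` for PANSS scales).
#' @param min_n Minimum paired observations; smaller sets are skipped with
#'   a warning.
#' @param nominal_alpha,bonferroni_alpha Flag thresholds (defaults 0.05 and
#'   0.01).
#' @return Tibble: `protein`, `score`, `scope`, `rho`, `p`, `n`, `nominal`,
#'   `bonferroni`.
#' @export
psychometric_correlation <- function(protein_matrix, cohort,
                                     scores = c("epqrs_psychoticism",
                                                "epqrs_extraversion",
                                                "epqrs_neuroticism"),
                                     scope = "all",
                                     min_n = 5,
                                     nominal_alpha = 0.05,
                                     bonferroni_alpha = 0.01) {
  assert_columns(cohort, c("subject", scores))
  long <- protein_matrix_long(protein_matrix)
  dat <- dplyr::inner_join(long, cohort, by = "subject")
  if (scope != "all") dat <- dplyr::filter(dat, .data$group == scope)
  out <- tidyr::expand_grid(protein = unique(dat$protein), score = scores) |>
    purrr::pmap_dfr(function(protein, score) {
      d <- dat[dat$protein == protein, ]
      pair <- na.omit(tibble::tibble(x = d$abundance, y = d[[score]]))
      if (nrow(pair) < min_n || sd(pair$y) == 0 || sd(pair$x) == 0) {
        warning(sprintf("skipping %s ~ %s (insufficient or constant data)",
                        protein, score), call. = FALSE)
        return(NULL)
      }
      ct <- suppressWarnings(cor.test(pair$x, pair$y, method = "spearman",
                                      exact = FALSE))
      tibble::tibble(protein = protein, score = score, scope = scope,
                     rho = unname(ct$estimate), p = ct$p.value,
                     n = nrow(pair))
    })
  dplyr::mutate(out,
                nominal = .data$p < nominal_alpha,
                bonferroni = .data$p < bonferroni_alpha)
}
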