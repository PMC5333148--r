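# Synthetic cohort generator with known ground truth.
#
# The generator emulates the study design the pipeline targets: 42 subjects
# in three groups (16 healthy controls, 14 stimulant-dependent, 12 with
# stimulant-associated psychosis), a 43-protein SRM serum panel observed at
# the transition level in duplicate injections, ROI-level diffusion
# summaries over the 48-region JHU white-matter atlas, and psychometric
# scores. Group effects, transition interference and cross-modal couplings
# are planted with known magnitudes so every pipeline stage has a recovery
# test.

srm_panel <- function() {
  c("APOC2", "APOH", "HPTR", "A1AT", "A2AP", "AACT", "C1R", "CFAB", "CO4A",
    "PEDF", "APOA1", "APOA2", "APOA4", "APOB", "APOC1", "APOC3", "APOD",
    "APOE", "APOM", "TTHY", "CFH", "CERU", "HPT", "HEMO", "A2MG", "ANT3",
    "C1QB", "C1S", "CO3", "CO5", "CO6", "CO9", "CRP", "FIBA", "FIBB",
    "FIBG", "GELS", "ITIH4", "KNG1", "PLMN", "THRB", "TRFE", "VTDB")
}

# Group-wise demographic targets: exact categorical counts and continuous
# moments for age, education and EPQR-S/PANSS scales.
default_demographics <- function() {
  list(
    gender_male = c(Control = 14, MA = 10, MAP = 9),
    nicotine    = c(Control = 7,  MA = 9,  MAP = 12),
    cannabis    = c(Control = 5,  MA = 2,  MAP = 1),
    alcohol     = c(Control = 6,  MA = 7,  MAP = 1),
    mandrax     = c(Control = 0,  MA = 0,  MAP = 1),
    age_mean    = c(Control = 25.56, MA = 22.71, MAP = 25.00),
    age_sd      = c(Control = 5.99,  MA = 3.07,  MAP = 7.39),
    education_mean = c(Control = 12.13, MA = 10.29, MAP = 9.75),
    education_sd   = c(Control = 1.41,  MA = 1.98,  MAP = 1.22),
    epqrs_total_mean = c(Control = 20.38, MA = 19.93, MAP = 20.58),
    epqrs_total_sd   = c(Control = 5.08,  MA = 4.57,  MAP = 3.92),
    epqrs_psychoticism_mean = c(Control = 2.56, MA = 2.29, MAP = 2.83),
    epqrs_psychoticism_sd   = c(Control = 1.55, MA = 1.86, MAP = 1.95),
    epqrs_extraversion_mean = c(Control = 9.94, MA = 9.14, MAP = 7.17),
    epqrs_extraversion_sd   = c(Control = 2.38, MA = 2.25, MAP = 2.55),
    epqrs_neuroticism_mean  = c(Control = 2.63, MA = 4.86, MAP = 5.00),
    epqrs_neuroticism_sd    = c(Control = 2.36, MA = 2.88, MAP = 2.92),
    panss = c(positive_mean = 12.5,  positive_sd = 5.66,
              negative_mean = 15.5,  negative_sd = 10.05,
              total_mean    = 50.58, total_sd    = 23.71)
  )
}

#' Default planted protein group effects
#'
#' Shifts are in residual-SD units of the per-subject protein signal;
#' `sd_scale` multiplies the residual spread within the shifted group
#' (the psychosis group's APOH spread is generated tighter than the other
#' groups', matching the reduced-variance pattern the panel is built to
#' emulate).
#' @return Tibble with columns `protein`, `group`, `shift`, `sd_scale`.
#' @export
default_protein_effects <- function() {
  tibble::tibble(
    protein  = c("APOC2", "APOH", "HPTR"),
    group    = "MAP",
    shift    = c(2.0, -2.0, 1.5),
    sd_scale = c(1.0, 0.5, 1.0)
  )
}

#' Default planted DTI group effects
#'
#' Radial diffusivity is elevated by 1.5 residual SDs in the psychosis group
#' for eight bilateral tracts (corticospinal tract, superior and inferior
#' cerebellar peduncles, fornix-cres/stria terminalis); axial diffusivity
#' receives a 0.75-SD shift, the balance point of the tensor identities at
#' which the derived mean diffusivity is elevated by about 1.5 residual SDs
#' while fractional anisotropy and axial diffusivity each move by less than
#' 0.8 SD (radial elevation with neither FA nor AD silent is physically
#' impossible when MD must rise).
#' @return Tibble with columns `roi`, `metric`, `group`, `shift`.
#' @export
default_roi_effects <- function() {
  rois <- c("CST-R", "CST-L", "SCP-R", "SCP-L",
            "ICP-R", "ICP-L", "FXST-R", "FXST-L")
  dplyr::bind_rows(
    tibble::tibble(roi = rois, metric = "RD", group = "MAP", shift = 1.5),
    tibble::tibble(roi = rois, metric = "AD", group = "MAP", shift = 0.75)
  )
}

#' Default cross-modal couplings
#'
#' Couplings are induced by shared latent factors. Each row requests a
#' target Pearson correlation `r` between a protein's signal and one ROI
#' diffusivity axis (`AD` or `RD`) within a subject `scope`; derived metrics
#' (MD, FA) inherit correlations with physically consistent signs. Defaults
#' plant: a negative fornix / uncinate coupling for APOH across all
#' subjects; a 15-ROI control-only RD coupling for A1AT; a shared
#' control-only middle-cerebellar-peduncle factor for five
#' complement/protease proteins; a psychosis-only coupling of PEDF to left
#' posterior corona radiata AD; and control-only background co-linearity
#' factors, one per remaining panel protein, emulating the broad loss of
#' protein-microstructure coupling outside the control group.
#' @return Tibble with columns `factor`, `protein`, `roi`, `metric`,
#'   `scope`, `r`.
#' @export
default_couplings <- function() {
  apoh <- tibble::tibble(
    factor = "APOH_FX", protein = "APOH",
    roi = c("FX", "FX", "UNC-L", "UNC-L"),
    metric = c("RD", "AD", "RD", "AD"),
    scope = "all", r = c(-0.50, -0.40, -0.45, -0.45)
  )
  a1at_rois <- c("ACR-R", "ACR-L", "SCR-R", "SCR-L", "PCR-R",
                 "ICP-R", "ICP-L", "FXST-R", "FXST-L", "SLF-R", "SLF-L",
                 "EC-R", "EC-L", "CGC-R", "CGC-L")
  a1at <- tibble::tibble(
    factor = "A1AT_CTL", protein = "A1AT", roi = a1at_rois,
    metric = "RD", scope = "Control", r = 0.60
  )
  mcp <- tidyr::expand_grid(
    protein = c("A2AP", "AACT", "C1R", "CFAB", "CO4A"),
    metric = c("RD", "AD")
  ) |>
    dplyr::mutate(factor = "MCP_CTL", roi = "MCP", scope = "Control",
                  r = ifelse(.data$metric == "RD", 0.65, 0.50))
  pedf <- tibble::tibble(
    factor = "PEDF_MAP", protein = "PEDF", roi = "PCR-L",
    metric = "AD", scope = "MAP", r = 0.70
  )
  # Background control-only co-linearity: one factor per remaining panel
  # protein. Most proteins couple to both diffusivity axes of one free ROI;
  # proteins left over once free ROIs run out couple to the unused axial
  # cells of the A1AT ROIs.
  used_rois <- unique(c("FX", "UNC-L", a1at_rois, "MCP", "PCR-L"))
  free_rois <- setdiff(jhu_atlas()$roi, used_rois)
  named <- c("APOC2", "APOH", "HPTR", "A1AT", "A2AP", "AACT", "C1R",
             "CFAB", "CO4A", "PEDF")
  bg_proteins <- setdiff(srm_panel(), named)
  n_bg <- min(length(bg_proteins), length(free_rois))
  background <- tidyr::expand_grid(
    i = seq_len(n_bg), metric = c("AD", "RD")
  ) |>
    dplyr::mutate(
      protein = bg_proteins[.data$i],
      roi = free_rois[.data$i],
      factor = paste0("BG_", .data$protein),
      scope = "Control", r = 0.72
    ) |>
    dplyr::select(-"i")
  rest <- bg_proteins[-seq_len(n_bg)]
  background2 <- NULL
  if (length(rest) > 0) {
    background2 <- tibble::tibble(
      roi = a1at_rois,
      protein = rep_len(rest, length(a1at_rois))
    ) |>
      dplyr::mutate(factor = paste0("BG_", .data$protein), metric = "AD",
                    scope = "Control", r = 0.60)
  }
  dplyr::bind_rows(apoh, a1at, mcp, pedf, background, background2) |>
    dplyr::select("factor", "protein", "roi", "metric", "scope", "r")
}

#' Build a generator configuration
#'
#' Returns the full parameter set of the synthetic-cohort generator. The
#' defaults encode the study conditions the pipeline is designed around:
#' group sizes 16/14/12, a 43-protein panel with 1-3 peptides per protein
#' and 2-3 transitions per peptide measured in duplicate injections, Table-1
#' demographic margins, planted group effects
#' ([default_protein_effects()], [default_roi_effects()]), planted
#' transition interference, and latent-factor cross-modal couplings
#' ([default_couplings()]).
#'
#' @param group_sizes Named integer vector (Control, MA, MAP).
#' @param n_proteins Number of panel proteins (43 uses the named panel;
#'   other values generate `PROT###` labels and require empty effect lists).
#' @param peptides_per_protein,transitions_per_peptide Integer vectors the
#'   per-protein/per-peptide counts are drawn from.
#' @param replicate_count Injection replicates per subject (duplicates).
#' @param run_effect_sd SD of the per-session additive bias on the log2
#'   scale (shared by a subject's consecutive duplicate injections).
#' @param injection_drift_sd SD of the small per-injection drift that
#'   differs between duplicates (log2 scale).
#' @param transition_noise_sd SD of transition-level measurement noise
#'   (log2 scale, shared between a subject's replicates).
#' @param duplicate_cv_target Target raw-scale coefficient of variation
#'   between duplicate injections.
#' @param interference List with `n_transitions` (planted interfered
#'   transitions) and `spike_sd` (SD of the per-run uncorrelated spike on
#'   the log2 scale).
#' @param protein_effects,roi_effects,couplings Tibbles as returned by the
#'   corresponding `default_*()` helpers.
#' @param roi_cv_ad,roi_cv_rd Residual coefficients of variation of the
#'   per-subject AD and RD values around their ROI baselines.
#' @param demographics Group-wise demographic targets (see
#'   `srmdti:::default_demographics`).
#' @return A list of class `srmdti_config`.
#' @export
generator_config <- function(group_sizes = c(Control = 16, MA = 14, MAP = 12),
                             n_proteins = 43,
                             peptides_per_protein = 1:3,
                             transitions_per_peptide = 2:3,
                             replicate_count = 2,
                             run_effect_sd = 0.3,
                             injection_drift_sd = 0.03,
                             transition_noise_sd = 0.2,
                             duplicate_cv_target = 0.04,
                             interference = list(n_transitions = 10,
                                                 spike_sd = 2),
                             protein_effects = default_protein_effects(),
                             roi_effects = default_roi_effects(),
                             couplings = default_couplings(),
                             roi_cv_ad = 0.05,
                             roi_cv_rd = 0.06,
                             demographics = default_demographics()) {
  stopifnot(all(group_sizes >= 3), replicate_count >= 1,
            run_effect_sd > 0, injection_drift_sd > 0,
            transition_noise_sd > 0,
            duplicate_cv_target > 0, roi_cv_ad > 0, roi_cv_rd > 0)
  if (!setequal(names(group_sizes), c("Control", "MA", "MAP"))) {
    stop("group_sizes must be named Control, MA, MAP", call. = FALSE)
  }
  if (nrow(couplings) > 0 && any(abs(couplings$r) >= 1)) {
    stop("coupling target correlations must satisfy |r| < 1", call. = FALSE)
  }
  cfg <- list(group_sizes = group_sizes[c("Control", "MA", "MAP")],
              n_proteins = n_proteins,
              peptides_per_protein = peptides_per_protein,
              transitions_per_peptide = transitions_per_peptide,
              replicate_count = replicate_count,
              run_effect_sd = run_effect_sd,
              injection_drift_sd = injection_drift_sd,
              transition_noise_sd = transition_noise_sd,
              duplicate_cv_target = duplicate_cv_target,
              interference = interference,
              protein_effects = protein_effects,
              roi_effects = roi_effects,
              couplings = couplings,
              roi_cv_ad = roi_cv_ad,
              roi_cv_rd = roi_cv_rd,
              demographics = demographics)
  class(cfg) <- "srmdti_config"
  cfg
}

# Resolve latent-factor loadings from the coupling table. Each factor must
# admit a rank-1 decomposition r[protein, cell] = lambda_p * lambda_c.
resolve_factors <- function(couplings) {
  if (nrow(couplings) == 0) return(list())
  split(couplings, couplings$factor) |>
    lapply(function(fc) {
      fc$cell <- paste(fc$roi, fc$metric, sep = ".")
      proteins <- unique(fc$protein)
      cells <- unique(fc$cell)
      grid <- matrix(NA_real_, length(proteins), length(cells),
                     dimnames = list(proteins, cells))
      grid[cbind(fc$protein, fc$cell)] <- fc$r
      if (anyNA(grid)) {
        stop(sprintf("coupling factor '%s': incomplete protein x cell grid",
                     fc$factor[1]), call. = FALSE)
      }
      lp1 <- sqrt(max(abs(grid[1, ])))
      if (lp1 == 0) {
        stop(sprintf("coupling factor '%s': all-zero targets", fc$factor[1]),
             call. = FALSE)
      }
      lc <- setNames(grid[1, ] / lp1, cells)
      lp <- if (length(proteins) == 1) lp1 else grid[, which.max(abs(lc))] /
        lc[which.max(abs(lc))]
      lp <- setNames(as.numeric(lp), proteins)
      if (max(abs(grid - outer(lp, lc))) > 1e-8) {
        stop(sprintf(
          "coupling factor '%s': targets are not rank-1 consistent",
          fc$factor[1]), call. = FALSE)
      }
      # Single-protein factors are sourced from the protein's final signal
      # (so the realized correlation hits the target even in the presence
      # of planted group effects on that protein); multi-protein factors
      # use a shared latent score.
      list(name = fc$factor[1], scope = fc$scope[1],
           single = length(proteins) == 1,
           protein_loadings = lp, cell_loadings = lc,
           cell_targets = setNames(grid[1, ], cells))
    }) |>
    unname()
}

scope_mask <- function(scope, group) {
  switch(scope,
         all = rep(TRUE, length(group)),
         "MA+MAP" = group %in% c("MA", "MAP"),
         group == scope)
}

# Exact-count binary assignment within each group.
assign_counts <- function(group, counts) {
  out <- integer(length(group))
  for (g in names(counts)) {
    idx <- which(group == g)
    ones <- sample(idx, counts[[g]])
    out[ones] <- 1L
  }
  out
}

build_cohort_table <- function(cfg) {
  dem <- cfg$demographics
  group <- factor(rep(names(cfg$group_sizes), cfg$group_sizes),
                  levels = c("Control", "MA", "MAP"))
  n <- length(group)
  subject <- sprintf("S%02d", seq_len(n))
  draw <- function(mean, sd, lo, digits = 1) {
    x <- rnorm(n, mean[as.character(group)], sd[as.character(group)])
    round(pmax(x, lo), digits)
  }
  cohort <- tibble::tibble(
    subject = subject,
    group = group,
    age = draw(dem$age_mean, dem$age_sd, 16),
    gender = factor(ifelse(assign_counts(group, dem$gender_male) == 1,
                           "M", "F"), levels = c("F", "M")),
    education_years = draw(dem$education_mean, dem$education_sd, 6),
    nicotine = assign_counts(group, dem$nicotine),
    cannabis = assign_counts(group, dem$cannabis),
    alcohol = assign_counts(group, dem$alcohol),
    mandrax = assign_counts(group, dem$mandrax),
    epqrs_psychoticism = draw(dem$epqrs_psychoticism_mean,
                              dem$epqrs_psychoticism_sd, 0, 0),
    epqrs_extraversion = draw(dem$epqrs_extraversion_mean,
                              dem$epqrs_extraversion_sd, 0, 0),
    epqrs_neuroticism = draw(dem$epqrs_neuroticism_mean,
                             dem$epqrs_neuroticism_sd, 0, 0),
    epqrs_total = draw(dem$epqrs_total_mean, dem$epqrs_total_sd, 0, 0)
  )
  map_idx <- cohort$group == "MAP"
  pn <- dem$panss
  cohort$panss_positive <- NA_real_
  cohort$panss_negative <- NA_real_
  cohort$panss_total <- NA_real_
  cohort$panss_positive[map_idx] <-
    round(pmax(rnorm(sum(map_idx), pn["positive_mean"], pn["positive_sd"]), 7))
  cohort$panss_negative[map_idx] <-
    round(pmax(rnorm(sum(map_idx), pn["negative_mean"], pn["negative_sd"]), 7))
  cohort$panss_total[map_idx] <-
    round(pmax(rnorm(sum(map_idx), pn["total_mean"], pn["total_sd"]), 30))
  cohort
}

# Latent factor scores: one N(0,1) value per factor per subject, used only
# inside the factor's scope.
draw_factor_scores <- function(factors, n) {
  if (length(factors) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  m <- matrix(rnorm(n * length(factors)), nrow = n)
  colnames(m) <- vapply(factors, `[[`, character(1), "name")
  m
}

build_protein_signals <- function(cfg, cohort, proteins, factors, scores) {
  n <- nrow(cohort)
  # Per-protein loadings across factors.
  sig <- matrix(rnorm(n * length(proteins)), nrow = n,
                dimnames = list(cohort$subject, proteins))
  for (p in proteins) {
    lam2 <- rep(0, n)
    contrib <- rep(0, n)
    for (k in seq_along(factors)) {
      f <- factors[[k]]
      if (f$single || !p %in% names(f$protein_loadings)) next
      lam <- f$protein_loadings[[p]]
      mask <- scope_mask(f$scope, cohort$group)
      lam2[mask] <- lam2[mask] + lam^2
      contrib[mask] <- contrib[mask] + lam * scores[mask, k]
    }
    if (any(lam2 > 0.95)) {
      stop(sprintf(
        "infeasible coupling targets for protein %s (summed loading^2 = %.2f)",
        p, max(lam2)), call. = FALSE)
    }
    sig[, p] <- sqrt(1 - lam2) * sig[, p] + contrib
  }
  # Planted group effects.
  pe <- cfg$protein_effects
  if (nrow(pe) > 0) {
    unknown <- setdiff(pe$protein, proteins)
    if (length(unknown) > 0) {
      stop("protein_effects references unknown protein(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(pe))) {
      idx <- cohort$group == pe$group[i]
      sig[idx, pe$protein[i]] <-
        sig[idx, pe$protein[i]] * pe$sd_scale[i] + pe$shift[i]
    }
  }
  sig
}

build_roi_values <- function(cfg, cohort, factors, scores, signals) {
  atlas <- jhu_atlas()
  n <- nrow(cohort)
  # Deterministic atlas-like baselines (mm^2/s).
  frac1 <- ((atlas$index * 7) %% 48) / 47
  frac2 <- ((atlas$index * 13) %% 48) / 47
  ad_base <- (1.1 + 0.5 * frac1) * 1e-3
  rd_base <- ad_base * (0.35 + 0.30 * frac2)
  cell_loadings <- function(roi, metric) {
    lam2 <- rep(0, n)
    contrib <- rep(0, n)
    cell <- paste(roi, metric, sep = ".")
    for (k in seq_along(factors)) {
      f <- factors[[k]]
      if (!cell %in% names(f$cell_loadings)) next
      mask <- scope_mask(f$scope, cohort$group)
      if (f$single) {
        # weight is the target correlation itself; source is the final
        # (post-group-effect) protein signal, standardized within scope
        lam <- f$cell_targets[[cell]]
        src <- signals[, names(f$protein_loadings)]
        src_sc <- src[mask]
        if (sd(src_sc) == 0) {
          stop(sprintf("coupling factor '%s': constant protein signal",
                       f$name), call. = FALSE)
        }
        source <- (src - mean(src_sc)) / sd(src_sc)
      } else {
        lam <- f$cell_loadings[[cell]]
        source <- scores[, k]
      }
      lam2[mask] <- lam2[mask] + lam^2
      contrib[mask] <- contrib[mask] + lam * source[mask]
    }
    if (any(lam2 > 0.75)) {
      stop(sprintf(
        "infeasible coupling targets for ROI cell %s (summed loading^2 = %.2f)",
        cell, max(lam2)), call. = FALSE)
    }
    list(lam2 = lam2, contrib = contrib)
  }
  re <- cfg$roi_effects
  out <- vector("list", nrow(atlas))
  for (j in seq_len(nrow(atlas))) {
    roi <- atlas$roi[j]
    s_roi <- rnorm(n)  # shared subject factor: AD-RD correlation 0.5
    z <- list()
    for (metric in c("AD", "RD")) {
      cl <- cell_loadings(roi, metric)
      eps <- rnorm(n)
      z[[metric]] <- 0.5 * s_roi + sqrt(0.75 - cl$lam2) * eps + cl$contrib
      if (nrow(re) > 0) {
        hits <- re[re$roi == roi & re$metric == metric, ]
        for (i in seq_len(nrow(hits))) {
          idx <- cohort$group == hits$group[i]
          z[[metric]][idx] <- z[[metric]][idx] + hits$shift[i]
        }
      }
    }
    ad <- ad_base[j] * (1 + cfg$roi_cv_ad * z$AD)
    rd <- rd_base[j] * (1 + cfg$roi_cv_rd * z$RD)
    ad <- pmax(ad, 1e-5)
    rd <- pmin(pmax(rd, 1e-6), 0.97 * ad)  # physical ordering AD >= RD
    md <- (ad + 2 * rd) / 3
    fa <- (ad - rd) / sqrt(ad^2 + 2 * rd^2)
    out[[j]] <- tibble::tibble(
      subject = rep(cohort$subject, 4),
      roi = roi,
      metric = rep(c("FA", "MD", "AD", "RD"), each = n),
      value = c(fa, md, ad, rd)
    )
  }
  dplyr::bind_rows(out)
}

build_transitions <- function(cfg, cohort, signals) {
  proteins <- colnames(signals)
  n <- nrow(cohort)
  npep <- sample(cfg$peptides_per_protein, length(proteins), replace = TRUE)
  layout <- purrr::map2_dfr(proteins, npep, function(p, k) {
    pep <- sprintf("%s.pep%d", p, seq_len(k))
    ntr <- sample(cfg$transitions_per_peptide, k, replace = TRUE)
    tibble::tibble(protein = p,
                   peptide = rep(pep, ntr),
                   transition = unlist(lapply(seq_len(k), function(i) {
                     sprintf("%s.t%d", pep[i], seq_len(ntr[i]))
                   })))
  })
  layout$mu <- runif(nrow(layout), 12, 24)

  # Interference: at most one planted transition per protein, drawn from
  # multi-transition peptides of multi-peptide proteins without planted
  # group effects, so every protein keeps a clean peptide.
  interfered <- character(0)
  n_int <- cfg$interference$n_transitions %||% 0
  if (n_int > 0) {
    pep_sizes <- dplyr::count(layout, .data$protein, .data$peptide)
    eligible <- layout |>
      dplyr::add_count(.data$protein, .data$peptide, name = "pep_size") |>
      dplyr::group_by(.data$protein) |>
      dplyr::mutate(n_pep = dplyr::n_distinct(.data$peptide)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$pep_size >= 2, .data$n_pep >= 2,
                    !.data$protein %in% cfg$protein_effects$protein)
    pick_proteins <- sample(unique(eligible$protein),
                            min(n_int, dplyr::n_distinct(eligible$protein)))
    if (length(pick_proteins) < n_int) {
      warning(sprintf("only %d of %d requested interfered transitions placed",
                      length(pick_proteins), n_int), call. = FALSE)
    }
    interfered <- eligible |>
      dplyr::filter(.data$protein %in% pick_proteins) |>
      dplyr::group_by(.data$protein) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::pull("transition")
  }

  # Between-run bias: a session component shared by a subject's duplicate
  # injections (samples are injected back to back) plus a small
  # per-injection drift.
  session <- tibble::tibble(subject = cohort$subject,
                            session_effect = rnorm(nrow(cohort), 0,
                                                   cfg$run_effect_sd))
  runs <- tidyr::expand_grid(subject = cohort$subject,
                             replicate = seq_len(cfg$replicate_count)) |>
    dplyr::left_join(session, by = "subject")
  runs$run_effect <- runs$session_effect +
    rnorm(nrow(runs), 0, cfg$injection_drift_sd)
  runs$session_effect <- NULL

  long <- tidyr::expand_grid(layout, subject = cohort$subject)
  long$signal <- signals[cbind(long$subject, long$protein)]
  long$tnoise <- rnorm(nrow(long), 0, cfg$transition_noise_sd)
  long <- tidyr::expand_grid(long, replicate = seq_len(cfg$replicate_count)) |>
    dplyr::left_join(runs, by = c("subject", "replicate"))
  dup_sd <- cfg$duplicate_cv_target / log(2)
  long$dup <- rnorm(nrow(long), 0, dup_sd)
  long$spike <- 0
  if (length(interfered) > 0) {
    hit <- long$transition %in% interfered
    long$spike[hit] <- rnorm(sum(hit), 0, cfg$interference$spike_sd)
  }
  long$intensity <- 2^(long$mu + long$signal + long$tnoise +
                         long$run_effect + long$dup + long$spike)
  transitions <- long |>
    dplyr::select("protein", "peptide", "transition", "subject",
                  "replicate", "intensity") |>
    dplyr::arrange(.data$protein, .data$peptide, .data$transition,
                   .data$subject, .data$replicate)
  list(transitions = set_transition_scale(transitions, "raw"),
       interfered = sort(interfered))
}

#' Generate a synthetic multi-modal cohort
#'
#' Produces a full synthetic data set (transition-level SRM table, subject
#' covariates with psychometrics, tidy ROI diffusion table) together with
#' the ground truth of everything that was planted. Output is deterministic
#' for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return A list of class `srmdti_cohort` with elements `transitions`,
#'   `cohort`, `roi`, `psychometrics` (long form) and `truth`. `truth`
#'   carries `protein_signals` (subject x protein tibble of true signals),
#'   `interfered_transitions`, `differential_proteins`,
#'   `affected_roi_cells` (planted RD cells plus the derived MD cells) and
#'   `couplings`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' dplyr::count(cohort$cohort, group)
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "srmdti_config"))
  with_seed(seed, {
    proteins <- if (config$n_proteins == 43) {
      srm_panel()
    } else {
      sprintf("PROT%03d", seq_len(config$n_proteins))
    }
    factors <- resolve_factors(config$couplings)
    if (nrow(config$couplings) > 0) {
      unknown <- setdiff(config$couplings$protein, proteins)
      if (length(unknown) > 0) {
        stop("couplings reference unknown protein(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
    cohort <- build_cohort_table(config)
    scores <- draw_factor_scores(factors, nrow(cohort))
    signals <- build_protein_signals(config, cohort, proteins, factors,
                                     scores)
    roi <- build_roi_values(config, cohort, factors, scores, signals)
    trn <- build_transitions(config, cohort, signals)
    psychometrics <- cohort |>
      dplyr::select("subject", dplyr::starts_with("epqrs"),
                    dplyr::starts_with("panss")) |>
      tidyr::pivot_longer(-"subject", names_to = "measure",
                          values_to = "value") |>
      dplyr::filter(!is.na(.data$value))
    affected <- config$roi_effects |>
      dplyr::filter(.data$metric == "RD") |>
      dplyr::distinct(.data$roi) |>
      tidyr::expand_grid(metric = c("RD", "MD")) |>
      dplyr::select("roi", "metric")
    truth <- list(
      protein_signals = tibble::as_tibble(signals) |>
        dplyr::mutate(subject = cohort$subject, .before = 1),
      interfered_transitions = trn$interfered,
      differential_proteins = config$protein_effects,
      affected_roi_cells = affected,
      couplings = config$couplings,
      seed = seed
    )
    structure(list(transitions = trn$transitions, cohort = cohort,
                   roi = roi, psychometrics = psychometrics, truth = truth,
                   config = config),
              class = "srmdti_cohort")
  })
}

#' Generate a null cohort (no planted structure)
#'
#' Same generative process as [generate_cohort()] with every effect list
#' emptied: no protein or ROI group effects, no cross-modal couplings and
#' no planted interference. Used for type-I-error suites.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()]; all `truth` effect lists are empty.
#' @export
null_cohort <- function(config = generator_config(), seed = 1) {
  config$protein_effects <- default_protein_effects()[0, ]
  config$roi_effects <- default_roi_effects()[0, ]
  config$couplings <- default_couplings()[0, ]
  config$interference$n_transitions <- 0
  generate_cohort(config, seed = seed)
}

#' @export
print.srmdti_cohort <- function(x, ...) {
  cat("Synthetic multi-modal cohort (seed ", x$truth$seed, ")\n", sep = "")
  cat("  subjects:   ", nrow(x$cohort), " (",
      paste(table(x$cohort$group), collapse = "/"), ")\n", sep = "")
  cat("  transitions:", dplyr::n_distinct(x$transitions$transition),
      "over", nrow(x$transitions), "rows\n")
  cat("  ROI cells:  ", dplyr::n_distinct(x$roi$roi), "ROIs x",
      dplyr::n_distinct(x$roi$metric), "metrics\n")
  cat("  planted:    ", nrow(x$truth$differential_proteins), "protein effects,",
      nrow(x$truth$affected_roi_cells), "ROI cells,",
      length(x$truth$interfered_transitions), "interfered transitions\n")
  invisible(x)
}
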