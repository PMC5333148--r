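# Cross-modal correlation screen, influence diagnostics, stratification
# and the sign-test comparison.

small_assoc_setup <- function(seed = 20, n = 20) {
  withr::with_seed(seed, {
    pm_mat <- matrix(rnorm(3 * n), nrow = 3)
    roi_vals <- list(
      FA = matrix(rnorm(n * 2, 0.5, 0.05), nrow = n),
      RD = matrix(rnorm(n * 2, 6e-4, 5e-5), nrow = n)
    )
  })
  co <- make_cohort(c(Control = n))
  rois <- jhu_atlas()$roi[1:2]
  roi <- dplyr::bind_rows(lapply(names(roi_vals), function(metric) {
    mm <- roi_vals[[metric]]
    dplyr::bind_rows(lapply(1:2, function(j) tibble::tibble(
      subject = sprintf("S%d", seq_len(n)), roi = rois[j],
      metric = metric, value = mm[, j])))
  }))
  list(pm = make_protein_matrix(pm_mat), roi = roi, co = co)
}

test_that("cross-modal screen recovers exact and affine-invariant r", {
  s <- small_assoc_setup()
  # protein identical to an ROI metric vector: r = 1, p below any cutoff
  roi1 <- s$roi$value[s$roi$roi == jhu_atlas()$roi[1] &
                        s$roi$metric == "FA"]
  pm <- s$pm
  pm[1, -1] <- as.list(roi1)
  g <- crossmodal_correlate(pm, s$roi, s$co, scope = "Control")
  hit <- g[g$protein == "P1" & g$metric == "FA" &
             g$roi == jhu_atlas()$roi[1], ]
  expect_equal(hit$r, 1, tolerance = 1e-12)
  expect_true(hit$bonferroni && hit$nominal)

  # affine transform of either side leaves |r| and p unchanged
  pm2 <- s$pm
  pm2[2, -1] <- as.list(3 - 2 * as.numeric(s$pm[2, -1]))
  g0 <- crossmodal_correlate(s$pm, s$roi, s$co, scope = "Control")
  g2 <- crossmodal_correlate(pm2, s$roi, s$co, scope = "Control")
  expect_equal(abs(g2$r[g2$protein == "P2"]),
               abs(g0$r[g0$protein == "P2"]), tolerance = 1e-10)
  expect_equal(g2$p[g2$protein == "P2"], g0$p[g0$protein == "P2"],
               tolerance = 1e-10)

  # Bonferroni-significant implies nominal (nesting)
  expect_true(all(!g0$bonferroni | g0$nominal))

  # p-values match the exact t transform recomputed directly
  r <- g0$r[5]; n <- g0$n[5]
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(g0$p[5], 2 * pt(-abs(t), n - 2), tolerance = 1e-12)

  # constant vector is skipped with a warning
  pmc <- s$pm
  pmc[3, -1] <- as.list(rep(1, 20))
  expect_warning(gc <- crossmodal_correlate(pmc, s$roi, s$co,
                                            scope = "Control"),
                 "constant")
  expect_false("P3" %in% gc$protein)
})

test_that("influence screen flags single-point-driven correlations", {
  # perfectly collinear points are never flagged
  x <- 1:10
  res <- influence_screen(x, 2 * x + 1)
  expect_false(res$influence_flag)
  expect_equal(res$r, 1)

  # 15 null points plus one extreme point manufacturing r ~ 0.7
  withr::with_seed(22, {
    x2 <- c(rnorm(15), 8)
    y2 <- c(rnorm(15), 8)
  })
  expect_gt(cor(x2, y2), 0.6)
  res2 <- influence_screen(x2, y2)
  expect_true(res2$influence_flag)
  # direct recomputation without the extreme point kills significance
  expect_gte(pearson_p_direct(cor(x2[-16], y2[-16]), 15), 0.05)

  # the reported extreme is among the leave-one-out values
  loo <- vapply(seq_along(x2), function(i) cor(x2[-i], y2[-i]), numeric(1))
  expect_true(any(abs(loo - res2$r_loo_extreme) < 1e-12))

  expect_error(influence_screen(1:4, 1:4), "at least 5")
})

test_that("influence screen is stable for strong correlations at n >= 30", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      u <- rnorm(30)
      x <- u + rnorm(30, 0, 0.2)
      y <- u + rnorm(30, 0, 0.2)
    })
    stopifnot(abs(cor(x, y)) >= 0.9)
    expect_false(influence_screen(x, y)$influence_flag)
  }
})

test_that("grid influence flags agree with the scalar screen", {
  s <- small_assoc_setup(seed = 23)
  # guarantee nominal hits: protein 1 partially tracks one ROI vector
  roi1 <- s$roi$value[s$roi$roi == jhu_atlas()$roi[1] &
                        s$roi$metric == "FA"]
  s$pm[1, -1] <- as.list(scale(roi1)[, 1] +
                           withr::with_seed(25, rnorm(20, 0, 0.8)))
  g <- crossmodal_correlate(s$pm, s$roi, s$co, scope = "Control")
  expect_gte(sum(g$nominal), 1)
  subj <- sprintf("S%d", 1:20)
  for (k in which(g$nominal)) {
    x <- as.numeric(s$pm[s$pm$protein == g$protein[k], subj])
    y <- s$roi$value[s$roi$roi == g$roi[k] & s$roi$metric == g$metric[k]]
    y <- y[match(subj, s$roi$subject[s$roi$roi == g$roi[k] &
                                       s$roi$metric == g$metric[k]])]
    sc <- influence_screen(x, y)
    expect_equal(g$influence_flag[k], sc$influence_flag)
    expect_equal(g$r_loo_extreme[k], sc$r_loo_extreme, tolerance = 1e-12)
  }
})

test_that("p-value stratification counts nested strata", {
  g <- tibble::tibble(protein = "P1", roi = "MCP", metric = "FA",
                      scope = "all", p = c(0.04, 0.009, 0.0005),
                      r = 0.1, n = 20)
  st <- stratify_pvalues(g)
  expect_equal(st$count, c(3, 2, 1))

  # empty grid: all counts zero
  st0 <- stratify_pvalues(g[0, ])
  expect_true(all(st0$count == 0))

  # unsorted cutoffs sorted with warning
  expect_warning(st1 <- stratify_pvalues(g, cutoffs = c(0.001, 0.05, 0.01)),
                 "sort")
  expect_equal(st1$cutoff, c(0.05, 0.01, 0.001))

  # brute-force count agreement on a random grid
  withr::with_seed(24, gr <- tibble::tibble(
    protein = "P1", roi = "MCP", metric = "FA", scope = "all",
    p = runif(200)))
  st2 <- stratify_pvalues(gr)
  for (i in seq_len(nrow(st2))) {
    expect_equal(st2$count[i], sum(gr$p < st2$cutoff[i]))
  }
  expect_true(all(diff(st2$count) <= 0))
})

test_that("sign test matches the closed-form binomial", {
  base <- tidyr::expand_grid(protein = sprintf("P%d", 1:20),
                             roi = "MCP", metric = "FA")
  mk <- function(p) dplyr::mutate(base, scope = "x", p = p, r = 0, n = 10)
  # identical grids: all ties, p = 1
  g <- mk(rep(0.5, 20))
  expect_warning(st <- compare_association_counts(g, g), "ties")
  expect_equal(st$p, 1)

  # control ahead in 20 of 20 units: p = 2 * 0.5^20
  st2 <- compare_association_counts(mk(rep(0.01, 20)), mk(rep(0.5, 20)))
  expect_equal(st2$wins_control, 20)
  expect_equal(st2$p, 2 * 0.5^20, tolerance = 1e-12)

  # random grids match the enumeration oracle
  for (seed in 1:5) {
    withr::with_seed(seed, {
      gc <- mk(runif(20, 0, 0.15))
      gp <- mk(runif(20, 0, 0.15))
    })
    st3 <- compare_association_counts(gc, gp)
    m <- st3$wins_control + st3$wins_patient
    expect_equal(st3$p, oracle_sign_p(st3$wins_control, m),
                 tolerance = 1e-12)
  }

  # mismatched universes are rejected
  g2 <- mk(rep(0.5, 20)); g2$roi <- "PCT"
  expect_error(compare_association_counts(g, g2), "universe")
})

test_that("control-only couplings appear in the control scope only", {
  ch <- generate_cohort(seed = 9)
  pre <- suppressWarnings(preprocess_srm(ch$transitions))
  pm <- pre$protein_matrix
  g_ctl <- crossmodal_correlate(pm, ch$roi, ch$cohort, scope = "Control",
                                influence = FALSE)
  g_pat <- crossmodal_correlate(pm, ch$roi, ch$cohort, scope = "MA+MAP",
                                influence = FALSE)
  # A1AT-RD planted couplings: stronger in controls than pooled patients
  pl <- ch$truth$couplings
  a1 <- pl[pl$protein == "A1AT" & pl$metric == "RD", ]
  key <- paste(a1$protein, a1$roi, a1$metric)
  rc <- g_ctl$r[match(key, paste(g_ctl$protein, g_ctl$roi, g_ctl$metric))]
  rp <- g_pat$r[match(key, paste(g_pat$protein, g_pat$roi, g_pat$metric))]
  expect_gt(mean(rc), 0.35)
  expect_lt(mean(abs(rp)), 0.25)

  # all-subject APOH fornix coupling is recovered near its target
  apoh <- crossmodal_correlate(pm, ch$roi, ch$cohort, scope = "all",
                               influence = FALSE)
  r_fx <- apoh$r[apoh$protein == "APOH" & apoh$roi == "FX" &
                   apoh$metric == "RD"]
  expect_lt(abs(r_fx - (-0.50)), 0.25)
})
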