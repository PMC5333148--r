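# Covariate-adjusted group statistics and the cohort demographic tests.

test_that("binary-trait statistic equals (N-1)/N chi-squared (oracle sweep)", {
  # exhaustive small tables: 3 groups, positives 0..4 of totals 4..6
  totals <- c(4, 5, 6)
  for (a in 0:4) for (b in 0:4) for (c in 0:4) {
    tab <- cbind(c(a, b, c), totals - c(a, b, c))
    if (any(colSums(tab) == 0)) next
    got <- categorical_group_test(tab)
    expect_equal(got$statistic,
                 (sum(tab) - 1) / sum(tab) * oracle_chisq(tab),
                 tolerance = 1e-12)
    expect_equal(got$df, 2)
  }
})

test_that("binary-trait statistic matches Kruskal-Wallis on the indicator", {
  counts <- c(5, 2, 1); totals <- c(16, 14, 12)
  x <- unlist(mapply(function(k, n) c(rep(1, k), rep(0, n - k)),
                     counts, totals))
  g <- factor(rep(1:3, totals))
  kw <- kruskal.test(x, g)
  got <- categorical_group_test(counts, totals = totals)
  expect_equal(got$statistic, unname(kw$statistic), tolerance = 1e-12)
  expect_equal(got$p, kw$p.value, tolerance = 1e-12)
})

test_that("degenerate and equal-proportion contingency tables are handled", {
  expect_warning(res <- categorical_group_test(c(0, 0, 0),
                                               totals = c(5, 5, 5)),
                 "constant")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  eq <- categorical_group_test(c(2, 2, 2), totals = c(4, 4, 4))
  expect_equal(eq$statistic, 0)

  # plain chi-squared option
  tab <- cbind(c(5, 2, 1), c(11, 12, 11))
  expect_equal(categorical_group_test(tab, method = "chisq")$statistic,
               oracle_chisq(tab), tolerance = 1e-12)
})

test_that("Tukey machinery: k = 2 collapse, monotonicity, affine invariance", {
  pm <- make_protein_matrix(matrix(rnorm(30, 0, 1), nrow = 1))
  co <- make_cohort(c(Control = 15, MA = 15))
  withr::with_seed(1, {
    da2 <- differential_abundance(pm, co,
                                  covariates = character(0), alpha = 0.05)
  })
  ct <- da2$contrasts
  # two groups: single contrast, Tukey-adjusted p equals the raw t-test p
  expect_equal(nrow(ct), 1)
  tt <- t.test(as.numeric(pm[1, co$subject[co$group == "MA"]]),
               as.numeric(pm[1, co$subject[co$group == "Control"]]),
               var.equal = TRUE)
  expect_equal(ct$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(ct$p_raw, tt$p.value, tolerance = 1e-10)

  # three groups: adjusted >= raw, and adjusted p monotone in |t|
  withr::with_seed(2, m <- matrix(rnorm(5 * 42), nrow = 5))
  m[2, 1:16] <- m[2, 1:16] + 2
  pm3 <- make_protein_matrix(m)
  co3 <- make_cohort()
  da3 <- suppressWarnings(differential_abundance(pm3, co3))
  ct3 <- da3$contrasts
  expect_true(all(ct3$p_adj >= ct3$p_raw - 1e-6))
  ord <- order(abs(ct3$statistic))
  expect_true(all(diff(ct3$p_adj[ord]) <= 1e-6))

  # affine rescaling of a protein leaves t statistics unchanged
  m2 <- m
  m2[3, ] <- 5 + 7 * m2[3, ]
  da3b <- suppressWarnings(differential_abundance(make_protein_matrix(m2),
                                                  co3))
  expect_equal(da3b$contrasts$statistic[da3b$contrasts$protein == "P3"],
               ct3$statistic[ct3$protein == "P3"], tolerance = 1e-8)
  expect_equal(da3b$proteins$omnibus_p[3], da3$proteins$omnibus_p[3],
               tolerance = 1e-8)
})

test_that("planted MAP shift at study group sizes is detected", {
  # 2-residual-SD MAP shift, n = 16/14/12: both MAP contrasts significant
  hits <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      co <- make_cohort()
      y <- rnorm(42) + 2 * (co$group == "MAP")
    })
    pm <- make_protein_matrix(matrix(y, nrow = 1))
    da <- differential_abundance(pm, co)
    ct <- da$contrasts
    all(ct$p_adj[ct$contrast %in% c("MAP-Control", "MAP-MA")] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("constant covariates are dropped with a warning", {
  co <- make_cohort()
  co$mandrax <- 0L
  pm <- make_protein_matrix(matrix(rnorm(42), nrow = 1))
  expect_warning(da <- differential_abundance(pm, co), "mandrax")
  expect_false("mandrax" %in% da$covariates_used)
})

test_that("variance fractions are normalized and find planted structure", {
  co <- make_cohort()
  withr::with_seed(4, {
    noise <- matrix(rnorm(3 * 42, 0, 1), nrow = 3)
  })
  # protein 2 is the gender indicator plus tiny noise
  noise[2, ] <- as.numeric(co$gender == "M") +
    withr::with_seed(5, rnorm(42, 0, 0.02))
  vf <- variance_fractions(make_protein_matrix(noise), co)
  sums <- tapply(vf$fraction, vf$protein, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(vf$fraction >= -1e-12))
  expect_gt(vf$fraction[vf$protein == "P2" & vf$term == "gender"], 0.9)
  # pure-noise protein: residual dominates
  expect_gt(vf$fraction[vf$protein == "P1" & vf$term == "residual"], 0.5)
})

test_that("normality gate picks ANOVA or Kruskal-Wallis correctly", {
  g <- factor(rep(c("a", "b", "c"), each = 12))
  withr::with_seed(6, vals <- rnorm(36) + 2 * (g == "c"))
  res <- demographic_group_test(vals, g)
  expect_equal(res$method, "anova")
  expect_equal(res$shapiro_p,
               shapiro.test(residuals(lm(vals ~ g)))$p.value)
  expect_lt(res$p, 0.01)

  # heavy-tailed data routes to Kruskal-Wallis
  withr::with_seed(7, heavy <- rcauchy(36))
  res2 <- demographic_group_test(heavy, g)
  expect_equal(res2$method, "kruskal")
  expect_equal(res2$statistic,
               unname(kruskal.test(heavy, g)$statistic))

  # identical distributions across groups: KW statistic 0, p 1
  same <- rep(c(1, 2, 3), 12)
  res3 <- demographic_group_test(same, g)
  if (res3$method == "kruskal") {
    expect_equal(res3$statistic, 0)
    expect_equal(res3$p, 1)
  }
  expect_error(demographic_group_test(rep(1, 36), g), "constant")
})

test_that("psychometric screen respects ranks and degenerate inputs", {
  co <- make_cohort()
  withr::with_seed(8, neuro <- sample(0:12, 42, replace = TRUE))
  co$epqrs_neuroticism <- neuro
  co$epqrs_extraversion <- 7L
  co$epqrs_psychoticism <- withr::with_seed(9, sample(0:12, 42, TRUE))
  # protein 1 is a monotone transform of neuroticism -> rho = 1
  pm <- make_protein_matrix(rbind(exp(neuro / 3)))
  res <- suppressWarnings(psychometric_correlation(pm, co))
  r1 <- res[res$score == "epqrs_neuroticism", ]
  expect_equal(r1$rho, 1)
  expect_true(r1$bonferroni && r1$nominal)
  # constant score skipped with warning
  expect_warning(psychometric_correlation(pm, co), "extraversion")
  expect_false("epqrs_extraversion" %in% res$score)
})
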