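# Transition-level QC: log2 transform, run normalization, interference and
# CV filters, eigengene summarisation, outlier screen.

test_that("log2 transform maps known intensities and rejects bad input", {
  tr <- make_transitions(list(pep1 = rbind(c(8, 1, 10), c(2, 4, 16))))
  lg <- log2_transform(tr)
  expect_equal(lg$intensity[lg$transition == "pep1.t1"],
               c(3, 0, log(10) / log(2)))
  expect_error(log2_transform(lg), "already log2")

  bad <- tr
  bad$intensity[2] <- -1
  expect_error(log2_transform(bad), "pep1.t1")
})

test_that("run normalization equalizes medians, preserves ranks, idempotent", {
  # two runs with medians 10 and 12 -> both shifted to the global median 11
  m <- rbind(c(9, 11), c(10, 12), c(11, 13))
  tr <- make_transitions(list(pep1 = m))
  attr(tr, "srm_scale") <- "log2"
  nm <- normalize_runs(tr)
  med <- tapply(nm$intensity, nm$subject, median)
  expect_equal(as.numeric(med[c("S1", "S2")]), c(11, 11))

  # already-equal medians: unchanged
  again <- normalize_runs(nm)
  expect_equal(again$intensity, nm$intensity)

  # random 5-transition x 4-run table: medians equal by direct recomputation
  withr::with_seed(11, {
    m2 <- matrix(rnorm(20, 15, 2), nrow = 5)
  })
  tr2 <- make_transitions(list(pep1 = m2))
  attr(tr2, "srm_scale") <- "log2"
  nm2 <- normalize_runs(tr2)
  meds <- vapply(split(nm2$intensity, nm2$subject), median, numeric(1))
  expect_true(max(meds) - min(meds) < 1e-12)
  # within-run rank order preserved
  for (s in unique(nm2$subject)) {
    expect_equal(order(nm2$intensity[nm2$subject == s]),
                 order(tr2$intensity[tr2$subject == s]))
  }

  # run with no usable transitions is named
  tr3 <- tr2
  tr3$intensity[tr3$subject == "S3"] <- NA
  expect_error(normalize_runs(tr3), "S3")
})

test_that("interference score matches hand-built cases and Pearson oracle", {
  # transition equal to the others' mean plus a constant -> score 1
  base <- c(10, 12, 11, 13)
  m <- rbind(base + 2, base, base)
  tr <- as_normalized(make_transitions(list(pep1 = m)))
  expect_equal(interference_score(tr, "pep1.t1"), 1)

  # transition equal to the negated (centered) reference -> score -1
  m2 <- rbind(mean(base) - (base - mean(base)), base, base)
  tr2 <- as_normalized(make_transitions(list(pep1 = m2)))
  expect_equal(interference_score(tr2, "pep1.t1"), -1)

  # 4-run peptide, 3 transitions, one spiked in one run: spiked scores
  # lowest; every score equals the textbook Pearson computation
  withr::with_seed(5, {
    clean <- matrix(rep(base, each = 3), nrow = 3) +
      matrix(rnorm(12, 0, 0.05), nrow = 3)
  })
  spiked <- clean
  spiked[1, 2] <- spiked[1, 2] + 5
  tr3 <- as_normalized(make_transitions(list(pep1 = spiked)))
  scores <- vapply(sprintf("pep1.t%d", 1:3),
                   function(t) interference_score(tr3, t), numeric(1))
  expect_lt(scores[1], min(scores[2:3]))
  for (i in 1:3) {
    loo <- colMeans(spiked[-i, , drop = FALSE])
    expect_equal(unname(scores[i]), oracle_pearson(spiked[i, ], loo),
                 tolerance = 1e-12)
  }

  # degenerate inputs
  single <- as_normalized(make_transitions(list(pep1 = m[1, , drop = FALSE])))
  expect_error(interference_score(single, "pep1.t1"), "single transition")
  short <- as_normalized(make_transitions(list(pep1 = m[, 1:2])))
  expect_error(interference_score(short, "pep1.t1"), "3 paired runs")
})

test_that("interference score survives run constants and affine rescaling", {
  withr::with_seed(21, {
    m <- matrix(rnorm(24, 15, 1), nrow = 3) +
      rep(rnorm(8, 0, 0.5), each = 3)  # run effects
  })
  tr <- make_transitions(list(pep1 = m))
  attr(tr, "srm_scale") <- "log2"
  s0 <- vapply(sprintf("pep1.t%d", 1:3), function(t)
    interference_score(normalize_runs(tr), t), numeric(1))

  # add a constant to all intensities of one run, then renormalize
  tr2 <- tr
  tr2$intensity[tr2$subject == "S3"] <- tr2$intensity[tr2$subject == "S3"] + 7
  s1 <- vapply(sprintf("pep1.t%d", 1:3), function(t)
    interference_score(normalize_runs(tr2), t), numeric(1))
  expect_equal(s1, s0, tolerance = 1e-10)

  # positive affine rescaling of one transition leaves its score unchanged
  nm <- normalize_runs(tr)
  tr3 <- nm
  sel <- tr3$transition == "pep1.t2"
  tr3$intensity[sel] <- 3 + 2 * tr3$intensity[sel]
  expect_equal(interference_score(tr3, "pep1.t2"),
               interference_score(nm, "pep1.t2"), tolerance = 1e-12)
})

test_that("interference filter honors thresholds and logs exclusions", {
  base <- c(10, 12, 11, 13, 9, 14)
  withr::with_seed(31, {
    m <- matrix(rep(base, each = 3), nrow = 3) +
      matrix(rnorm(18, 0, 0.05), nrow = 3)
  })
  tr <- as_normalized(make_transitions(list(pep1 = m)))
  # all scores high: table unchanged, empty exclusion set
  fi <- filter_interference(tr, threshold = 0.8)
  expect_equal(sum(fi$report$excluded), 0)
  expect_equal(nrow(fi$transitions), nrow(tr))

  # threshold 1: every noisy transition is excluded
  fi2 <- suppressWarnings(filter_interference(tr, threshold = 1.0))
  expect_true(all(fi2$report$excluded))
  expect_equal(nrow(fi2$transitions), 0)

  # rerunning the filter on its own output is rejected
  expect_error(filter_interference(fi$transitions), "already")
})

test_that("planted interference is recovered on the synthetic cohort", {
  ch <- generate_cohort(seed = 42)
  nm <- normalize_runs(log2_transform(ch$transitions))
  fi <- filter_interference(nm)
  planted <- ch$truth$interfered_transitions
  hit <- sum(fi$report$excluded & fi$report$transition %in% planted)
  expect_gte(hit, 9)
})

test_that("CV filter applies the sd/mean duplicate rule on the raw scale", {
  # identical duplicates: all CVs zero, nothing excluded
  n_subj <- 20
  vals <- rep(100, 2 * n_subj)
  tr <- make_transitions(list(pep1 = rbind(vals, vals + 50)), reps = 2)
  fc <- cv_filter(tr)
  expect_equal(sum(fc$report$excluded), 0)

  # duplicate pair (100, 150) for 3 of 20 subjects: CV = sd/mean ~ 28.3%,
  # fail fraction 0.15 > 0.10 -> excluded
  bad <- rep(100, 2 * n_subj)
  bad[c(2, 4, 6)] <- 150  # second replicate of subjects 1-3
  cv_hand <- sd(c(100, 150)) / mean(c(100, 150))
  expect_gt(cv_hand, 0.28)
  tr2 <- make_transitions(list(pep1 = rbind(bad, vals + 50)), reps = 2)
  fc2 <- cv_filter(tr2)
  rep1 <- fc2$report[fc2$report$transition == "pep1.t1", ]
  expect_equal(rep1$cv_fail_fraction, 0.15)
  expect_true(rep1$excluded)
  expect_false(fc2$report$excluded[fc2$report$transition == "pep1.t2"])

  # infinite threshold: vacuously no exclusions
  fc3 <- cv_filter(tr2, cv_threshold = Inf)
  expect_equal(sum(fc3$report$excluded), 0)

  # single replicate: instructive error
  tr4 <- make_transitions(list(pep1 = rbind(vals[1:20])), reps = 1)
  expect_error(cv_filter(tr4), "duplicate")
})

test_that("eigengene matches rank-1 identities and the power-iteration oracle", {
  # single transition: eigengene is that transition's standardized profile
  withr::with_seed(7, x <- rnorm(10, 20, 2))
  tr <- as_normalized(make_transitions(list(pep1 = rbind(x))))
  eg <- protein_eigengene(tr, "P1")
  ord <- match(sprintf("S%d", seq_along(x)), eg$subject)
  expect_equal(eg$eigengene[ord], as.numeric(scale(x)), tolerance = 1e-12)

  # two identical transitions: proportional to the shared profile
  tr2 <- as_normalized(make_transitions(list(pep1 = rbind(x, x))))
  eg2 <- protein_eigengene(tr2, "P1")
  expect_gt(cor(eg2$eigengene[ord], x), 0.999999)

  # random 4 x 10 matrix vs the power-iteration oracle (1e-8 after sign
  # alignment)
  withr::with_seed(8, m <- matrix(rnorm(40, 18, 1.5), nrow = 4))
  tr3 <- as_normalized(make_transitions(list(pep1 = m[1:2, ],
                                             pep2 = m[3:4, ])))
  eg3t <- protein_eigengene(tr3, "P1")
  eg3 <- eg3t$eigengene[match(sprintf("S%d", 1:10), eg3t$subject)]
  z <- t(scale(t(m)))
  ora <- oracle_power_eigengene(z)
  if (sum((ora - mean(ora)) * (colMeans(z) - mean(colMeans(z)))) < 0) {
    ora <- -ora
  }
  expect_equal(eg3, ora, tolerance = 1e-8)

  # all-constant protein is rejected
  trc <- as_normalized(make_transitions(list(pep1 = rbind(rep(5, 6)))))
  expect_error(protein_eigengene(trc, "P1"), "zero variance")
})

test_that("eigengene explains at least any single transition's variance", {
  # first-PC optimality against the power-iteration oracle, matrices up to
  # 6 x 20
  for (seed in 1:5) {
    withr::with_seed(seed, {
      nt <- sample(2:6, 1)
      ns <- sample(8:20, 1)
      m <- matrix(rnorm(nt * ns, 15, 1), nrow = nt) +
        rep(rnorm(ns), each = nt)
    })
    tr <- as_normalized(make_transitions(list(pep1 = m)))
    eg <- protein_eigengene(tr, "P1")$eigengene
    z <- t(scale(t(m)))
    expect_equal(sum(eg^2), sum(oracle_power_eigengene(z)^2),
                 tolerance = 1e-8)
    # leading singular value^2 >= variance captured along any single
    # standardized transition profile
    for (i in seq_len(nrow(z))) {
      u <- z[i, ] / sqrt(sum(z[i, ]^2))
      expect_gte(sum(eg^2) + 1e-10, sum((z %*% u)^2))
    }
  }
})

test_that("eigengenes track the generator's true protein signals", {
  ch <- generate_cohort(seed = 3)
  pre <- suppressWarnings(preprocess_srm(ch$transitions))
  sig <- ch$truth$protein_signals
  pm <- pre$protein_matrix
  cors <- vapply(pm$protein, function(p) {
    cor(as.numeric(pm[pm$protein == p, sig$subject]), sig[[p]])
  }, numeric(1))
  expect_gte(min(cors), 0.9)
})

test_that("outlier screen flags gross outliers and spares homogeneity", {
  # i.i.d. multivariate-normal cohort: flag fraction stays small
  fracs <- vapply(1:4, function(seed) {
    withr::with_seed(seed, m <- matrix(rnorm(43 * 42), nrow = 43))
    mean(outlier_screen(make_protein_matrix(m))$flagged)
  }, numeric(1))
  expect_lt(mean(fracs), 0.15)

  # one subject shifted by +10 SD is flagged
  withr::with_seed(13, m <- matrix(rnorm(30 * 20), nrow = 30))
  m[, 7] <- m[, 7] + 10
  scr <- outlier_screen(make_protein_matrix(m))
  expect_true(scr$flagged[scr$subject == "S7"])

  # perfectly homogeneous cohort (identical profiles): zero flags
  withr::with_seed(14, prof <- rnorm(25))
  mh <- matrix(rep(prof, 12), ncol = 12)
  expect_equal(sum(outlier_screen(make_protein_matrix(mh))$flagged), 0)

  expect_error(outlier_screen(make_protein_matrix(m[, 1:2, drop = FALSE])),
               "3 subjects")
})

test_that("missing intensities are dropped or imputed per the 20% rule", {
  m <- rbind(c(8, 9, 10, 11, 12), c(6, 7, 8, 9, 10), c(7, 8, 9, 10, 11))
  tr <- make_transitions(list(pep1 = m))
  # one transition missing in 2/5 runs (> 20%): dropped
  tr_drop <- tr[!(tr$transition == "pep1.t1" &
                    tr$subject %in% c("S1", "S2")), ]
  out <- impute_missing(tr_drop)
  expect_false("pep1.t1" %in% out$transition)
  log <- attr(out, "imputation_log")
  expect_equal(log$dropped_transitions, "pep1.t1")

  # one missing cell (1/5 runs): imputed as the run's peptide mean
  tr_one <- tr[!(tr$transition == "pep1.t2" & tr$subject == "S3"), ]
  out2 <- impute_missing(tr_one)
  imputed <- out2$intensity[out2$transition == "pep1.t2" &
                              out2$subject == "S3"]
  expect_equal(imputed, mean(c(10, 9)))
  expect_equal(nrow(attr(out2, "imputation_log")$imputed_cells), 1)
})
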