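# Independent oracle implementations used to cross-check the package's
# computations. These deliberately use textbook formulations, not the code
# paths they validate.

# Textbook Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}

# Pearson chi-squared by explicit observed/expected loops.
oracle_chisq <- function(tab) {
  N <- sum(tab)
  chi2 <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / N
      chi2 <- chi2 + (tab[i, j] - e)^2 / e
    }
  }
  chi2
}

# Leading eigenvector of t(z) %*% z by power iteration; returns the
# eigengene (first right singular vector of z scaled by the singular
# value).
oracle_power_eigengene <- function(z, iters = 100000, tol = 1e-28) {
  a <- crossprod(z)  # subjects x subjects
  v <- rep(1, ncol(a)) + seq_len(ncol(a)) / ncol(a)  # deterministic start
  for (i in seq_len(iters)) {
    v_new <- a %*% v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (sum((v_new - v)^2) < tol) break
    v <- v_new
  }
  lambda <- as.numeric(t(v) %*% a %*% v)
  as.numeric(v) * sqrt(lambda)
}

# Plain O(n^3) UPGMA agglomeration on a distance matrix; returns merge
# heights in merge order.
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        dd <- d[active[i], active[j]]
        if (dd < best_d) {
          best_d <- dd
          best <- c(active[i], active[j])
        }
      }
    }
    heights <- c(heights, best_d)
    a <- best[1]; b <- best[2]
    # average linkage: size-weighted mean of the two clusters' distances
    for (k in setdiff(active, c(a, b))) {
      d[a, k] <- d[k, a] <-
        (sizes[a] * d[a, k] + sizes[b] * d[b, k]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  heights
}

# Exact two-sided binomial sign-test p under p = 0.5, by enumeration of
# outcomes no more likely than the observed one.
oracle_sign_p <- function(k, m) {
  if (m == 0) return(1)
  probs <- dbinom(0:m, m, 0.5)
  min(1, sum(probs[probs <= probs[k + 1] * (1 + 1e-7)]))
}

# Direct two-sided p for a Pearson r via the t transform.
pearson_p_direct <- function(r, n) {
  2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
}
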