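# Internal helpers shared across modules.

# Run = one mass-spectrometer injection, identified by subject x replicate.
run_id <- function(subject, replicate) paste(subject, replicate, sep = ":")

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

transition_scale <- function(transitions) {
  sc <- attr(transitions, "srm_scale")
  if (is.null(sc)) "raw" else sc
}

set_transition_scale <- function(transitions, scale) {
  attr(transitions, "srm_scale") <- scale
  transitions
}

is_normalized <- function(transitions) isTRUE(attr(transitions, "srm_normalized"))

# Two-sided p-value for a Pearson correlation via the exact t transform.
pearson_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  df <- n - 2
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), df)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
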