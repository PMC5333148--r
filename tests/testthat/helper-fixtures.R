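# Small in-code fixtures shared across test files.

# Long-form transition table from a named list of transition x run
# matrices, one matrix per peptide (rows = transitions, cols = runs).
# Runs are mapped to subjects S1..Sk with `reps` replicates each.
make_transitions <- function(peptides, protein = "P1", reps = 1) {
  rows <- list()
  for (pep in names(peptides)) {
    m <- peptides[[pep]]
    n_runs <- ncol(m)
    n_subj <- n_runs / reps
    stopifnot(n_subj == round(n_subj))
    subj <- rep(sprintf("S%d", seq_len(n_subj)), each = reps)
    repl <- rep(seq_len(reps), n_subj)
    for (i in seq_len(nrow(m))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        protein = protein, peptide = pep,
        transition = sprintf("%s.t%d", pep, i),
        subject = subj, replicate = repl,
        intensity = as.numeric(m[i, ])
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Mark a table as log2-scale and normalized so mid-pipeline operations can
# be tested in isolation.
as_normalized <- function(transitions) {
  attr(transitions, "srm_scale") <- "log2"
  attr(transitions, "srm_normalized") <- TRUE
  transitions
}

# Small protein matrix (proteins x subjects) from a numeric matrix.
make_protein_matrix <- function(m) {
  df <- as.data.frame(m)
  names(df) <- sprintf("S%d", seq_len(ncol(m)))
  tibble::as_tibble(cbind(
    data.frame(protein = sprintf("P%d", seq_len(nrow(m)))), df))
}

# Cohort table for arbitrary group sizes with innocuous covariates.
make_cohort <- function(sizes = c(Control = 16, MA = 14, MAP = 12),
                        seed = 99) {
  withr::with_seed(seed, {
    group <- factor(rep(names(sizes), sizes),
                    levels = c("Control", "MA", "MAP"))
    n <- length(group)
    tibble::tibble(
      subject = sprintf("S%d", seq_len(n)),
      group = group,
      age = round(stats::rnorm(n, 25, 5), 1),
      gender = factor(sample(rep(c("M", "F"), c(ceiling(0.75 * n),
                                                n - ceiling(0.75 * n)))),
                      levels = c("F", "M")),
      nicotine = sample(rep(c(1L, 0L), c(ceiling(n / 2), floor(n / 2)))),
      cannabis = sample(rep(c(1L, 0L), c(ceiling(n / 5),
                                         n - ceiling(n / 5)))),
      alcohol = sample(rep(c(1L, 0L), c(ceiling(n / 3),
                                        n - ceiling(n / 3)))),
      mandrax = c(1L, rep(0L, n - 1))
    )
  })
}

# Tiny null generator configuration for fast structural tests: three small
# groups with demographic targets scaled down to fit.
tiny_config <- function(n_proteins = 6) {
  dem <- srmdti:::default_demographics()
  dem$gender_male <- c(Control = 4, MA = 3, MAP = 3)
  dem$nicotine <- c(Control = 2, MA = 2, MAP = 4)
  dem$cannabis <- c(Control = 2, MA = 1, MAP = 1)
  dem$alcohol <- c(Control = 2, MA = 2, MAP = 1)
  dem$mandrax <- c(Control = 0, MA = 0, MAP = 1)
  cfg <- generator_config(group_sizes = c(Control = 5, MA = 4, MAP = 4),
                          n_proteins = n_proteins,
                          protein_effects = default_protein_effects()[0, ],
                          roi_effects = default_roi_effects()[0, ],
                          couplings = default_couplings()[0, ],
                          interference = list(n_transitions = 0,
                                              spike_sd = 2),
                          demographics = dem)
  cfg
}
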