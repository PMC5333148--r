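# srmdti

Multi-modal integration of targeted serum proteomics, diffusion MRI and
psychometrics for three-group case-control studies of
methamphetamine-associated psychosis (MAP), methamphetamine dependence
without psychosis (MA), and healthy controls.

## The problem

Studies of stimulant-associated psychosis increasingly collect several
modalities on the same small cohort: a targeted selected-reaction-monitoring
(SRM) serum panel quantified at the peptide-transition level, ROI-level
diffusion-tensor summaries (FA, MD, AD, RD over the 48 regions of the
JHU ICBM-DTI-81 white-matter atlas), and psychometric scales (EPQR-S,
PANSS). Each layer needs its own care — transition-level quality control
before any protein-level claim, familywise-corrected group contrasts with
demographic covariates, and cross-modal correlation screens that are
honest about single-subject leverage at n ≤ 42. `srmdti` packages that
whole analysis as composable, tested functions plus a seedful synthetic
cohort generator with known ground truth so every stage has a recovery
test.

## What it computes

* **SRM preprocessing** — log2 transform; per-run median equalisation;
  between-run **interference scores** (correlation of each transition
  with its peptide's leave-one-out per-run mean, exclusion below 0.8);
  the **10%/10% duplicate-CV rule** on raw-scale replicate intensities;
  **eigengene summarisation**, i.e. the first right singular vector of
  each protein's standardized transition-by-subject matrix scaled by its
  singular value; subject outlier screening (2-SD rule on mean
  inter-subject correlation and the first two PCs).
* **Group statistics** — per feature (protein eigengene or ROI metric),
  `response ~ group + age + gender + nicotine + cannabis + alcohol +
  mandrax`, with the omnibus group F-test and single-step Tukey
  (max-|t|) adjusted pairwise contrasts from the same fit; per-protein
  variance-fraction attribution (random-intercept components for
  categorical covariates, fixed-term share for age); Shapiro-gated
  ANOVA/Kruskal–Wallis for continuous demographics; the
  H = ((N−1)/N)·χ² indicator test for binary traits; Spearman screens
  against psychometrics.
* **DTI statistics** — the same adjusted model over all 48 × 4
  (ROI, metric) cells; hierarchical clustering of the omnibus p-value
  matrix (1 − Pearson distance, average linkage); tensor-identity
  validation (MD = (AD + 2·RD)/3, AD ≥ RD, FA ∈ [0, 1]).
* **Integration** — Pearson screens of every protein against every ROI
  metric within a scope (all subjects, one group, or pooled MA+MAP);
  leave-one-out influence flags for associations that hinge on one
  subject; nested p-value stratification (0.05/0.01/0.001); exact
  two-tailed sign test comparing nominal association counts between
  control and patient scopes, paired per protein.
* **Synthetic cohorts** — `generate_cohort()` emulates the full design
  (group sizes 16/14/12, demographic margins, duplicate injections,
  planted differential proteins, planted RD/MD tract elevations,
  latent-factor cross-modal couplings with scope masks, planted
  transition interference) and returns the ground truth;
  `null_cohort()` strips all planted structure; `evaluate_recovery()`
  scores one end-to-end run against the truth.

## Worked example

```r
library(srmdti)

cohort <- generate_cohort(seed = 1)
cohort
#> Synthetic multi-modal cohort (seed 1)
#>   subjects:   42 (16/14/12)
#>   transitions: 203 over 17052 rows
#>   ROI cells:   48 ROIs x 4 metrics
#>   planted:     3 protein effects, 16 ROI cells, 10 interfered transitions

run <- run_pipeline(cohort$transitions, cohort$cohort, cohort$roi)
run
#> Multi-modal pipeline run
#>   transitions kept: 175 of 203
#>   significant proteins: APOC2, APOH, HPTR, KNG1
#>   MAP-elevated ROI cells: 16
#>   nominal associations: control 645 vs patient 448 (p = 0.00191)
```

The preprocessing kept 175 of 203 transitions (the interference filter
removed the 10 planted interfered transitions plus their compromised
peptide-mates; the CV rule removed a handful more), and the
covariate-adjusted Tukey contrasts recover the planted apolipoprotein
effects:

```r
dplyr::filter(tidy(run$diffabund),
              protein %in% c("APOC2", "APOH"), grepl("MAP", contrast))
#>   protein    contrast  estimate        p_adj
#> 1   APOC2 MAP-Control  3.078404 2.045258e-03
#> 2   APOC2      MAP-MA  2.892325 3.722299e-03
#> 3    APOH MAP-Control -4.840028 1.835279e-05
#> 4    APOH      MAP-MA -5.160564 4.356034e-06
```

APOC2 is elevated and APOH reduced in the psychosis group against both
comparison groups, with Tukey-adjusted p-values well below 0.05 — the
planted 2-SD effects. On the integration side, the control group shows
many more nominal protein–DTI associations than the pooled patient
groups (645 vs 448 of 8256 screened pairs; exact sign test over 43
per-protein pairs p = 0.0019), reproducing the qualitative loss of
protein–microstructure co-linearity outside the control group that the
generator plants:

```r
glance(run$signtest)
#>   n_control n_patient wins_control wins_patient  ties       p pairing_unit
#> 1       645       448           32           11     0 0.00191 protein
```

Result objects have broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()` displays (contrast panels for differential abundance, the
clustered ROI p-value heat map, stratification bar charts). A thin
command-line wrapper over the same functions lives at
`inst/cli/srmdti.R` (subcommands `simulate`, `preprocess`, `diffabund`,
`dti`, `integrate`, `run-all`).

The methods vignette (`vignettes/multimodal-methods.Rmd`) documents the
models, the QC rules and their numerical edge cases, the generator's
design and calibration, and a power analysis of what recovery can and
cannot demonstrate at this cohort size.

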