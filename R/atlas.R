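#' White-matter atlas label table
#'
#' Returns the 48-region JHU ICBM-DTI-81 white-matter label set used for
#' ROI-level diffusion summaries, with hemisphere annotation (`L`, `R`, or
#' `M` for unpaired midline tracts) and a `tract` key shared by left/right
#' homologues so bilateral symmetry can be inspected.
#'
#' @return A tibble with columns `index`, `roi` (short label), `name`,
#'   `hemisphere` and `tract`.
#' @export
#' @examples
#' atlas <- jhu_atlas()
#' table(atlas$hemisphere)
jhu_atlas <- function() {
  path <- system.file("extdata", "jhu_icbm_dti81_labels.tsv",
                      package = "srmdti", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' DTI metrics handled by the pipeline
#' @return Character vector `c("FA", "MD", "AD", "RD")`.
#' @export
dti_metrics <- function() c("FA", "MD", "AD", "RD")
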