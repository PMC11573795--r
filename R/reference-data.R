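#' Bundled reference data from a human-lung stereology study
#'
#' Two small tables from a stereological study of mitochondrial
#' distribution in AE1 cells of three infant (C1-C3) and three adult
#' (A2-A8) human lungs, bundled as package data so the analysis can be
#' reproduced end to end:
#'
#' * `ae1_profile_counts()` - pooled per-age-group compartment counts: test
#'   points `p` (25-point grid) and observed mitochondrial profiles `n_0`
#'   for the on-capillary and above-pillar AE1 compartments.  Feeding one
#'   age group into [chi_squared()] reproduces the published localization
#'   analysis.
#' * `ae1_stereology_table()` - the per-subject volume-fraction cascade:
#'   parenchymal volume `v_par` (cm^3), the chained volume fractions and
#'   absolute volumes, and the observed profile fractions `q_comp1`,
#'   `q_comp2` (%).
#'
#' @param age_group Optionally restrict `ae1_profile_counts()` to
#'   `"infant"` or `"adult"`.
#' @return A tibble.
#' @name reference_data
#' @examples
#' chi_squared(ae1_profile_counts("infant"))
NULL

#' @rdname reference_data
#' @export
ae1_profile_counts <- function(age_group = NULL) {
  df <- readr::read_csv(
    system.file("extdata", "ae1_profile_counts.csv",
                package = "mitostereo", mustWork = TRUE),
    show_col_types = FALSE
  )
  if (!is.null(age_group)) {
    stopifnot(age_group %in% df$age_group)
    df <- df[df$age_group == age_group, ]
  }
  df
}

#' @rdname reference_data
#' @export
ae1_stereology_table <- function() {
  readr::read_csv(
    system.file("extdata", "ae1_stereology_table.csv",
                package = "mitostereo", mustWork = TRUE),
    show_col_types = FALSE
  )
}
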