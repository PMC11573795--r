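#' Configure a synthetic interalveolar-septum section
#'
#' Defines the ground truth for [generate_section()]: physical extent, pixel
#' size, the target area fraction of each compartment, the mean density of
#' mitochondrial profiles per square micrometre of AE1 area, and a
#' per-compartment index of relative localization (IRL) that biases where
#' profiles are placed.  An IRL of 1 in every compartment means profiles are
#' placed in proportion to compartment area (random localization); values
#' above/below 1 enrich/deplete a compartment while preserving the overall
#' density.
#'
#' @param width_um,height_um Section extent in micrometres.
#' @param pixel_size_um Edge length of one raster pixel, micrometres.
#' @param area_fractions Named numeric vector over
#'   `compartment_labels()`; must sum to 1.
#' @param mito_density_um2 Mean number of mitochondrial profiles per
#'   square micrometre of AE1 area.  The default 0.85 corresponds to a
#'   mitochondrial volume fraction of about 6% of AE1 cytoplasm carried by
#'   profiles of 0.15 um radius.
#' @param irl Named numeric vector over the AE1 compartments; the
#'   area-weighted mean over AE1 compartments must equal 1 so total density
#'   is preserved.
#' @param profile_radius_um Profile radius in micrometres.  Mitochondrial
#'   profiles on thin sections measure roughly 0.2-0.5 um across.
#' @param stripe_period_um Period of the alternating capillary/pillar
#'   stripe pattern along the septum, micrometres.
#' @param seed Integer seed; sections are bit-reproducible per seed.
#'
#' @return A `section_config` list, validated.
#' @seealso [generate_section()]
#' @export
#' @examples
#' cfg <- section_config(width_um = 50, height_um = 50, seed = 1)
#' cfg$area_fractions
section_config <- function(width_um,
                           height_um,
                           pixel_size_um = 0.1,
                           area_fractions = c(
                             air           = 0.45,
                             septum_other  = 0.45,
                             ae1_capillary = 0.061,
                             ae1_pillar    = 0.028,
                             ae1_nucleus   = 0.011
                           ),
                           mito_density_um2 = 0.85,
                           irl = c(ae1_capillary = 1, ae1_pillar = 1,
                                   ae1_nucleus = 1),
                           profile_radius_um = 0.15,
                           stripe_period_um = 10,
                           seed = 1L) {
  cfg <- structure(
    list(
      width_um = width_um, height_um = height_um,
      pixel_size_um = pixel_size_um,
      area_fractions = area_fractions[names(COMPARTMENTS)],
      mito_density_um2 = mito_density_um2,
      irl = irl[AE1_COMPARTMENTS],
      profile_radius_um = profile_radius_um,
      stripe_period_um = stripe_period_um,
      seed = as.integer(seed)
    ),
    class = "section_config"
  )
  validate_section_config(cfg)
}

validate_section_config <- function(cfg) {
  af <- cfg$area_fractions
  if (anyNA(af) || !setequal(names(af), names(COMPARTMENTS))) {
    abort("`area_fractions` must be named over all compartment labels.",
          class = "mitostereo_invalid_config")
  }
  if (any(af < 0) || abs(sum(af) - 1) > 1e-9) {
    abort("`area_fractions` must be non-negative and sum to 1.",
          class = "mitostereo_invalid_config")
  }
  if (cfg$pixel_size_um <= 0 ||
      cfg$pixel_size_um > min(cfg$width_um, cfg$height_um)) {
    abort("`pixel_size_um` must be positive and no larger than the section.",
          class = "mitostereo_invalid_config")
  }
  if (cfg$mito_density_um2 < 0) {
    abort("`mito_density_um2` must be >= 0.",
          class = "mitostereo_invalid_config")
  }
  irl <- cfg$irl
  if (anyNA(irl) || any(irl < 0)) {
    abort("`irl` must be named over the AE1 compartments and non-negative.",
          class = "mitostereo_invalid_config")
  }
  ae1 <- af[AE1_COMPARTMENTS]
  if (sum(ae1) > 0) {
    wmean <- sum(irl * ae1) / sum(ae1)
    if (abs(wmean - 1) > 1e-9) {
      abort(paste0(
        "Area-weighted mean IRL over AE1 compartments must be 1 (got ",
        format(wmean), ") so total profile density is preserved."
      ), class = "mitostereo_invalid_config")
    }
  }
  cfg
}

#' @export
print.section_config <- function(x, ...) {
  cat("<section_config> ", x$width_um, " x ", x$height_um, " um @ ",
      x$pixel_size_um, " um/px, seed ", x$seed, "\n", sep = "")
  cat("  area fractions: ",
      paste(names(x$area_fractions),
            format(x$area_fractions, digits = 3), collapse = ", "), "\n")
  cat("  mito density:", x$mito_density_um2, "um^-2; IRL:",
      paste(format(x$irl, digits = 3), collapse = "/"), "\n")
  invisible(x)
}

#' Solve IRL values that preserve total density
#'
#' Given the IRL for the capillary compartment and the AE1 area fractions,
#' returns the full IRL vector with the pillar (and nucleus) compartments
#' sharing a common value chosen so the area-weighted mean IRL is exactly 1,
#' as required by [section_config()].
#'
#' @param irl_capillary IRL for the on-capillary compartment.
#' @param area_fractions Named area-fraction vector as in [section_config()].
#' @return Named IRL vector over the AE1 compartments.
#' @export
#' @examples
#' balance_irl(0.93)
balance_irl <- function(irl_capillary,
                        area_fractions = c(
                          air = 0.45, septum_other = 0.45,
                          ae1_capillary = 0.061, ae1_pillar = 0.028,
                          ae1_nucleus = 0.011
                        )) {
  a <- area_fractions[AE1_COMPARTMENTS]
  rest <- sum(a) - a[["ae1_capillary"]]
  if (rest <= 0) abort("No non-capillary AE1 area to balance against.")
  other <- (sum(a) - irl_capillary * a[["ae1_capillary"]]) / rest
  if (other < 0) abort("`irl_capillary` too large for these area fractions.")
  c(ae1_capillary = irl_capillary, ae1_pillar = other, ae1_nucleus = other)
}
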