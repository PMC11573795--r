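# Shared fixtures built in code.

# Assemble a synthetic_section by hand from a label matrix (codes as in
# compartment_codes()) and an optional profile table.
manual_section <- function(labels, pixel_size_um = 1,
                           profiles = NULL) {
  profiles <- profiles %||% tibble::tibble(
    x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
    compartment = character(0)
  )
  structure(
    list(labels = labels, pixel_size_um = pixel_size_um,
         profiles = profiles, config = NULL),
    class = "synthetic_section"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

whole_section_fov <- function(section) {
  tibble::tibble(
    fov_id = 1L, x_um = 0, y_um = 0,
    width_um = ncol(section$labels) * section$pixel_size_um,
    height_um = nrow(section$labels) * section$pixel_size_um
  )
}

# Section config whose comp1:comp2 area ratio 27:7 makes the IRL pair
# (0.93, 1.27) exactly density-preserving.
recovery_config <- function(seed, width_um = 60, height_um = 60,
                            density = 0.95) {
  section_config(
    width_um, height_um, pixel_size_um = 0.2,
    area_fractions = c(air = 0.33, septum_other = 0.33,
                       ae1_capillary = 0.27, ae1_pillar = 0.07,
                       ae1_nucleus = 0),
    mito_density_um2 = density,
    irl = c(ae1_capillary = 0.93, ae1_pillar = 1.27, ae1_nucleus = 1),
    seed = seed
  )
}

# Balanced config used for calibration simulations: large AE1 compartments
# so the point-count size estimator has many more points than profiles, and
# no nucleus so the null (IRL = 1 for both analysed compartments) holds for
# the statistic exactly as the pipeline computes it.
calibration_config <- function(seed, density = 0.15) {
  section_config(
    30, 30, pixel_size_um = 0.2,
    area_fractions = c(air = 0.2, septum_other = 0.26,
                       ae1_capillary = 0.36, ae1_pillar = 0.18,
                       ae1_nucleus = 0),
    mito_density_um2 = density,
    seed = seed
  )
}

# Independent seed stream for test-side randomness.
derive_seed_test <- function(r) (r * 7919 + 13) %% 2147483647

infant_counts <- function() {
  compartment_counts(c("on_capillary", "above_pillar"),
                     p = c(1841, 1241), n_0 = c(1374, 442))
}

adult_counts <- function() {
  compartment_counts(c("on_capillary", "above_pillar"),
                     p = c(1306, 347), n_0 = c(859, 311))
}
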