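#' Write and read synthetic sections and images on disk
#'
#' A section is stored as a single-channel label TIFF (codes scaled by
#' 1/255), a profile CSV (`x_um`, `y_um`, `radius_um`, `compartment`) and a
#' YAML config echoing the ground truth; a two-channel image as a 2-page
#' TIFF with intensities scaled to `[0, 1]` by the joint maximum.
#'
#' @param section A `synthetic_section`.
#' @param img A `two_channel_image`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem.
#' @param path TIFF path.
#' @return `write_section()` returns the written paths invisibly.
#' @name section_io
NULL

#' @rdname section_io
#' @export
write_section <- function(section, dir, stem = "section") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    labels = file.path(dir, paste0(stem, "_labels.tif")),
    profiles = file.path(dir, paste0(stem, "_profiles.csv")),
    config = file.path(dir, paste0(stem, "_config.yaml"))
  )
  tiff::writeTIFF(section$labels / 255, paths$labels,
                  bits.per.sample = 8L)
  readr::write_csv(section$profiles, paths$profiles)
  cfg <- section$config
  yaml::write_yaml(
    list(
      width_um = cfg$width_um, height_um = cfg$height_um,
      pixel_size_um = cfg$pixel_size_um,
      area_fractions = as.list(cfg$area_fractions),
      mito_density_um2 = cfg$mito_density_um2,
      irl = as.list(cfg$irl),
      profile_radius_um = cfg$profile_radius_um,
      stripe_period_um = cfg$stripe_period_um,
      seed = cfg$seed
    ),
    paths$config
  )
  invisible(paths)
}

#' @rdname section_io
#' @export
write_two_channel_tiff <- function(img, path) {
  top <- max(img$ch1, img$ch2, 1e-12)
  tiff::writeTIFF(list(img$ch1 / top, img$ch2 / top), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname section_io
#' @export
read_two_channel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) {
    abort("Expected a 2-page TIFF.", class = "mitostereo_schema_error")
  }
  structure(
    list(ch1 = pages[[1]], ch2 = pages[[2]],
         truth_mode = NA_character_, truth_shift_px = NA_integer_),
    class = "two_channel_image"
  )
}

#' Load a per-compartment counts table
#'
#' Reads and validates a CSV with one row per compartment and columns
#' `compartment`, `p` (test points) and `n_0` (observed profiles).
#'
#' @param path CSV path.
#' @param allowed Permitted compartment labels; defaults to the IRL
#'   analysis compartments plus the raster labels.
#' @return A validated [compartment_counts()] tibble.
#' @export
load_counts_csv <- function(path,
                            allowed = c("on_capillary", "above_pillar",
                                        compartment_labels())) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("compartment", "p", "n_0")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Counts CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mitostereo_schema_error")
  }
  unknown <- setdiff(df$compartment, allowed)
  if (length(unknown)) {
    abort(paste0("Unknown compartment label(s): ",
                 paste(unknown, collapse = ", ")),
          class = "mitostereo_schema_error")
  }
  compartment_counts(df$compartment, df$p, df$n_0)
}
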