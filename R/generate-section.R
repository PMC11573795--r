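#' Generate a labeled synthetic section with known ground truth
#'
#' Builds a 2D labeled raster emulating a thin section through lung
#' parenchyma: air above and below a horizontal interalveolar-septum band,
#' thin AE1 rims on both surfaces of the band, and an alternating
#' capillary/pillar stripe pattern along the septum that splits the rim into
#' the on-capillary, above-pillar and nucleus compartments in the configured
#' proportions.  Mitochondrial profiles are then placed inside the AE1
#' compartments as a Poisson draw with per-compartment mean
#' `irl_c * mito_density_um2 * area_c`, so the configured IRL is the ground
#' truth for the localization analysis.
#'
#' Coordinates use a lower-left origin with x to the right and y up, in
#' micrometres; pixels are half-open `[i*s, (i+1)*s)`.  Raster row 1 is the
#' bottom row of the section.
#'
#' @param config A [section_config()].
#' @return A `synthetic_section`: list with `labels` (integer matrix,
#'   `ny x nx`, values `compartment_codes()`), `pixel_size_um`, `profiles`
#'   (tibble with `x_um`, `y_um`, `radius_um`, `compartment`) and `config`
#'   (the ground-truth echo).
#' @export
#' @examples
#' sec <- generate_section(section_config(width_um = 40, height_um = 40,
#'                                        pixel_size_um = 0.2, seed = 7))
#' section_area_fractions(sec)
generate_section <- function(config) {
  config <- validate_section_config(config)
  s <- config$pixel_size_um
  nx <- round(config$width_um / s)
  ny <- round(config$height_um / s)
  af <- config$area_fractions

  labels <- matrix(COMPARTMENTS[["air"]], nrow = ny, ncol = nx)

  # Horizontal septum band, vertically centred.
  n_band <- round(ny * (1 - af[["air"]]))
  r0 <- floor((ny - n_band) / 2) + 1L
  band_rows <- seq_len(n_band) + r0 - 1L
  labels[band_rows, ] <- COMPARTMENTS[["septum_other"]]

  # AE1 rims on the two band surfaces.
  f_ae1 <- sum(af[AE1_COMPARTMENTS])
  n_rim <- min(round(ny * f_ae1), n_band)
  rim_rows <- integer(0)
  if (n_rim > 0 && n_band > 0) {
    n_top <- ceiling(n_rim / 2)
    n_bot <- n_rim - n_top
    rim_rows <- c(
      utils::head(band_rows, n_bot),
      utils::tail(band_rows, n_top)
    )
    # Compartment by x position within the stripe period.
    q <- af[AE1_COMPARTMENTS] / f_ae1
    x_mid <- (seq_len(nx) - 0.5) * s
    u <- (x_mid %% config$stripe_period_um) / config$stripe_period_um
    comp_code <- ifelse(
      u < q[["ae1_capillary"]], COMPARTMENTS[["ae1_capillary"]],
      ifelse(u < q[["ae1_capillary"]] + q[["ae1_pillar"]],
             COMPARTMENTS[["ae1_pillar"]], COMPARTMENTS[["ae1_nucleus"]])
    )
    labels[rim_rows, ] <- matrix(comp_code, nrow = length(rim_rows),
                                 ncol = nx, byrow = TRUE)
  }

  profiles <- place_profiles(labels, s, config)

  structure(
    list(labels = labels, pixel_size_um = s, profiles = profiles,
         config = config),
    class = "synthetic_section"
  )
}

place_profiles <- function(labels, s, config) {
  empty <- tibble::tibble(
    x_um = numeric(0), y_um = numeric(0), radius_um = numeric(0),
    compartment = character(0)
  )
  if (config$mito_density_um2 <= 0) return(empty)
  px_area <- s^2
  set.seed(derive_seed(config$seed, 1L))
  out <- purrr::map(AE1_COMPARTMENTS, function(comp) {
    idx <- which(labels == COMPARTMENTS[[comp]])
    if (length(idx) == 0) return(empty)
    area <- length(idx) * px_area
    n <- rpois(1L, config$irl[[comp]] * config$mito_density_um2 * area)
    if (n == 0) return(empty)
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    row <- (pick - 1L) %% nrow(labels) + 1L
    col <- (pick - 1L) %/% nrow(labels) + 1L
    tibble::tibble(
      x_um = (col - 1L + runif(n)) * s,
      y_um = (row - 1L + runif(n)) * s,
      radius_um = config$profile_radius_um,
      compartment = comp
    )
  })
  dplyr::bind_rows(out)
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat("<synthetic_section> ", ncol(x$labels), " x ", nrow(x$labels),
      " px @ ", x$pixel_size_um, " um/px, ",
      nrow(x$profiles), " mitochondrial profiles\n", sep = "")
  invisible(x)
}

#' Compartment codes used in label rasters
#'
#' @return Named integer vector mapping compartment labels to raster codes.
#' @export
compartment_codes <- function() COMPARTMENTS

#' Empirical area fractions of a labeled section
#'
#' @param section A `synthetic_section` (or any list with an integer
#'   `labels` matrix using `compartment_codes()`).
#' @return Tibble with `compartment` and empirical `fraction`, in canonical
#'   compartment order; fractions sum to 1.
#' @export
section_area_fractions <- function(section) {
  n <- length(section$labels)
  counts <- vapply(COMPARTMENTS,
                   function(code) sum(section$labels == code), numeric(1))
  tibble::tibble(
    compartment = names(COMPARTMENTS),
    fraction = as.numeric(counts) / n
  )
}

#' Compartment label at a point
#'
#' Classifies micrometre coordinates by the half-open pixel containing them.
#'
#' @param section A `synthetic_section`.
#' @param x_um,y_um Coordinate vectors, micrometres (lower-left origin).
#' @return Character vector of compartment labels.
#' @export
label_at <- function(section, x_um, y_um) {
  s <- section$pixel_size_um
  col <- floor(x_um / s) + 1L
  row <- floor(y_um / s) + 1L
  bad <- col < 1L | col > ncol(section$labels) |
    row < 1L | row > nrow(section$labels)
  if (any(bad)) {
    abort("Point(s) outside the section raster.",
          class = "mitostereo_out_of_bounds")
  }
  codes <- section$labels[cbind(row, col)]
  names(COMPARTMENTS)[match(codes, COMPARTMENTS)]
}
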