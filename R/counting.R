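#' Count test points by compartment
#'
#' Classifies each test point by the label of the half-open pixel containing
#' it and tallies points per compartment, separately for the full fine
#' lattice and its nested coarse subset.  Because coarse points are a subset
#' of fine points, the coarse tally never exceeds the fine tally.
#'
#' @param section A `synthetic_section`.
#' @param points Tibble from [overlay_grid()] (`x_um`, `y_um`, `is_coarse`).
#' @param fov_id Optional identifier carried into the output.
#' @return Tibble `fov_id`, `compartment`, `grid` (`"fine"` or
#'   `"coarse"`), `count`, complete over all compartments and both grids.
#' @export
count_points <- function(section, points, fov_id = 1L) {
  comp <- label_at(section, points$x_um, points$y_um)
  tally <- dplyr::bind_rows(
    tibble::tibble(compartment = comp, grid = "fine"),
    tibble::tibble(compartment = comp[points$is_coarse], grid = "coarse")
  ) |>
    dplyr::count(.data$compartment, .data$grid, name = "count")
  tidyr::expand_grid(
    compartment = names(COMPARTMENTS), grid = c("fine", "coarse")
  ) |>
    dplyr::left_join(tally, by = c("compartment", "grid")) |>
    dplyr::mutate(
      count = as.integer(tidyr::replace_na(.data$count, 0L)),
      fov_id = fov_id, .before = 1
    )
}

#' Count every mitochondrial profile in a field
#'
#' Exhaustive profile counting under the unbiased counting-frame rule
#' (Gundersen forbidden line): a profile contributes if its centroid lies
#' inside the field and does not touch the left or bottom exclusion edges;
#' the right and top edges are inclusion edges.  Abutting fields therefore
#' count every profile exactly once.
#'
#' @param section A `synthetic_section`.
#' @param fov One-row tibble or list with `x_um`, `y_um`, `width_um`,
#'   `height_um`.
#' @return Tibble `compartment` (the three AE1 compartments), `n_0`
#'   (observed profile count).
#' @export
count_profiles <- function(section, fov) {
  p <- section$profiles
  inside <- p$x_um > fov$x_um & p$x_um <= fov$x_um + fov$width_um &
    p$y_um > fov$y_um & p$y_um <= fov$y_um + fov$height_um
  tibble::tibble(compartment = AE1_COMPARTMENTS) |>
    dplyr::left_join(
      dplyr::count(p[inside, ], .data$compartment, name = "n_0"),
      by = "compartment"
    ) |>
    dplyr::mutate(n_0 = as.integer(tidyr::replace_na(.data$n_0, 0L)))
}

#' Count test points hitting mitochondrial profiles
#'
#' A test point hits a mitochondrion when it falls inside any profile disc.
#' Used as the fine-grid numerator of the mitochondrial volume-fraction
#' estimator.
#'
#' @param section A `synthetic_section`.
#' @param points Tibble with `x_um`, `y_um` (and optionally `is_coarse`).
#' @return Integer: number of points hitting a mitochondrial profile.
#' @export
count_mito_points <- function(section, points) {
  prof <- section$profiles
  if (nrow(prof) == 0 || nrow(points) == 0) return(0L)
  hit <- logical(nrow(points))
  for (k in seq_len(nrow(prof))) {
    d2 <- (points$x_um - prof$x_um[k])^2 + (points$y_um - prof$y_um[k])^2
    hit <- hit | d2 <= prof$radius_um[k]^2
  }
  sum(hit)
}

#' Per-compartment observed and test-point counts
#'
#' Validating constructor for the table feeding the localization analysis:
#' one row per compartment with the number of test points `p` hitting it
#' (the compartment-size estimator) and the number of observed
#' mitochondrial profiles `n_0`.
#'
#' @param compartment Character vector of compartment names.
#' @param p Integer vector of test-point counts, `>= 0`.
#' @param n_0 Integer vector of observed profile counts, `>= 0`.
#' @return Tibble `compartment`, `p`, `n_0`.
#' @export
#' @examples
#' compartment_counts(c("on_capillary", "above_pillar"),
#'                    p = c(1841, 1241), n_0 = c(1374, 442))
compartment_counts <- function(compartment, p, n_0) {
  if (anyDuplicated(compartment)) abort("Compartment names must be unique.")
  if (any(p < 0) || any(n_0 < 0)) {
    abort("Counts must be non-negative.", class = "mitostereo_invalid_counts")
  }
  if (any(p != round(p)) || any(n_0 != round(n_0))) {
    abort("Counts must be integers.", class = "mitostereo_invalid_counts")
  }
  tibble::tibble(compartment = as.character(compartment),
                 p = as.integer(p), n_0 = as.integer(n_0))
}

#' Observed profile fractions
#'
#' The percentage of mitochondrial profiles falling in each compartment,
#' `Q_c = 100 * N_0,c / sum(N_0)`.  For the lungs studied this ratio is
#' roughly 3:1 between the on-capillary and above-pillar compartments.
#'
#' @param counts Tibble with `compartment` and `n_0` columns.
#' @return Input with an added `q_pct` column; `q_pct` sums to 100.
#' @export
#' @examples
#' profile_fraction(compartment_counts(c("cap", "pillar"),
#'                                     p = c(0, 0), n_0 = c(1374, 442)))
profile_fraction <- function(counts) {
  total <- sum(counts$n_0)
  if (total <= 0) {
    abort("Profile fractions are undefined when no profiles were counted.",
          class = "mitostereo_undefined_fraction")
  }
  dplyr::mutate(counts, q_pct = 100 * .data$n_0 / total)
}
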