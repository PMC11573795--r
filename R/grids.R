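#' Nested coarse/fine point grid
#'
#' A test system of points on a regular lattice where every `a`-th point
#' along x and `b`-th point along y also belongs to a coarse sub-grid, so
#' one coarse point represents `a * b` fine points.  The two designs used
#' for lung sections are a 6:1 grid (nesting `c(3, 2)`: 24 fine / 4 coarse
#' points per field) for septum-versus-air counting at the light level, and
#' a 16:1 grid (nesting `c(4, 4)`: 144 fine / 9 coarse points) for
#' mitochondria-versus-AE1 counting at the electron-microscope level.
#'
#' @param fine_spacing_um Lattice spacing of the fine grid, micrometres.
#' @param nesting Integer pair `c(a, b)`; the coarse:fine ratio is `a * b`.
#' @param origin_offset_um Length-2 offset of the first lattice point from
#'   the field's lower-left corner.  `NULL` (default) draws a fresh uniform
#'   offset in `[0, spacing)^2` each time the grid is overlaid, the
#'   design-based choice; a fixed numeric offset makes overlays
#'   deterministic.
#' @return A `point_grid` object.
#' @export
#' @examples
#' point_grid(10, nesting = c(3, 2))   # 6:1 design
#' point_grid(2, nesting = c(4, 4))    # 16:1 design
point_grid <- function(fine_spacing_um, nesting = c(1L, 1L),
                       origin_offset_um = NULL) {
  if (fine_spacing_um <= 0) abort("Grid spacing must be positive.")
  nesting <- as.integer(nesting)
  if (length(nesting) != 2L || any(nesting < 1L)) {
    abort("`nesting` must be two integers >= 1.")
  }
  if (!is.null(origin_offset_um)) {
    stopifnot(length(origin_offset_um) == 2L)
    if (any(origin_offset_um < 0) || any(origin_offset_um >= fine_spacing_um))
      abort("`origin_offset_um` must lie in [0, spacing).")
  }
  structure(
    list(fine_spacing_um = fine_spacing_um, nesting = nesting,
         origin_offset_um = origin_offset_um),
    class = "point_grid"
  )
}

#' @export
print.point_grid <- function(x, ...) {
  cat("<point_grid> spacing ", x$fine_spacing_um, " um, nesting ",
      x$nesting[1], " x ", x$nesting[2], " (coarse ratio ",
      prod(x$nesting), ":1)\n", sep = "")
  invisible(x)
}

#' Systematic uniform random sampling of fields of view
#'
#' Places fields on a regular step lattice with a single uniformly random
#' start in `[0, step)` per axis, the SURS design: every location in the
#' section has the same inclusion probability across seeds.  The lattice
#' conceptually covers the whole plane, so fields protruding past either
#' section edge are clipped to the section; a location is then sampled
#' exactly when its phase within the step period falls inside a field,
#' which makes the inclusion probability `prod(fov_size / step)` uniformly.
#' A field spanning a full axis is pinned to that axis (exhaustive
#' sampling, the offset is irrelevant).
#'
#' @param section_extent Length-2 numeric, section width and height (um).
#' @param fov_size Length-2 numeric, field width and height (um); must not
#'   exceed the section.
#' @param step Length-2 numeric, lattice step (um); must be at least
#'   `fov_size` componentwise so fields do not overlap.
#' @param seed Integer seed for the random start.
#' @return Tibble of fields: `fov_id`, `x_um`, `y_um` (lower-left corner),
#'   `width_um`, `height_um` (after clipping).
#' @export
#' @examples
#' surs_fields(c(100, 100), c(10, 10), c(25, 25), seed = 1)
surs_fields <- function(section_extent, fov_size, step, seed = 1L) {
  ex <- section_extent
  if (any(fov_size > ex)) {
    abort("Field of view larger than the section.",
          class = "mitostereo_invalid_config")
  }
  if (any(step < fov_size)) {
    abort("`step` must be >= `fov_size` componentwise.",
          class = "mitostereo_invalid_config")
  }
  set.seed(derive_seed(seed, 3L))
  start <- runif(2) * step
  axis_fields <- function(ax) {
    if (fov_size[ax] >= ex[ax]) {
      return(tibble::tibble(lo = 0, hi = ex[ax]))
    }
    origins <- seq(start[ax] - step[ax], ex[ax], by = step[ax])
    lo <- pmax(origins, 0)
    hi <- pmin(origins + fov_size[ax], ex[ax])
    keep <- hi > lo
    tibble::tibble(lo = lo[keep], hi = hi[keep])
  }
  fx <- axis_fields(1)
  fy <- axis_fields(2)
  grid <- tidyr::expand_grid(y = seq_len(nrow(fy)), x = seq_len(nrow(fx)))
  tibble::tibble(
    fov_id = seq_len(nrow(grid)),
    x_um = fx$lo[grid$x],
    y_um = fy$lo[grid$y],
    width_um = fx$hi[grid$x] - fx$lo[grid$x],
    height_um = fy$hi[grid$y] - fy$lo[grid$y]
  )
}

#' Project a point grid onto a field of view
#'
#' Generates the fine-lattice test points falling inside a field, flagging
#' the nested coarse subset (lattice indices congruent to 0 modulo the
#' nesting pair).
#'
#' @param fov A one-row tibble or list with `x_um`, `y_um`, `width_um`,
#'   `height_um` (as returned by [surs_fields()]).
#' @param grid A [point_grid()].
#' @return Tibble with `x_um`, `y_um`, `is_coarse`.
#' @export
#' @examples
#' fov <- tibble::tibble(x_um = 0, y_um = 0, width_um = 60, height_um = 40)
#' g <- point_grid(10, nesting = c(3, 2), origin_offset_um = c(5, 5))
#' pts <- overlay_grid(fov, g)
#' sum(pts$is_coarse)  # 4 coarse among 24 fine
overlay_grid <- function(fov, grid) {
  s <- grid$fine_spacing_um
  if (fov$width_um <= 0 || fov$height_um <= 0) {
    abort("Field of view must have positive extent.")
  }
  off <- grid$origin_offset_um %||% runif(2, 0, s)
  if (off[1] >= fov$width_um || off[2] >= fov$height_um) {
    return(tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          is_coarse = logical(0)))
  }
  i <- 0:floor((fov$width_um - off[1]) / s)
  j <- 0:floor((fov$height_um - off[2]) / s)
  i <- i[off[1] + i * s < fov$width_um]
  j <- j[off[2] + j * s < fov$height_um]
  pts <- tidyr::expand_grid(j = j, i = i)
  tibble::tibble(
    x_um = fov$x_um + off[1] + pts$i * s,
    y_um = fov$y_um + off[2] + pts$j * s,
    is_coarse = pts$i %% grid$nesting[1] == 0L &
      pts$j %% grid$nesting[2] == 0L
  )
}
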