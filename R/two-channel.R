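#' Generate a synthetic two-channel fluorescence image
#'
#' Builds a pair of intensity rasters with known colocalization ground
#' truth, emulating a confocal slice with fluorescent puncta.  The first
#' channel is a field of Gaussian spots on a dark background; the second
#' channel depends on `mode`:
#'
#' * `identical_noisy` - channel 2 is channel 1 plus additive Gaussian
#'   noise (perfect colocalization).
#' * `shifted` - channel 2 is channel 1 translated by `shift_px` pixels
#'   along x with zero padding (partial colocalization with a known
#'   cross-correlation peak at `shift_px`).
#' * `independent` - channel 2 is an independent spot field (no
#'   colocalization).
#' * `partial` - half the spots are shared between channels, half are
#'   channel-exclusive.
#'
#' @param mode One of `"identical_noisy"`, `"shifted"`, `"independent"`,
#'   `"partial"`.
#' @param size_px Integer pair `c(ny, nx)`, at least 16 each.
#' @param shift_px Integer translation along x for `mode = "shifted"`;
#'   must satisfy `abs(shift_px) < nx / 4`.
#' @param n_spots Number of spots in channel 1.
#' @param spot_sigma_px Gaussian spot standard deviation, pixels.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity
#'   units; spots have unit peak amplitude).  Negative intensities are
#'   clipped to zero.
#' @param seed Integer seed.
#'
#' @return A `two_channel_image`: list with matrices `ch1`, `ch2`
#'   (identical shape, finite, non-negative), `truth_mode` and
#'   `truth_shift_px`.
#' @export
#' @examples
#' img <- generate_two_channel_image("shifted", size_px = c(64, 64),
#'                                   shift_px = 3, seed = 2)
#' img$truth_shift_px
generate_two_channel_image <- function(mode,
                                       size_px = c(64L, 64L),
                                       shift_px = 0L,
                                       n_spots = 40L,
                                       spot_sigma_px = 1.5,
                                       noise_sd = 0.02,
                                       seed = 1L) {
  modes <- c("identical_noisy", "shifted", "independent", "partial")
  if (!mode %in% modes) {
    abort(paste0("Unknown mode '", mode, "'; expected one of ",
                 paste(modes, collapse = ", "), "."),
          class = "mitostereo_invalid_config")
  }
  ny <- as.integer(size_px[1]); nx <- as.integer(size_px[2])
  if (ny < 16L || nx < 16L) {
    abort("`size_px` must be at least 16 x 16.",
          class = "mitostereo_invalid_config")
  }
  if (mode == "shifted" && abs(shift_px) >= nx / 4) {
    abort("`abs(shift_px)` must be below a quarter of the image width.",
          class = "mitostereo_invalid_config")
  }

  set.seed(derive_seed(seed, 2L))
  spots1 <- random_spots(n_spots, ny, nx)
  ch1 <- render_spots(spots1, ny, nx, spot_sigma_px)
  shift_out <- 0L

  ch2 <- switch(
    mode,
    identical_noisy = ch1,
    shifted = {
      shift_out <- as.integer(shift_px)
      shift_x(ch1, shift_out)
    },
    independent = render_spots(random_spots(n_spots, ny, nx),
                               ny, nx, spot_sigma_px),
    partial = {
      n_half <- n_spots %/% 2L
      shared <- spots1[seq_len(n_half), , drop = FALSE]
      excl <- random_spots(n_spots - n_half, ny, nx)
      render_spots(rbind(shared, excl), ny, nx, spot_sigma_px)
    }
  )
  if (noise_sd > 0) {
    ch1 <- ch1 + rnorm(length(ch1), sd = noise_sd)
    ch2 <- ch2 + rnorm(length(ch2), sd = noise_sd)
  }
  structure(
    list(ch1 = pmax(ch1, 0), ch2 = pmax(ch2, 0),
         truth_mode = mode, truth_shift_px = shift_out),
    class = "two_channel_image"
  )
}

random_spots <- function(n, ny, nx) {
  cbind(row = runif(n, 1, ny), col = runif(n, 1, nx))
}

render_spots <- function(spots, ny, nx, sigma) {
  img <- matrix(0, ny, nx)
  rr <- matrix(seq_len(ny), ny, nx)
  cc <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (k in seq_len(nrow(spots))) {
    d2 <- (rr - spots[k, "row"])^2 + (cc - spots[k, "col"])^2
    img <- img + exp(-d2 / (2 * sigma^2))
  }
  img
}

# Translate a matrix by `shift` columns (+x), zero-padding the vacated
# region; content at column j moves to column j + shift.
shift_x <- function(img, shift) {
  out <- matrix(0, nrow(img), ncol(img))
  nx <- ncol(img)
  if (shift >= 0) {
    if (shift < nx) out[, (1 + shift):nx] <- img[, 1:(nx - shift)]
  } else {
    if (-shift < nx) out[, 1:(nx + shift)] <- img[, (1 - shift):nx]
  }
  out
}

#' @export
print.two_channel_image <- function(x, ...) {
  cat("<two_channel_image> ", nrow(x$ch1), " x ", ncol(x$ch1),
      " px, mode '", x$truth_mode, "'",
      if (x$truth_mode == "shifted") paste0(" (shift ", x$truth_shift_px,
                                            " px)"),
      "\n", sep = "")
  invisible(x)
}
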