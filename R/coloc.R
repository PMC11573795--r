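#' Pearson correlation of two channels
#'
#' Sample correlation of pixel intensity pairs, optionally restricted to a
#' logical mask.  The standard global colocalization measure; invariant
#' under positive affine rescaling of either channel.
#'
#' @param ch1,ch2 Numeric matrices of identical shape.
#' @param mask Logical matrix of the same shape, or `NULL` for all pixels.
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' m <- matrix(1:9, 3)
#' coloc_pearson(m, 10 - m)   # -1
coloc_pearson <- function(ch1, ch2, mask = NULL) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  if (is.null(mask)) mask <- !logical(length(ch1))
  x <- ch1[mask]; y <- ch2[mask]
  if (length(x) < 2) {
    abort("Need at least two masked pixels.",
          class = "mitostereo_undefined_correlation")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Correlation undefined: a channel is constant within the mask.",
          class = "mitostereo_undefined_correlation")
  }
  cor(x, y)
}

#' Costes automatic intensity thresholds
#'
#' Fits the channel-2-versus-channel-1 relationship by orthogonal (total
#' least squares) regression, then scans candidate thresholds `t1` downward
#' through the observed channel-1 intensities with `t2 = a * t1 + b`,
#' returning the largest `t1` for which the Pearson correlation of the
#' pixels *below both* thresholds is non-positive.  Pixels above the
#' thresholds are then taken as genuine signal.  If the below-threshold
#' correlation never reaches zero the minima are returned, retaining every
#' pixel as signal.
#'
#' @param ch1,ch2 Numeric matrices of identical shape.
#' @return List with `t1`, `t2`, `slope`, `intercept`.
#' @export
costes_threshold <- function(ch1, ch2) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  x <- as.numeric(ch1); y <- as.numeric(ch2)
  if (var(x) == 0 || var(y) == 0) {
    abort("Costes regression degenerate: a channel is constant.",
          class = "mitostereo_undefined_correlation")
  }
  fit <- tls_line(x, y)
  cand <- sort(unique(x), decreasing = TRUE)
  for (t1 in cand) {
    t2 <- fit$slope * t1 + fit$intercept
    below <- x < t1 & y < t2
    if (sum(below) < 2) next
    xb <- x[below]; yb <- y[below]
    if (var(xb) == 0 || var(yb) == 0) next
    if (cor(xb, yb) <= 0) {
      return(list(t1 = t1, t2 = t2, slope = fit$slope,
                  intercept = fit$intercept))
    }
  }
  list(t1 = min(x), t2 = min(y), slope = fit$slope,
       intercept = fit$intercept)
}

# Orthogonal regression line through (x, y): major principal axis of the
# covariance matrix.
tls_line <- function(x, y) {
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxy == 0) {
    slope <- if (syy > sxx) Inf else 0
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  if (!is.finite(slope)) {
    abort("Costes regression degenerate: vertical principal axis.",
          class = "mitostereo_undefined_correlation")
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Van Steensel cross-correlation function
#'
#' Pearson correlation of channel 1 against channel 2 translated along x by
#' each shift `delta` in `[-max_shift, max_shift]`, computed over the valid
#' overlap region (no wrap-around).  A positive `delta` compares `ch1`
#' column `x` with `ch2` column `x + delta`.  A peak at zero indicates
#' colocalization; a displaced peak indicates a systematic offset between
#' the structures.
#'
#' @param ch1,ch2 Numeric matrices of identical shape.
#' @param max_shift Maximum absolute shift in pixels; must be below half
#'   the image width.
#' @param mask Optional logical matrix restricting the compared pixels
#'   (intersected with its own translate).
#' @return List with `ccf` (tibble `shift`, `ccf`) and `peak_shift`
#'   (argmax of the finite CCF values).
#' @export
#' @examples
#' img <- generate_two_channel_image("shifted", size_px = c(48, 48),
#'                                   shift_px = 3, noise_sd = 0, seed = 1)
#' van_steensel_ccf(img$ch1, img$ch2, max_shift = 8)$peak_shift
van_steensel_ccf <- function(ch1, ch2, max_shift = 20L, mask = NULL) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  nx <- ncol(ch1)
  if (max_shift >= nx / 2) {
    abort("`max_shift` must be below half the image width.",
          class = "mitostereo_invalid_config")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), nx)
  shifts <- seq.int(-max_shift, max_shift)
  vals <- vapply(shifts, function(d) {
    if (d >= 0) {
      c1 <- ch1[, 1:(nx - d), drop = FALSE]
      c2 <- ch2[, (1 + d):nx, drop = FALSE]
      m <- mask[, 1:(nx - d), drop = FALSE] &
        mask[, (1 + d):nx, drop = FALSE]
    } else {
      c1 <- ch1[, (1 - d):nx, drop = FALSE]
      c2 <- ch2[, 1:(nx + d), drop = FALSE]
      m <- mask[, (1 - d):nx, drop = FALSE] &
        mask[, 1:(nx + d), drop = FALSE]
    }
    if (sum(m) < 2 || var(c1[m]) == 0 || var(c2[m]) == 0) return(NA_real_)
    cor(c1[m], c2[m])
  }, numeric(1))
  if (all(is.na(vals))) {
    abort("Empty or degenerate overlap at every shift.",
          class = "mitostereo_undefined_correlation")
  }
  list(
    ccf = tibble::tibble(shift = shifts, ccf = vals),
    peak_shift = shifts[which.max(vals)]
  )
}

#' Classify a colocalization pattern
#'
#' The three-case rule combining the global Pearson coefficient with the
#' location of the cross-correlation peak: a negative correlation means no
#' colocalization; a non-negative correlation with the CCF peak (almost) at
#' zero means colocalization; a non-negative correlation with a displaced
#' peak means partial colocalization.
#'
#' @param pc Pearson coefficient.
#' @param peak_shift CCF peak location, pixels.
#' @param eps_shift Largest |peak| still treated as "(almost) zero";
#'   default 1 px.
#' @return One of `"no_colocalization"`, `"colocalization"`,
#'   `"partial_colocalization"`.
#' @export
#' @examples
#' classify_coloc(0.5, 0)    # colocalization
#' classify_coloc(0.4, 4)    # partial_colocalization
classify_coloc <- function(pc, peak_shift, eps_shift = 1L) {
  stopifnot(eps_shift >= 0)
  dplyr::case_when(
    pc < 0 ~ "no_colocalization",
    abs(peak_shift) <= eps_shift ~ "colocalization",
    TRUE ~ "partial_colocalization"
  )
}

#' Evans strength class of a correlation
#'
#' Maps a Pearson coefficient onto descriptive strength labels using the
#' conventional band edges (configurable): non-positive values are "no"
#' correlation, then very weak below 0.2, weak below 0.4, moderate below
#' 0.6, strong below 0.8 and very strong up to 1.
#'
#' @param pc Correlation in `[-1, 1]`.
#' @param bands Named numeric vector of strictly increasing upper band
#'   edges ending at 1.
#' @return Character label.
#' @export
#' @examples
#' evans_class(0.25)   # "weak"
evans_class <- function(pc,
                        bands = c(very_weak = 0.2, weak = 0.4,
                                  moderate = 0.6, strong = 0.8,
                                  very_strong = 1)) {
  stopifnot(all(pc >= -1 & pc <= 1))
  if (is.unsorted(bands, strictly = TRUE) || any(bands <= 0) ||
      utils::tail(bands, 1) != 1) {
    abort("`bands` must be strictly increasing, positive, and end at 1.",
          class = "mitostereo_invalid_config")
  }
  vapply(pc, function(v) {
    if (v <= 0) return("no")
    names(bands)[which(v <= bands)[1]]
  }, character(1))
}

#' Full colocalization analysis of a two-channel image
#'
#' Computes the global Pearson coefficient, the Costes automatic thresholds
#' and the Pearson coefficient over above-threshold pixels, the Van
#' Steensel cross-correlation curve with its peak, the three-case
#' classification and the Evans strength class.
#'
#' @param img A `two_channel_image`, or a list with matrices `ch1`, `ch2`.
#' @param max_shift Passed to [van_steensel_ccf()].
#' @param eps_shift Passed to [classify_coloc()].
#' @param evans_bands Passed to [evans_class()].
#' @return A `coloc_result`; see [tidy.coloc_result()] and
#'   [glance.coloc_result()].
#' @export
#' @examples
#' img <- generate_two_channel_image("identical_noisy", size_px = c(32, 32),
#'                                   noise_sd = 0.01, seed = 5)
#' glance(coloc_analysis(img, max_shift = 5))
coloc_analysis <- function(img, max_shift = 20L, eps_shift = 1L,
                           evans_bands = c(very_weak = 0.2, weak = 0.4,
                                           moderate = 0.6, strong = 0.8,
                                           very_strong = 1)) {
  ch1 <- img$ch1; ch2 <- img$ch2
  pc <- coloc_pearson(ch1, ch2)
  th <- costes_threshold(ch1, ch2)
  above <- ch1 > th$t1 & ch2 > th$t2
  pc_costes <- if (sum(above) >= 2 && var(ch1[above]) > 0 &&
                   var(ch2[above]) > 0) cor(ch1[above], ch2[above])
  else NA_real_
  vs <- van_steensel_ccf(ch1, ch2, max_shift = max_shift)
  structure(
    list(
      pc_global = pc,
      costes = th,
      pc_costes = pc_costes,
      ccf = vs$ccf,
      ccf_peak_shift = vs$peak_shift,
      case = classify_coloc(pc, vs$peak_shift, eps_shift = eps_shift),
      evans = evans_class(pc, bands = evans_bands)
    ),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization analysis\n")
  cat(sprintf("  Pearson (global)          %.3f  [Evans: %s]\n",
              x$pc_global, x$evans))
  cat(sprintf("  Costes thresholds         t1 = %.3g, t2 = %.3g\n",
              x$costes$t1, x$costes$t2))
  cat(sprintf("  Pearson (above Costes)    %s\n",
              ifelse(is.na(x$pc_costes), "NA",
                     sprintf("%.3f", x$pc_costes))))
  cat(sprintf("  CCF peak shift            %d px\n", x$ccf_peak_shift))
  cat("  Classification:", x$case, "\n")
  invisible(x)
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return The cross-correlation curve: tibble `shift`, `ccf`.
#' @export
tidy.coloc_result <- function(x, ...) x$ccf

#' One-row summary of a colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return Tibble with `pc_global`, `pc_costes`, `costes_t1`, `costes_t2`,
#'   `ccf_peak_shift`, `case`, `evans`.
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(
    pc_global = x$pc_global, pc_costes = x$pc_costes,
    costes_t1 = x$costes$t1, costes_t2 = x$costes$t2,
    ccf_peak_shift = x$ccf_peak_shift, case = x$case, evans = x$evans
  )
}
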