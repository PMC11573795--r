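test_that("Pearson coefficient: fixtures, affine invariance, degeneracy", {
  m <- matrix(1:9, 3)
  expect_equal(coloc_pearson(m, m), 1)
  expect_equal(coloc_pearson(m, matrix(9:1, 3)), -1)
  expect_equal(coloc_pearson(m, 2.5 * m + 7), 1)

  set.seed(3)
  a <- matrix(runif(64), 8)
  b <- matrix(runif(64), 8)
  expect_equal(coloc_pearson(a, 0.3 * b + 2), coloc_pearson(a, b))

  mask <- matrix(FALSE, 3, 3); mask[1:2, 1] <- TRUE
  expect_equal(coloc_pearson(m, matrix(9:1, 3), mask), -1)

  expect_error(coloc_pearson(m, matrix(5, 3, 3)),
               class = "mitostereo_undefined_correlation")
  expect_error(coloc_pearson(m, m, mask = matrix(FALSE, 3, 3)),
               class = "mitostereo_undefined_correlation")
})

test_that("Costes threshold matches an exhaustive scan oracle on 8-bit images", {
  # Independent oracle: quantize to 8 bits, fit the orthogonal line via
  # eigen decomposition, walk every level from the top and take the first
  # threshold whose sub-threshold correlation is non-positive.
  costes_oracle <- function(ch1, ch2) {
    x <- as.numeric(ch1); y <- as.numeric(ch2)
    ev <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
    a <- ev[2] / ev[1]
    b <- mean(y) - a * mean(x)
    for (t1 in sort(unique(x), decreasing = TRUE)) {
      sel <- x < t1 & y < a * t1 + b
      if (sum(sel) < 2 || var(x[sel]) == 0 || var(y[sel]) == 0) next
      if (stats::cor(x[sel], y[sel]) <= 0) return(c(t1, a * t1 + b))
    }
    c(min(x), min(y))
  }
  quant <- function(m) round(m * 255) / 255
  for (seed in c(1, 7, 21)) {
    img <- generate_two_channel_image("partial", size_px = c(32, 32),
                                      noise_sd = 0.1, seed = seed)
    top <- max(img$ch1, img$ch2)
    ch1 <- quant(img$ch1 / top); ch2 <- quant(img$ch2 / top)
    th <- costes_threshold(ch1, ch2)
    expect_equal(c(th$t1, th$t2), costes_oracle(ch1, ch2),
                 tolerance = 1e-12)
  }
})

test_that("Costes behaviour in the forced regimes", {
  # Perfectly correlated channels: sub-threshold correlation never drops
  # to zero, so the minima are returned and all pixels count as signal.
  img <- generate_two_channel_image("identical_noisy", size_px = c(32, 32),
                                    noise_sd = 0, seed = 5)
  th <- costes_threshold(img$ch1, img$ch2)
  expect_equal(th$t1, min(img$ch1))
  expect_equal(th$t2, min(img$ch2))

  # Independent noise: thresholding removes nothing real, the remaining
  # above-threshold correlation stays near zero.
  set.seed(8)
  a <- matrix(runif(64 * 64), 64)
  b <- matrix(runif(64 * 64), 64)
  th2 <- costes_threshold(a, b)
  expect_gt(th2$t1, min(a))
  above <- a > th2$t1 & b > th2$t2
  if (sum(above) > 10) {
    expect_lt(abs(stats::cor(a[above], b[above])), 0.2)
  }

  expect_error(costes_threshold(a, matrix(1, 64, 64)),
               class = "mitostereo_undefined_correlation")
})

test_that("cross-correlation peaks at the constructed shift", {
  img0 <- generate_two_channel_image("identical_noisy", size_px = c(48, 48),
                                     noise_sd = 0, seed = 2)
  vs0 <- van_steensel_ccf(img0$ch1, img0$ch2, max_shift = 10)
  expect_identical(vs0$peak_shift, 0L)
  expect_equal(vs0$ccf$ccf[vs0$ccf$shift == 0], 1)

  for (shift in c(-4L, 3L, 7L)) {
    img <- generate_two_channel_image("shifted", size_px = c(48, 64),
                                      shift_px = shift, noise_sd = 0,
                                      seed = 6)
    vs <- van_steensel_ccf(img$ch1, img$ch2, max_shift = 12)
    expect_identical(vs$peak_shift, shift)
  }

  expect_error(van_steensel_ccf(img0$ch1, img0$ch2, max_shift = 40),
               class = "mitostereo_invalid_config")
})

test_that("ccf(0) equals the global Pearson coefficient exactly", {
  img <- generate_two_channel_image("partial", size_px = c(40, 40),
                                    noise_sd = 0.05, seed = 9)
  vs <- van_steensel_ccf(img$ch1, img$ch2, max_shift = 6)
  expect_equal(vs$ccf$ccf[vs$ccf$shift == 0],
               coloc_pearson(img$ch1, img$ch2), tolerance = 1e-15)
})

test_that("shifting a channel translates the cross-correlation curve", {
  # Content confined to the image centre so zero padding stays outside
  # the compared windows.
  set.seed(13)
  base <- matrix(0, 64, 64)
  base[25:40, 25:40] <- matrix(runif(256), 16)
  ch2 <- base + matrix(rnorm(64 * 64, sd = 0.01), 64)
  vs <- van_steensel_ccf(base, ch2, max_shift = 8)
  shifted <- van_steensel_ccf(base, mitostereo:::shift_x(ch2, 5),
                              max_shift = 8)
  expect_identical(shifted$peak_shift - vs$peak_shift, 5L)
  # Central section of the curve translates by the applied shift.
  for (d in -3:3) {
    expect_equal(
      shifted$ccf$ccf[shifted$ccf$shift == d + 5],
      vs$ccf$ccf[vs$ccf$shift == d],
      tolerance = 0.05
    )
  }
})

test_that("independent iid channels give a flat CCF inside the null band", {
  set.seed(17)
  n <- 96
  a <- matrix(rnorm(n * n), n)
  b <- matrix(rnorm(n * n), n)
  vs <- van_steensel_ccf(a, b, max_shift = 10)
  expect_true(all(abs(vs$ccf$ccf) < 3 / sqrt(n * (n - 10))))
})

test_that("three-case classification and Evans bands", {
  expect_identical(classify_coloc(-0.3, 5, eps_shift = 1),
                   "no_colocalization")
  expect_identical(classify_coloc(0.5, 0), "colocalization")
  expect_identical(classify_coloc(0.4, 4, eps_shift = 1),
                   "partial_colocalization")
  expect_identical(classify_coloc(0.4, 1, eps_shift = 1), "colocalization")

  expect_identical(evans_class(-0.1), "no")
  expect_identical(evans_class(0.25), "weak")
  expect_identical(evans_class(0.5), "moderate")
  expect_identical(evans_class(1.0), "very_strong")
  expect_identical(evans_class(c(0.05, 0.65)), c("very_weak", "strong"))
  expect_error(evans_class(0.5, bands = c(weak = 0.4, very_weak = 0.2)),
               class = "mitostereo_invalid_config")
})

test_that("full colocalization analysis ties the pieces together", {
  ident <- coloc_analysis(
    generate_two_channel_image("identical_noisy", size_px = c(40, 40),
                               noise_sd = 0.02, seed = 4),
    max_shift = 6
  )
  expect_identical(ident$case, "colocalization")
  expect_identical(ident$evans, "very_strong")
  expect_identical(ident$ccf_peak_shift, 0L)

  part <- coloc_analysis(
    generate_two_channel_image("shifted", size_px = c(48, 64),
                               shift_px = 5, noise_sd = 0, seed = 4),
    max_shift = 10
  )
  expect_identical(part$case, "partial_colocalization")
  expect_identical(part$ccf_peak_shift, 5L)

  gl <- glance(part)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$pc_global, part$pc_global)
  td <- tidy(part)
  expect_identical(nrow(td), 21L)
})
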