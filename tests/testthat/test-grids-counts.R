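test_that("SURS field placement follows the step lattice", {
  # Degenerate tiling: step equal to the section gives exactly one field.
  one <- surs_fields(c(50, 50), c(50, 50), c(50, 50), seed = 3)
  expect_identical(nrow(one), 1L)

  # 100x100 section, 10x10 fields on a 25 um step: four full periods per
  # axis, with one extra clipped field per axis when the start leaves room
  # for the preceding lattice cell; sampled area is always exactly
  # (10/25)^2 of the section.
  for (seed in 1:20) {
    f <- surs_fields(c(100, 100), c(10, 10), c(25, 25), seed = seed)
    expect_true(nrow(f) %in% c(16L, 20L, 25L))
    expect_true(all(f$x_um >= 0 & f$x_um + f$width_um <= 100 + 1e-9))
    expect_true(all(f$width_um > 0 & f$height_um > 0))
    expect_equal(sum(f$width_um * f$height_um), (10 / 25)^2 * 100^2)
    # Fields never overlap.
    xs <- sort(unique(f$x_um))
    expect_true(all(diff(xs) >= 10 - 1e-9 | diff(xs) == 0))
  }

  expect_error(surs_fields(c(10, 10), c(20, 20), c(20, 20)),
               class = "mitostereo_invalid_config")
  expect_error(surs_fields(c(100, 100), c(10, 10), c(5, 5)),
               class = "mitostereo_invalid_config")
})

test_that("every location has equal SURS inclusion probability", {
  probes <- tidyr::expand_grid(x = seq(2.5, 97.5, by = 10),
                               y = seq(2.5, 97.5, by = 10))
  n_seeds <- 4000
  hits <- numeric(nrow(probes))
  for (seed in seq_len(n_seeds)) {
    f <- surs_fields(c(100, 100), c(10, 10), c(25, 25), seed = seed)
    covered <- vapply(seq_len(nrow(probes)), function(i) {
      any(probes$x[i] >= f$x_um & probes$x[i] < f$x_um + f$width_um &
            probes$y[i] >= f$y_um & probes$y[i] < f$y_um + f$height_um)
    }, logical(1))
    hits <- hits + covered
  }
  p <- (10 / 25)^2
  bound <- 3 * sqrt(p * (1 - p) / n_seeds)
  expect_true(all(abs(hits / n_seeds - p) < bound))
})

test_that("nested grids produce the 6:1 and 16:1 designs", {
  fov <- tibble::tibble(x_um = 0, y_um = 0, width_um = 60, height_um = 40)
  g6 <- point_grid(10, nesting = c(3, 2), origin_offset_um = c(5, 5))
  pts <- overlay_grid(fov, g6)
  expect_identical(nrow(pts), 24L)
  expect_identical(sum(pts$is_coarse), 4L)

  fov2 <- tibble::tibble(x_um = 0, y_um = 0, width_um = 24, height_um = 24)
  g16 <- point_grid(2, nesting = c(4, 4), origin_offset_um = c(1, 1))
  pts2 <- overlay_grid(fov2, g16)
  expect_identical(nrow(pts2), 144L)
  expect_identical(sum(pts2$is_coarse), 9L)

  g1 <- point_grid(10, nesting = c(1, 1), origin_offset_um = c(5, 5))
  pts3 <- overlay_grid(fov, g1)
  expect_true(all(pts3$is_coarse))

  # Ratio identity for exactly tiling lattices.
  expect_equal(nrow(pts), sum(pts$is_coarse) * prod(g6$nesting))
  expect_equal(nrow(pts2), sum(pts2$is_coarse) * prod(g16$nesting))
})

test_that("count_points classifies by the half-open pixel convention", {
  labels <- matrix(c(0L, 0L, 1L,
                     2L, 2L, 1L,
                     3L, 4L, 1L), nrow = 3, byrow = TRUE)
  # manual_section rows are y from the bottom: row 1 = (0,0,1).
  sec <- manual_section(labels[3:1, ], pixel_size_um = 1)
  pts <- tidyr::expand_grid(y_um = c(0.5, 1.5, 2.5),
                            x_um = c(0.5, 1.5, 2.5)) |>
    dplyr::mutate(is_coarse = FALSE)
  tally <- count_points(sec, pts)
  fine <- setNames(tally$count[tally$grid == "fine"],
                   tally$compartment[tally$grid == "fine"])
  expect_identical(fine[["air"]], 2L)
  expect_identical(fine[["septum_other"]], 3L)
  expect_identical(fine[["ae1_capillary"]], 2L)
  expect_identical(fine[["ae1_pillar"]], 1L)
  expect_identical(fine[["ae1_nucleus"]], 1L)
  expect_identical(sum(tally$count[tally$grid == "coarse"]), 0L)

  # Homogeneous field tallies a single label.
  air <- manual_section(matrix(0L, 4, 4))
  t2 <- count_points(air, tibble::tibble(x_um = c(1, 2), y_um = c(1, 2),
                                         is_coarse = c(TRUE, FALSE)))
  expect_identical(sum(t2$count[t2$compartment != "air"]), 0L)

  # A point on a pixel boundary belongs to the higher pixel ([i, i+1)).
  bound <- manual_section(matrix(c(0L, 2L), 1, 2))
  expect_identical(label_at(bound, 1, 0.5), "ae1_capillary")
  expect_error(label_at(bound, 2, 0.5),
               class = "mitostereo_out_of_bounds")
})

test_that("forbidden-line counting tallies each profile exactly once over a tiling", {
  sec <- generate_section(section_config(40, 40, pixel_size_um = 0.2,
                                         mito_density_um2 = 2, seed = 5))
  whole <- count_profiles(sec, whole_section_fov(sec))
  expect_identical(sum(whole$n_0), nrow(sec$profiles))

  tiles <- tidyr::expand_grid(x_um = c(0, 20), y_um = c(0, 20)) |>
    dplyr::mutate(width_um = 20, height_um = 20)
  tiled <- purrr::map(seq_len(nrow(tiles)),
                      ~ count_profiles(sec, tiles[.x, ])) |>
    dplyr::bind_rows() |>
    dplyr::summarise(n_0 = sum(.data$n_0), .by = "compartment")
  expect_identical(
    setNames(tiled$n_0, tiled$compartment),
    setNames(whole$n_0, whole$compartment)
  )

  # Edge rule: right/top edges include, left/bottom exclude.
  prof <- tibble::tibble(x_um = c(2, 0, 1), y_um = c(1, 1, 0),
                         radius_um = 0.1,
                         compartment = "ae1_capillary")
  toy <- manual_section(matrix(2L, 2, 2), profiles = prof)
  fov <- tibble::tibble(x_um = 0, y_um = 0, width_um = 2, height_um = 2)
  expect_identical(count_profiles(toy, fov)$n_0[1], 1L)

  # Empty field.
  empty_fov <- tibble::tibble(x_um = 0, y_um = 0, width_um = 1,
                              height_um = 1)
  none <- manual_section(matrix(2L, 4, 4))
  expect_identical(sum(count_profiles(none, empty_fov)$n_0), 0L)
})

test_that("profile fractions reproduce the pooled study ratios", {
  q_inf <- profile_fraction(infant_counts())
  expect_equal(round(q_inf$q_pct, 1), c(75.7, 24.3))
  q_ad <- profile_fraction(adult_counts())
  expect_equal(round(q_ad$q_pct, 1), c(73.4, 26.6))
  # Both pools are approximately 3:1 capillary:pillar.
  expect_gt(q_inf$q_pct[1] / q_inf$q_pct[2], 2.5)
  expect_gt(q_ad$q_pct[1] / q_ad$q_pct[2], 2.5)

  even <- profile_fraction(compartment_counts(c("a", "b"), c(0, 0), c(1, 1)))
  expect_equal(even$q_pct, c(50, 50))
  expect_equal(sum(q_inf$q_pct), 100)

  expect_error(
    profile_fraction(compartment_counts(c("a", "b"), c(1, 1), c(0, 0))),
    class = "mitostereo_undefined_fraction"
  )
})

test_that("fine-grid label fractions converge to pixel-area fractions", {
  sec <- generate_section(section_config(50, 50, pixel_size_um = 0.1,
                                         mito_density_um2 = 0, seed = 2))
  truth <- section_area_fractions(sec)
  fov <- whole_section_fov(sec)
  est <- function(spacing) {
    pts <- overlay_grid(fov, point_grid(spacing,
                                        origin_offset_um = rep(spacing / 2, 2)))
    tally <- count_points(sec, pts)
    fine <- tally[tally$grid == "fine", ]
    setNames(fine$count / sum(fine$count), fine$compartment)
  }
  sparse <- est(5)
  dense <- est(0.5)
  truth_v <- setNames(truth$fraction, truth$compartment)
  expect_lt(max(abs(dense[names(truth_v)] - truth_v)), 0.02)
  expect_lt(max(abs(sparse[names(truth_v)] - truth_v)), 0.2)
})
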