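#' Expected profile counts under random localization
#'
#' Under the null hypothesis that mitochondrial profiles are distributed at
#' random over the AE1 compartments, the expected count in compartment `c`
#' is proportional to its size as estimated by test points:
#' `N_E,c = N_tot * P_c / P_tot`.
#'
#' @param counts Tibble from [compartment_counts()] (`compartment`, `p`,
#'   `n_0`).
#' @return Input with an added `n_e` column; `sum(n_e) == sum(n_0)`.
#' @export
#' @examples
#' infant <- compartment_counts(c("on_capillary", "above_pillar"),
#'                              p = c(1841, 1241), n_0 = c(1374, 442))
#' expected_counts(infant)
expected_counts <- function(counts) {
  p_tot <- sum(counts$p)
  if (p_tot <= 0) {
    abort("Expected counts undefined: no test points hit any compartment.",
          class = "mitostereo_undefined_expectation")
  }
  dplyr::mutate(counts, n_e = sum(.data$n_0) * .data$p / p_tot)
}

#' Index of relative localization
#'
#' `IRL = N_0 / N_E`: about 1 for random localization, above 1 for
#' preferential and below 1 for non-preferential localization of profiles
#' in a compartment.
#'
#' @param n_0 Observed profile count(s).
#' @param n_e Expected profile count(s), `> 0`.
#' @return `n_0 / n_e`.
#' @export
#' @examples
#' irl(442, 731.23)   # ~0.60, non-preferential
irl <- function(n_0, n_e) {
  if (any(n_e <= 0)) {
    abort("IRL undefined where the expected count is zero.",
          class = "mitostereo_undefined_irl")
  }
  n_0 / n_e
}

#' Classify an IRL value
#'
#' Descriptive labelling of localization: `preferential` if
#' `IRL > 1 + tol`, `non-preferential` if `IRL < 1 - tol`, otherwise
#' `random`.  Statistical significance comes from [chi_squared()], not from
#' this label.
#'
#' @param irl Non-negative IRL value(s).
#' @param tol Half-width of the band treated as random; default 0.05.
#' @return Character vector over
#'   `c("random", "preferential", "non-preferential")`.
#' @export
#' @examples
#' classify_irl(c(1.27, 0.60, 1.0))
classify_irl <- function(irl, tol = 0.05) {
  stopifnot(all(irl >= 0), tol >= 0)
  dplyr::case_when(
    irl > 1 + tol ~ "preferential",
    irl < 1 - tol ~ "non-preferential",
    TRUE ~ "random"
  )
}

#' Chi-squared test of observed versus expected profile distribution
#'
#' Tests the null hypothesis that the observed and expected distributions
#' of mitochondrial profiles over the compartments are equal.  The
#' statistic is `sum((N_0 - N_E)^2 / N_E)` with `k - 1` degrees of freedom
#' and an upper-tail p-value; per-compartment contributions and IRL values
#' are reported alongside.
#'
#' @param counts Tibble from [compartment_counts()].
#' @param irl_tol Band half-width passed to [classify_irl()].
#' @return An `irl_test` object; see [tidy.irl_test()] and
#'   [glance.irl_test()].  A warning is attached (field `low_expected`)
#'   when any expected count falls below 5, where the chi-squared
#'   approximation is doubtful.
#' @export
#' @examples
#' adult <- compartment_counts(c("on_capillary", "above_pillar"),
#'                             p = c(1306, 347), n_0 = c(859, 311))
#' chi_squared(adult)
chi_squared <- function(counts, irl_tol = 0.05) {
  tab <- expected_counts(counts)
  if (any(tab$n_e <= 0)) {
    abort(paste0(
      "Chi-squared undefined: expected count is zero in compartment(s) ",
      paste(tab$compartment[tab$n_e <= 0], collapse = ", "),
      " (no test points hit them)."
    ), class = "mitostereo_undefined_expectation")
  }
  low <- any(tab$n_e < 5)
  if (low) {
    warn("Some expected counts are below 5; the chi-squared approximation may be poor.")
  }
  tab <- tab |>
    dplyr::mutate(
      irl = irl(.data$n_0, .data$n_e),
      localization = classify_irl(.data$irl, tol = irl_tol),
      chi2 = (.data$n_0 - .data$n_e)^2 / .data$n_e
    )
  statistic <- sum(tab$chi2)
  df <- nrow(tab) - 1L
  structure(
    list(
      table = tab,
      statistic = statistic,
      df = df,
      p_value = pchisq(statistic, df, lower.tail = FALSE),
      n_tot = sum(tab$n_0),
      p_tot = sum(tab$p),
      low_expected = low
    ),
    class = "irl_test"
  )
}

#' @export
print.irl_test <- function(x, digits = 2, ...) {
  cat("Index of relative localization / chi-squared test\n")
  tab <- x$table |>
    dplyr::mutate(dplyr::across(c("n_e", "irl", "chi2"),
                                ~ round(.x, digits)))
  print(as.data.frame(tab), row.names = FALSE)
  cat(sprintf("X-squared = %.2f, df = %d, p-value %s\n",
              x$statistic, x$df,
              format.pval(x$p_value, digits = 3, eps = 1e-3)))
  invisible(x)
}

#' Tidy an IRL test
#'
#' @param x An `irl_test` from [chi_squared()].
#' @param ... Unused.
#' @return One row per compartment: `compartment`, `p`, `n_0`, `n_e`,
#'   `irl`, `localization`, `chi2`.
#' @export
tidy.irl_test <- function(x, ...) x$table

#' One-row summary of an IRL test
#'
#' @param x An `irl_test` from [chi_squared()].
#' @param ... Unused.
#' @return Tibble with `statistic`, `df`, `p_value`, `n_tot`, `p_tot`,
#'   `low_expected`.
#' @export
glance.irl_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n_tot = x$n_tot, p_tot = x$p_tot, low_expected = x$low_expected
  )
}

#' Run the localization analysis on synthetic sections
#'
#' Pools test-point and profile counts over fields and sections, then runs
#' the expected-count / IRL / chi-squared cascade.  Following the
#' compartment definitions of the analysis, test points hitting the AE1
#' nucleus are excluded from the size estimator, while profiles over the
#' nucleus are pooled with the above-pillar compartment (from a single thin
#' section a perinuclear mitochondrion cannot be separated from one above a
#' pillar).
#'
#' @param sections A `synthetic_section` or list of them.
#' @param grid A [point_grid()] used as the compartment-size test system
#'   (the study design uses a 25-point grid per field).
#' @param fovs Tibble of fields from [surs_fields()] applied to every
#'   section, or `NULL` to use one field covering each whole section.
#' @param irl_tol Band half-width passed to [classify_irl()].
#' @return An `irl_test` over the compartments `on_capillary` and
#'   `above_pillar`.
#' @export
irl_pipeline <- function(sections, grid, fovs = NULL, irl_tol = 0.05) {
  if (inherits(sections, "synthetic_section")) sections <- list(sections)
  acc <- purrr::map(sections, function(sec) {
    sec_fovs <- fovs %||% tibble::tibble(
      fov_id = 1L, x_um = 0, y_um = 0,
      width_um = ncol(sec$labels) * sec$pixel_size_um,
      height_um = nrow(sec$labels) * sec$pixel_size_um
    )
    purrr::map(seq_len(nrow(sec_fovs)), function(i) {
      fov <- sec_fovs[i, ]
      pts <- overlay_grid(fov, grid)
      ptally <- count_points(sec, pts, fov_id = fov$fov_id)
      prof <- count_profiles(sec, fov)
      n0 <- setNames(prof$n_0, prof$compartment)
      fine <- ptally[ptally$grid == "fine", ]
      pc <- setNames(fine$count, fine$compartment)
      tibble::tibble(
        compartment = c("on_capillary", "above_pillar"),
        p = c(pc[["ae1_capillary"]], pc[["ae1_pillar"]]),
        n_0 = c(n0[["ae1_capillary"]],
                n0[["ae1_pillar"]] + n0[["ae1_nucleus"]])
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  pooled <- acc |>
    dplyr::summarise(p = sum(.data$p), n_0 = sum(.data$n_0),
                     .by = "compartment")
  chi_squared(
    compartment_counts(pooled$compartment, pooled$p, pooled$n_0),
    irl_tol = irl_tol
  )
}
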