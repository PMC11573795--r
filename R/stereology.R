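#' Point-count volume-fraction estimators
#'
#' Ratio estimators for the multistage stereological design.  Test points
#' falling on a structure estimate its volume fraction within a reference
#' space; when numerator and denominator come from nested grids of
#' different density the sparser count is scaled by the coarse:fine ratio.
#'
#' * `vv_sept_par()` - volume fraction of interalveolar septa in lung
#'   parenchyma from the light-microscopic 6:1 grid: septa are counted on
#'   the fine grid and air on the coarse grid, so
#'   `P_sept / (P_sept + 6 * P_air)`.
#' * `vv_mito_ae1()` - volume fraction of mitochondria in AE1 cells from
#'   the electron-microscopic 16:1 grid: mitochondria on the fine grid,
#'   AE1 cells on the coarse grid, so `P_mito / (16 * P_ae1)`.
#' * `vv_ratio()` - same-grid ratio `P_num / P_den`, used for AE1 per
#'   septum and for the AE1 sub-compartment fractions.
#'
#' @param p_sept_fine,p_air_coarse,p_mito_fine,p_ae1_coarse,p_num,p_den
#'   Non-negative point counts.
#' @param coarse_ratio Fine:coarse point ratio of the nested design
#'   (6 for the light-microscopic grid, 16 for the EM grid).
#' @return A volume fraction in `[0, 1]`.
#' @name volume_fractions
NULL

#' @rdname volume_fractions
#' @export
#' @examples
#' vv_sept_par(65, 35)          # 65 / (65 + 6 * 35)
#' vv_mito_ae1(96, 100)         # 0.06
vv_sept_par <- function(p_sept_fine, p_air_coarse, coarse_ratio = 6) {
  den <- p_sept_fine + coarse_ratio * p_air_coarse
  if (any(den <= 0)) {
    abort("Volume fraction undefined: no points hit septum or air.",
          class = "mitostereo_undefined_fraction")
  }
  p_sept_fine / den
}

#' @rdname volume_fractions
#' @export
vv_mito_ae1 <- function(p_mito_fine, p_ae1_coarse, coarse_ratio = 16) {
  if (any(p_ae1_coarse <= 0)) {
    abort("Volume fraction undefined: no points hit AE1 cells.",
          class = "mitostereo_undefined_fraction")
  }
  p_mito_fine / (coarse_ratio * p_ae1_coarse)
}

#' @rdname volume_fractions
#' @export
vv_ratio <- function(p_num, p_den) {
  if (any(p_den <= 0)) {
    abort("Volume fraction undefined: zero reference count.",
          class = "mitostereo_undefined_fraction")
  }
  p_num / p_den
}

#' Absolute volume from a fraction and its reference volume
#'
#' @param fraction Volume fraction in `[0, 1]`.
#' @param reference Reference volume (same units returned).
#' @return `fraction * reference`.
#' @export
#' @examples
#' total_volume(0.325, 115)  # total septal volume, cm^3
total_volume <- function(fraction, reference) {
  stopifnot(all(fraction >= 0 & fraction <= 1), all(reference >= 0))
  fraction * reference
}

#' Volume cascade from point tallies
#'
#' Chains the ratio estimators into per-subject absolute volumes: septa in
#' parenchyma (6:1 light-microscopic grid), AE1 cells in septa and
#' mitochondria in AE1 cells (9/144-point EM grid), and the three AE1
#' sub-compartments (25-point grid), each total volume being the fraction
#' times its reference volume down the chain from the parenchymal volume.
#' Counts must be pooled over all fields of a subject before calling
#' (ratio-of-sums estimation).
#'
#' @param data Data frame with one row per subject and columns
#'   `v_par` (parenchymal reference volume, cm^3),
#'   `p_sept_fine`, `p_air_coarse` (light-microscopic grid),
#'   `p_ae1_coarse`, `p_sept_coarse`, `p_mito_fine` (EM grid; the septum
#'   count includes its AE1 points),
#'   `p_comp1`, `p_comp2`, `p_nuc` (25-point grid over AE1).
#'   Additional columns (e.g. `subject`, `age_group`) are carried through.
#' @return Tibble with the input identifier columns plus fractions
#'   `vv_sept_par`, `vv_ae1_sept`, `vv_comp1`, `vv_comp2`, `vv_nuc`,
#'   `vv_mito` and volumes `v_sept`, `v_ae1`, `v_comp1`, `v_comp2`,
#'   `v_nuc`, `v_mito`.
#' @export
cascade <- function(data) {
  need <- c("v_par", "p_sept_fine", "p_air_coarse", "p_ae1_coarse",
            "p_sept_coarse", "p_mito_fine", "p_comp1", "p_comp2", "p_nuc")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("`data` is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mitostereo_schema_error")
  }
  p_ae1_25 <- data$p_comp1 + data$p_comp2 + data$p_nuc
  cascade_volumes(
    dplyr::select(data, -dplyr::all_of(setdiff(need, "v_par"))),
    vv_sept_par = vv_sept_par(data$p_sept_fine, data$p_air_coarse),
    vv_ae1_sept = vv_ratio(data$p_ae1_coarse, data$p_sept_coarse),
    vv_comp1 = vv_ratio(data$p_comp1, p_ae1_25),
    vv_comp2 = vv_ratio(data$p_comp2, p_ae1_25),
    vv_nuc = vv_ratio(data$p_nuc, p_ae1_25),
    vv_mito = vv_mito_ae1(data$p_mito_fine, data$p_ae1_coarse),
    v_par = data$v_par
  )
}

#' Volume cascade from known fractions
#'
#' The deterministic tail of [cascade()]: multiply fractions down the
#' reference chain.  Useful for recomputing published totals from printed
#' fractions.
#'
#' @param data Data frame of identifier columns carried through (may be
#'   omitted).
#' @param vv_sept_par,vv_ae1_sept,vv_comp1,vv_comp2,vv_nuc,vv_mito Volume
#'   fractions.
#' @param v_par Parenchymal reference volume.
#' @return Tibble as described in [cascade()].
#' @export
#' @examples
#' cascade_volumes(vv_sept_par = 0.325, vv_ae1_sept = 0.154,
#'                 vv_comp1 = 0.613, vv_comp2 = 0.273, vv_nuc = 0.114,
#'                 vv_mito = 0.060, v_par = 115)
cascade_volumes <- function(data = NULL, vv_sept_par, vv_ae1_sept,
                            vv_comp1, vv_comp2, vv_nuc, vv_mito, v_par) {
  v_sept <- total_volume(vv_sept_par, v_par)
  v_ae1 <- total_volume(vv_ae1_sept, v_sept)
  out <- tibble::tibble(
    v_par = v_par,
    vv_sept_par = vv_sept_par, v_sept = v_sept,
    vv_ae1_sept = vv_ae1_sept, v_ae1 = v_ae1,
    vv_comp1 = vv_comp1, v_comp1 = total_volume(vv_comp1, v_ae1),
    vv_comp2 = vv_comp2, v_comp2 = total_volume(vv_comp2, v_ae1),
    vv_nuc = vv_nuc, v_nuc = total_volume(vv_nuc, v_ae1),
    vv_mito = vv_mito, v_mito = total_volume(vv_mito, v_ae1)
  )
  if (!is.null(data)) {
    data <- dplyr::select(data, -dplyr::any_of("v_par"))
    if (ncol(data)) out <- dplyr::bind_cols(tibble::as_tibble(data), out)
  }
  out
}

#' Unweighted group mean of a stereological quantity
#'
#' @param values Non-empty numeric vector (one value per subject).
#' @return Arithmetic mean.
#' @export
#' @examples
#' group_mean(c(0.060, 0.069, 0.060))  # 0.063
group_mean <- function(values) {
  if (length(values) == 0) {
    abort("Cannot average an empty group.", class = "mitostereo_empty_group")
  }
  mean(values)
}
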