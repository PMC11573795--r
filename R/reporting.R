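#' Configure a synthetic stereological study
#'
#' Describes a full simulated study: the subject roster with parenchymal
#' reference volumes, the per-subject section geometry, the sampling design
#' (fields per section, grid designs) and one root seed from which every
#' subject's random streams are derived.
#'
#' @param subjects Tibble with columns `subject`, `age_group`, `v_par`
#'   (parenchymal volume, cm^3); subject ids must be unique.
#' @param section Template [section_config()]; its seed is overridden per
#'   subject/section from the study seed.
#' @param n_sections Sections (blocks) per subject.
#' @param fov_size,fov_step Field-of-view size and SURS step, micrometres.
#' @param lm_grid,em_grid,irl_grid The three point-grid designs: the 6:1
#'   septum/air grid, the 16:1 mitochondria/AE1 grid, and the 25-point
#'   compartment grid.
#' @param seed Root seed.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(subjects,
                         section = section_config(100, 100,
                                                  pixel_size_um = 0.2),
                         n_sections = 2L,
                         fov_size = c(25, 25),
                         fov_step = c(50, 50),
                         lm_grid = point_grid(5, nesting = c(3, 2)),
                         em_grid = point_grid(2, nesting = c(4, 4)),
                         irl_grid = point_grid(5, nesting = c(1, 1)),
                         seed = 1L) {
  subjects <- tibble::as_tibble(subjects)
  need <- c("subject", "age_group", "v_par")
  missing <- setdiff(need, names(subjects))
  if (length(missing)) {
    abort(paste0("`subjects` is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mitostereo_schema_error")
  }
  if (nrow(subjects) == 0) {
    abort("`subjects` must contain at least one subject.",
          class = "mitostereo_schema_error")
  }
  if (anyDuplicated(subjects$subject)) {
    abort("Subject ids must be unique.", class = "mitostereo_schema_error")
  }
  if (any(!nzchar(subjects$age_group)) || any(subjects$v_par <= 0)) {
    abort("`age_group` must be nonempty and `v_par` positive.",
          class = "mitostereo_schema_error")
  }
  structure(
    list(subjects = subjects, section = section,
         n_sections = as.integer(n_sections),
         fov_size = fov_size, fov_step = fov_step,
         lm_grid = lm_grid, em_grid = em_grid, irl_grid = irl_grid,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Run a full simulated study
#'
#' For every subject: generates sections, samples fields by SURS, performs
#' the three counting passes (septum/air on the 6:1 grid, AE1/septum and
#' mitochondria on the 16:1 grid, AE1 sub-compartments on the 25-point grid
#' plus exhaustive profile counting), pools counts per subject
#' (ratio-of-sums) and computes the volume cascade.  Counts are then pooled
#' per age group for the localization (IRL / chi-squared) analysis and the
#' observed profile fractions.  Fully deterministic for a fixed study seed.
#'
#' @param config A [study_config()].
#' @return A `study_bundle`: list with `volumes` (per-subject cascade
#'   tibble), `counts` (pooled per-subject counts), `irl` (named list of
#'   `irl_test` per age group), `q` (profile fractions per age group) and
#'   `log` (seed and per-stage tallies).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  subj_rows <- purrr::map(seq_len(nrow(config$subjects)), function(si) {
    sub <- config$subjects[si, ]
    per_sec <- purrr::map(seq_len(config$n_sections), function(bi) {
      stream <- si * 1000L + bi
      cfg <- config$section
      cfg$seed <- as.integer(derive_seed(config$seed, stream) %% 1e6)
      sec <- generate_section(cfg)
      ext <- c(ncol(sec$labels), nrow(sec$labels)) * sec$pixel_size_um
      fovs <- surs_fields(ext, config$fov_size, config$fov_step,
                          seed = derive_seed(config$seed, stream + 1L))
      set.seed(derive_seed(config$seed, stream + 2L))
      count_section(sec, fovs, config)
    })
    counts <- dplyr::bind_rows(per_sec) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), sum))
    dplyr::bind_cols(sub, counts)
  }) |> dplyr::bind_rows()

  volumes <- cascade(subj_rows)

  groups <- split(subj_rows, subj_rows$age_group)
  irl_tests <- purrr::map(groups, function(g) {
    chi_squared(compartment_counts(
      c("on_capillary", "above_pillar"),
      p = c(sum(g$p_comp1), sum(g$p_comp2)),
      n_0 = c(sum(g$n0_comp1), sum(g$n0_comp2))
    ))
  })
  q <- purrr::imap(groups, function(g, name) {
    profile_fraction(tibble::tibble(
      compartment = c("on_capillary", "above_pillar"),
      n_0 = c(sum(g$n0_comp1), sum(g$n0_comp2))
    )) |> dplyr::mutate(age_group = name, .before = 1)
  }) |> dplyr::bind_rows()

  structure(
    list(
      volumes = volumes,
      counts = subj_rows,
      irl = irl_tests,
      q = q,
      log = list(seed = config$seed, n_subjects = nrow(config$subjects),
                 n_sections = config$n_sections,
                 n_profiles = sum(subj_rows$n0_comp1 + subj_rows$n0_comp2))
    ),
    class = "study_bundle"
  )
}

# One section's counting passes, pooled over its fields.
count_section <- function(sec, fovs, config) {
  per_fov <- purrr::map(seq_len(nrow(fovs)), function(i) {
    fov <- fovs[i, ]
    lm <- count_points(sec, overlay_grid(fov, config$lm_grid), fov$fov_id)
    em_pts <- overlay_grid(fov, config$em_grid)
    em <- count_points(sec, em_pts, fov$fov_id)
    irl_pts <- overlay_grid(fov, config$irl_grid)
    il <- count_points(sec, irl_pts, fov$fov_id)
    prof <- count_profiles(sec, fov)
    n0 <- setNames(prof$n_0, prof$compartment)
    g <- function(tally, grid, labels) {
      sum(tally$count[tally$grid == grid & tally$compartment %in% labels])
    }
    sept_labels <- c("septum_other", AE1_COMPARTMENTS)
    tibble::tibble(
      p_sept_fine = g(lm, "fine", sept_labels),
      p_air_coarse = g(lm, "coarse", "air"),
      p_ae1_coarse = g(em, "coarse", AE1_COMPARTMENTS),
      p_sept_coarse = g(em, "coarse", sept_labels),
      p_mito_fine = count_mito_points(sec, em_pts),
      p_comp1 = g(il, "fine", "ae1_capillary"),
      p_comp2 = g(il, "fine", "ae1_pillar"),
      p_nuc = g(il, "fine", "ae1_nucleus"),
      n0_comp1 = n0[["ae1_capillary"]],
      n0_comp2 = n0[["ae1_pillar"]] + n0[["ae1_nucleus"]]
    )
  })
  dplyr::bind_rows(per_fov) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum))
}

#' Render an IRL test as a publication-shaped table
#'
#' Formats an `irl_test` the way the study tables print it: one row per
#' compartment with `n_0`, `p`, `n_e` (2 dp), `irl` (2 dp) and the
#' chi-squared contribution (2 dp), plus a totals row.  Note the totals row
#' sums every column including IRL; the summed IRL is a display artifact of
#' that convention, not a statistic.
#'
#' @param x An `irl_test`.
#' @return Tibble ready for CSV export.
#' @export
format_irl_table <- function(x) {
  tab <- x$table
  body <- tibble::tibble(
    compartment = tab$compartment,
    n_0 = tab$n_0, p = tab$p,
    n_e = round(tab$n_e, 2), irl = round(tab$irl, 2),
    chi2 = round(tab$chi2, 2)
  )
  dplyr::bind_rows(
    body,
    tibble::tibble(
      compartment = "total",
      n_0 = sum(body$n_0), p = sum(body$p),
      n_e = round(sum(tab$n_e), 2),
      irl = round(sum(round(tab$irl, 2)), 2),
      chi2 = round(sum(tab$chi2), 2)
    )
  )
}

#' Write a study bundle to disk
#'
#' Writes the per-subject volume table, one publication-shaped IRL table
#' per age group, the profile-fraction table, and a JSON summary carrying
#' the seed and per-stage tallies for provenance.
#'
#' @param bundle A `study_bundle` from [run_study()].
#' @param dir Output directory (created if missing).
#' @return The written paths, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(volumes = file.path(dir, "volumes.csv"),
             q = file.path(dir, "profile_fractions.csv"),
             summary = file.path(dir, "summary.json"))
  readr::write_csv(
    dplyr::mutate(
      bundle$volumes,
      dplyr::across(dplyr::starts_with("vv_"), ~ round(.x, 3)),
      dplyr::across(c(dplyr::starts_with("v_"), -"v_mito"), ~ round(.x, 1)),
      v_mito = round(.data$v_mito, 3)
    ),
    paths[["volumes"]]
  )
  readr::write_csv(dplyr::mutate(bundle$q, q_pct = round(.data$q_pct, 1)),
                   paths[["q"]])
  for (g in names(bundle$irl)) {
    p <- file.path(dir, paste0("irl_", g, ".csv"))
    readr::write_csv(format_irl_table(bundle$irl[[g]]), p)
    paths[[paste0("irl_", g)]] <- p
  }
  jsonlite::write_json(
    list(
      log = bundle$log,
      irl = purrr::map(bundle$irl, ~ as.list(glance(.x)))
    ),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle> ", nrow(x$volumes), " subjects, ",
      x$log$n_profiles, " profiles counted\n", sep = "")
  for (g in names(x$irl)) {
    s <- glance(x$irl[[g]])
    cat(sprintf("  %s: X-squared = %.2f, df = %d, p %s\n", g, s$statistic,
                s$df, format.pval(s$p_value, digits = 3, eps = 1e-3)))
  }
  invisible(x)
}
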