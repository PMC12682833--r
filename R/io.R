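#' Read and validate a root observation table
#'
#' Reads the long-format per-image CSV (`row_id, genotype, session,
#' position_mm, root_length_cm`, optionally `year`; alternatively
#' `root_length_px`, converted with the geometry's pixel calibration).
#' Schema violations are reported with file line numbers (the header is
#' line 1).
#'
#' @param path CSV file path.
#' @param geom A [tube_geometry()]; used for pixel conversion and position
#'   range checks.
#' @return A validated tibble with a `root_length_cm` column.
#' @export
read_observations <- function(path, geom = tube_geometry()) {
  if (!file.exists(path)) {
    abort(paste0("observation file not found: ", path), class = "deeproot_error")
  }
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("row_id", "genotype", "session", "position_mm")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols)) {
    abort(paste0("observation file lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "deeproot_error")
  }
  if (!"root_length_cm" %in% names(obs)) {
    if ("root_length_px" %in% names(obs)) {
      obs$root_length_cm <- pixels_to_cm(check_numeric(obs$root_length_px, "root_length_px"), geom)
    } else {
      abort("observation file needs a root_length_cm or root_length_px column",
            class = "deeproot_error")
    }
  }
  obs$position_mm <- check_numeric(obs$position_mm, "position_mm")
  obs$root_length_cm <- check_numeric(obs$root_length_cm, "root_length_cm")
  neg <- which(obs$root_length_cm < 0)
  if (length(neg)) {
    abort(paste0("negative root length on line(s): ", paste(neg + 1, collapse = ", ")),
          class = "deeproot_error")
  }
  out_range <- which(obs$position_mm < geom$first_image_position_mm - 1e-9 |
                       obs$position_mm > geom$tube_length_mm + 1e-9)
  if (length(out_range)) {
    abort(paste0("position outside imaged tube range on line(s): ",
                 paste(out_range + 1, collapse = ", ")), class = "deeproot_error")
  }
  message(sprintf("read %d root observations from %s", nrow(obs), path))
  obs
}

check_numeric <- function(x, name) {
  if (!is.numeric(x)) {
    suppressWarnings(xn <- as.numeric(x))
    bad <- which(!is.na(x) & is.na(xn))
    if (length(bad)) {
      abort(paste0("non-numeric ", name, " on line(s): ", paste(bad + 1, collapse = ", ")),
            class = "deeproot_error")
    }
    x <- xn
  }
  na <- which(is.na(x))
  if (length(na)) {
    abort(paste0("missing ", name, " on line(s): ", paste(na + 1, collapse = ", ")),
          class = "deeproot_error")
  }
  x
}

#' Read and validate a tissue sample table
#'
#' Schema: `row_id, genotype, tissue, dry_mass_g, n_pct, delta15N,
#' delta13C, delta2H` (optionally `year`). Delta columns may be missing
#' per sample (empty fields); masses and N concentrations must be present
#' and in range.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_tissue_samples <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("tissue file not found: ", path), class = "deeproot_error")
  }
  ts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("row_id", "genotype", "tissue", "dry_mass_g", "n_pct",
           "delta15N", "delta13C", "delta2H")
  missing_cols <- setdiff(req, names(ts))
  if (length(missing_cols)) {
    abort(paste0("tissue file lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "deeproot_error")
  }
  bad_tissue <- which(!ts$tissue %in% c("grain", "straw"))
  if (length(bad_tissue)) {
    abort(paste0("tissue must be grain or straw; offending line(s): ",
                 paste(bad_tissue + 1, collapse = ", ")), class = "deeproot_error")
  }
  ts$dry_mass_g <- check_numeric(ts$dry_mass_g, "dry_mass_g")
  ts$n_pct <- check_numeric(ts$n_pct, "n_pct")
  if (any(ts$dry_mass_g < 0)) abort("dry_mass_g must be non-negative", class = "deeproot_error")
  if (any(ts$n_pct < 0 | ts$n_pct > 100)) {
    abort("n_pct must lie in [0, 100]", class = "deeproot_error")
  }
  message(sprintf("read %d tissue samples from %s", nrow(ts), path))
  ts
}

#' Read a structured run configuration
#'
#' YAML with optional blocks `geometry`, `dose`, `constants`, `analysis`
#' (fields `bin_width_m`, `target_cm`, `intervals`, `alpha`, `min_reps`,
#' `fit_sigmoid`), `paths` (`roots`, `tissue`, `outdir`) and `seed`.
#' Unspecified keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "deeproot_error")
  }
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' Assemble a run configuration from a list
#'
#' @param x Named list with the blocks described in [read_run_config()].
#' @return A list of class `run_config`.
#' @export
as_run_config <- function(x = list()) {
  analysis <- modifyList(list(
    bin_width_m = 0.30, target_cm = 40,
    intervals = list(c(1.6, 1.8)), alpha = 0.05, min_reps = 4,
    fit_sigmoid = TRUE
  ), x$analysis %||% list())
  if (analysis$target_cm <= 0) abort("target_cm must be positive", class = "deeproot_error")
  if (analysis$alpha <= 0 || analysis$alpha >= 1) abort("alpha must lie in (0, 1)", class = "deeproot_error")
  structure(list(
    geometry = do.call(tube_geometry, x$geometry %||% list()),
    dose = do.call(tracer_dose, x$dose %||% list()),
    consts = do.call(isotope_constants, x$constants %||% list()),
    analysis = analysis,
    paths = x$paths %||% list(),
    seed = x$seed %||% 1L
  ), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the three analysis stages on validated inputs: `traits`
#' (profiles and deep-rooting traits per row), `isotopes` (excess 15N,
#' tracer recovery, model transforms) and `stats` (replication filter,
#' genotype means, cultivar-mean correlations). Writes tidy CSVs and a
#' human-readable report to `outdir`; a failure in any stage aborts with
#' the stage name and cause. Deterministic given inputs.
#'
#' @param config A [read_run_config()]/[as_run_config()] result; `paths`
#'   must name the `roots` and `tissue` CSVs and an `outdir`.
#' @return Invisibly, a list with the stage outputs (`traits`, `isotopes`,
#'   `genotype_means`, `correlations`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$paths$outdir %||% "."
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "deeproot_stage_error")
    })
  }

  traits <- stage("traits", {
    obs <- read_observations(config$paths$roots, config$geometry)
    compute_root_traits(obs, config$geometry,
                        target_cm = config$analysis$target_cm,
                        intervals = config$analysis$intervals,
                        fit_sigmoid = config$analysis$fit_sigmoid)
  })

  iso <- stage("isotopes", {
    ts <- read_tissue_samples(config$paths$tissue)
    rec <- recovery_percent(ts, config$dose, config$consts)
    grain <- ts |>
      filter(.data$tissue == "grain") |>
      mutate(ln_delta15N = transform_for_model(.data$delta15N, "15N"),
             ln_delta2H90 = ifelse(is.na(.data$delta2H), NA_real_,
                                   log(.data$delta2H + 90)))
    left_join(grain, rec, by = "row_id")
  })

  stats_out <- stage("stats", {
    key <- distinct(iso, .data$row_id, .data$genotype)
    tr <- traits
    if (!"year" %in% names(tr)) tr$year <- 1L
    filtered <- replication_filter(tr, min_reps = config$analysis$min_reps, scope = "per-year")
    means_dr <- cultivar_means(filtered, .data$deep_root40_cm)
    iso_means <- iso |>
      group_by(.data$genotype) |>
      summarise(ln_delta15N = mean(.data$ln_delta15N, na.rm = TRUE),
                delta13C = mean(.data$delta13C, na.rm = TRUE),
                ln_delta2H90 = mean(.data$ln_delta2H90, na.rm = TRUE),
                .groups = "drop")
    xy <- left_join(means_dr, iso_means, by = "genotype")
    cors <- bind_rows(
      mutate(cultivar_mean_correlation(xy, mean, ln_delta15N),
             var_x = "deep_root40_cm", var_y = "ln_delta15N"),
      mutate(cultivar_mean_correlation(xy, mean, delta13C),
             var_x = "deep_root40_cm", var_y = "delta13C"),
      mutate(cultivar_mean_correlation(xy, mean, ln_delta2H90),
             var_x = "deep_root40_cm", var_y = "ln_delta2H90")
    ) |>
      select("var_x", "var_y", "r", "p", "n", "note")
    gm <- tryCatch(
      estimate_genotype_means(filtered, deep_root40_cm, alpha = config$analysis$alpha),
      deeproot_error = function(e) NULL
    )
    list(correlations = cors, genotype_means = gm)
  })

  files <- c(
    traits = file.path(outdir, "traits.csv"),
    isotopes = file.path(outdir, "isotope_results.csv"),
    correlations = file.path(outdir, "correlations.csv"),
    genotype_means = file.path(outdir, "genotype_means.csv"),
    report = file.path(outdir, "report.txt")
  )
  readr::write_csv(traits, files["traits"], na = "")
  readr::write_csv(iso, files["isotopes"], na = "")
  readr::write_csv(stats_out$correlations, files["correlations"], na = "")
  if (!is.null(stats_out$genotype_means)) {
    readr::write_csv(tidy(stats_out$genotype_means), files["genotype_means"], na = "")
  }

  rpt <- c(
    "deeproot pipeline report",
    sprintf("rows: %d, genotypes: %d", dplyr::n_distinct(traits$row_id),
            dplyr::n_distinct(traits$genotype)),
    sprintf("mean DeepRoot40: %.1f cm (n = %d defined)",
            mean(traits$deep_root40_cm, na.rm = TRUE), sum(!is.na(traits$deep_root40_cm))),
    sprintf("mean grain 15N recovery: %.2f %%", mean(iso$recovery_pct_grain, na.rm = TRUE)),
    "",
    "cultivar-mean correlations:",
    utils::capture.output(as.data.frame(stats_out$correlations))
  )
  if (!is.null(stats_out$genotype_means)) {
    rpt <- c(rpt, "", "genotype means (deep_root40_cm):",
             utils::capture.output(as.data.frame(tidy(stats_out$genotype_means))))
  }
  writeLines(rpt, files["report"])

  invisible(list(traits = traits, isotopes = iso,
                 correlations = stats_out$correlations,
                 genotype_means = stats_out$genotype_means,
                 files = files))
}
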