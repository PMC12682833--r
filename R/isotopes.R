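#' Isotope ratio standards and natural-abundance baseline
#'
#' Literature heavy/light isotope ratios of the international reference
#' standards: atmospheric N2 for 15N/14N, VPDB for 13C/12C, VSMOW for
#' 2H/1H. The unlabelled baseline for tracer excess defaults to
#' delta15N = 0 permil against the air standard; set it to a measured
#' control-plot value when one is available.
#'
#' @param R_std_15N,R_std_13C,R_std_2H Standard isotope ratios.
#' @param natural_15N_delta_baseline Baseline delta15N (permil) treated as
#'   unlabelled when computing tracer excess.
#' @return A named list of class `isotope_constants`.
#' @export
isotope_constants <- function(R_std_15N = 0.0036765,
                              R_std_13C = 0.0111802,
                              R_std_2H = 0.00015576,
                              natural_15N_delta_baseline = 0) {
  if (any(c(R_std_15N, R_std_13C, R_std_2H) <= 0)) {
    abort("standard isotope ratios must be positive", class = "deeproot_error")
  }
  structure(list(R_std_15N = R_std_15N, R_std_13C = R_std_13C, R_std_2H = R_std_2H,
                 natural_15N_delta_baseline = natural_15N_delta_baseline),
            class = "isotope_constants")
}

#' Applied tracer dose and its per-row partition
#'
#' The deep tracer application: a mixture of carrier water, 15N-labelled
#' calcium nitrate and 2H-labelled water injected into subsoil irrigation
#' lines at 1.6 and 1.8 m depth. Totals are per labelled line application;
#' `n_injections` such applications contribute to the facility total, so
#' the tracer applied per crop row is
#' `total_15N_g * n_injections / n_rows_total`. The default `n_injections`
#' of 3 makes the per-row amount equal twice the printed per-row-side dose
#' (`total_15N_g / n_row_sides`).
#'
#' @param total_15N_g Grams of 15N per application (default 1.51725).
#' @param carrier_ca_nitrate_g Grams of labelled calcium nitrate (8.925).
#' @param carrier_water_L Litres of carrier water (54.6).
#' @param total_2H2O_mL Millilitres of 2H-labelled water (1000).
#' @param n_row_sides Divisor reproducing the printed per-row-side amounts
#'   (default 200).
#' @param n_rows_total Number of crop rows sharing the facility total (300).
#' @param n_injections Labelled line applications contributing to the
#'   facility total (default 3).
#' @param injection_depth_m Depths (m) of the two injection lines.
#' @return A named list of class `tracer_dose` with derived fields
#'   `per_row_side_15N_g`, `per_row_side_2H2O_mL` and `per_row_15N_g`.
#' @export
tracer_dose <- function(total_15N_g = 1.51725,
                        carrier_ca_nitrate_g = 8.925,
                        carrier_water_L = 54.6,
                        total_2H2O_mL = 1000,
                        n_row_sides = 200,
                        n_rows_total = 300,
                        n_injections = 3,
                        injection_depth_m = c(1.6, 1.8)) {
  amounts <- c(total_15N_g, carrier_ca_nitrate_g, carrier_water_L, total_2H2O_mL,
               n_row_sides, n_rows_total, n_injections)
  if (any(amounts <= 0)) abort("all tracer dose quantities must be positive", class = "deeproot_error")
  structure(list(
    total_15N_g = total_15N_g,
    carrier_ca_nitrate_g = carrier_ca_nitrate_g,
    carrier_water_L = carrier_water_L,
    total_2H2O_mL = total_2H2O_mL,
    n_row_sides = n_row_sides,
    n_rows_total = n_rows_total,
    n_injections = n_injections,
    injection_depth_m = injection_depth_m,
    per_row_side_15N_g = total_15N_g / n_row_sides,
    per_row_side_2H2O_mL = total_2H2O_mL / n_row_sides,
    per_row_15N_g = total_15N_g * n_injections / n_rows_total
  ), class = "tracer_dose")
}

#' Tracer amount applied per row side
#'
#' @param total_amount Total amount applied (any unit).
#' @param n_row_sides Number of row sides sharing it.
#' @return `total_amount / n_row_sides` (unrounded; round only for display).
#' @examples
#' dose_per_row_side(1.51725, 200)  # 0.00759 g to 3 significant figures
#' dose_per_row_side(1000, 200)     # 5 mL
#' @export
dose_per_row_side <- function(total_amount, n_row_sides) {
  if (any(n_row_sides <= 0)) abort("n_row_sides must be positive", class = "deeproot_error")
  total_amount / n_row_sides
}

#' Convert delta notation to atom fraction
#'
#' `R = (delta/1000 + 1) * R_std`; atom fraction `= R / (1 + R)`.
#' Strictly increasing in delta, always in (0, 1).
#'
#' @param delta_permil Delta value(s) in permil; must exceed -1000.
#' @param R_std Heavy/light ratio of the reference standard.
#' @return Atom fraction(s) of the heavy isotope.
#' @export
delta_to_atom_fraction <- function(delta_permil, R_std) {
  if (any(R_std <= 0)) abort("R_std must be positive", class = "deeproot_error")
  if (any(delta_permil <= -1000, na.rm = TRUE)) {
    abort("delta values at or below -1000 permil imply a non-physical isotope ratio",
          class = "deeproot_error")
  }
  r <- (delta_permil / 1000 + 1) * R_std
  r / (1 + r)
}

#' Convert atom fraction back to delta notation
#'
#' Inverse of [delta_to_atom_fraction()].
#'
#' @param atom_fraction Heavy-isotope atom fraction(s) in (0, 1).
#' @param R_std Heavy/light ratio of the reference standard.
#' @return Delta value(s) in permil.
#' @export
atom_fraction_to_delta <- function(atom_fraction, R_std) {
  if (any(atom_fraction <= 0 | atom_fraction >= 1, na.rm = TRUE)) {
    abort("atom fractions must lie strictly between 0 and 1", class = "deeproot_error")
  }
  r <- atom_fraction / (1 - atom_fraction)
  (r / R_std - 1) * 1000
}

#' Tracer-derived excess 15N mass in tissue samples
#'
#' Mass balance of labelled N: the sample's N mass times the difference
#' between its 15N atom fraction and the natural-abundance baseline atom
#' fraction. Values can only be negative within measurement noise; they
#' are flagged with a warning, never clamped, so that averages stay
#' unbiased.
#'
#' @param samples Data frame with columns `dry_mass_g`, `n_pct`, `delta15N`
#'   (other columns carried through).
#' @param consts An [isotope_constants()].
#' @return The input tibble with an added `excess_15N_g` column.
#' @export
excess_15n <- function(samples, consts = isotope_constants()) {
  stopifnot(is.data.frame(samples))
  req <- c("dry_mass_g", "n_pct", "delta15N")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    abort(paste0("samples lack column(s): ", paste(missing_cols, collapse = ", ")),
          class = "deeproot_error")
  }
  incomplete <- !complete.cases(samples[, req])
  if (any(incomplete)) {
    abort(paste0("missing dry_mass_g / n_pct / delta15N in sample row(s): ",
                 paste(which(incomplete), collapse = ", ")),
          class = "deeproot_error")
  }
  af <- delta_to_atom_fraction(samples$delta15N, consts$R_std_15N)
  af0 <- delta_to_atom_fraction(consts$natural_15N_delta_baseline, consts$R_std_15N)
  out <- as_tibble(samples)
  out$excess_15N_g <- out$dry_mass_g * out$n_pct / 100 * (af - af0)
  if (any(out$excess_15N_g < 0)) {
    warn(sprintf("%d sample(s) have negative excess 15N (below baseline); retained unclamped",
                 sum(out$excess_15N_g < 0)))
  }
  out
}

#' Percent recovery of applied 15N tracer, per crop row
#'
#' Total excess 15N found in a row's harvested tissue as a percentage of
#' the tracer applied to that row
#' (`total_15N_g * n_injections / n_rows_total`). Grain-only and
#' grain-plus-straw recoveries are both reported, since straw is sampled
#' in a subset of rows.
#'
#' @param samples Tissue table for one or more rows, with columns `row_id`,
#'   `tissue` (`"grain"` or `"straw"`), `dry_mass_g`, `n_pct`, `delta15N`.
#' @param dose A [tracer_dose()].
#' @param consts An [isotope_constants()].
#' @return A tibble with one row per `row_id`: `excess_15N_g_grain`,
#'   `excess_15N_g_total`, `recovery_pct_grain`, `recovery_pct_total`.
#' @export
recovery_percent <- function(samples, dose = tracer_dose(), consts = isotope_constants()) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0) abort("empty sample set", class = "deeproot_error")
  if (!all(c("row_id", "tissue") %in% names(samples))) {
    abort("samples need row_id and tissue columns", class = "deeproot_error")
  }
  bad_tissue <- setdiff(unique(samples$tissue), c("grain", "straw"))
  if (length(bad_tissue)) {
    abort(paste0("unknown tissue type(s): ", paste(bad_tissue, collapse = ", ")),
          class = "deeproot_error")
  }
  per_row_dose <- dose$per_row_15N_g
  excess_15n(samples, consts) |>
    group_by(.data$row_id) |>
    summarise(
      excess_15N_g_grain = sum(.data$excess_15N_g[.data$tissue == "grain"]),
      excess_15N_g_total = sum(.data$excess_15N_g),
      .groups = "drop"
    ) |>
    mutate(
      recovery_pct_grain = 100 * .data$excess_15N_g_grain / per_row_dose,
      recovery_pct_total = 100 * .data$excess_15N_g_total / per_row_dose
    )
}

#' Log transforms used in the isotope models
#'
#' 15N values are log-transformed directly; 2H values are shifted by
#' +90 permil before the log to accommodate negative deltas.
#'
#' @param values Numeric vector of delta values (permil).
#' @param isotope `"15N"` or `"2H"`.
#' @return Element-wise transformed vector (order preserving).
#' @export
transform_for_model <- function(values, isotope = c("15N", "2H")) {
  isotope <- match.arg(isotope)
  shifted <- if (isotope == "15N") values else values + 90
  bad <- which(shifted <= 0)
  if (length(bad)) {
    abort(sprintf("log transform undefined for %s value(s) at position(s): %s",
                  isotope, paste(bad, collapse = ", ")),
          class = "deeproot_error")
  }
  log(shifted)
}
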