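#' Configuration of a synthetic semi-field root phenotyping trial
#'
#' Defines the study conditions emulated by [simulate_trial()]: a
#' two-bed facility with 9 core genotypes replicated ten times and 39
#' additional genotypes replicated four times per year (246 rows/year),
#' logistic depth-decay root profiles with genotype-shifted midpoints and
#' genotype-varying steepness, multiplicative lognormal observation noise,
#' and tracer uptake coupled to the realized root length at the injection
#' depth. Tissue delta15N is derived from the planted uptake fraction by
#' inverting the excess-15N mass balance, so generator bookkeeping and the
#' isotope module agree exactly.
#'
#' @param n_core_genotypes,core_reps Core genotype set and its replication
#'   (default 9 x 10).
#' @param n_extra_genotypes,extra_reps Additional genotypes and replication
#'   (default 39 x 4).
#' @param n_years Number of simulated years (default 1; genotype effects
#'   persist across years with year-specific perturbation `sigma_year`).
#' @param geometry A [tube_geometry()].
#' @param dose A [tracer_dose()].
#' @param consts An [isotope_constants()].
#' @param A Surface-layer expected root length per image (cm).
#' @param sigma_A Lognormal SD of the genotype surface scale.
#' @param k Depth-decay steepness (1/cm).
#' @param sigma_k Lognormal SD of genotype steepness (profile shape
#'   variation; without it all deep-interval lengths are collinear across
#'   genotypes).
#' @param m0 Baseline depth-decay midpoint (cm).
#' @param sigma_b SD of the genotype midpoint shift b_g (cm).
#' @param sigma_year SD of the year-specific perturbation of b_g (cm).
#' @param sigma_row SD of the row-level midpoint jitter (cm).
#' @param sigma_obs Lognormal SD of per-image observation noise.
#' @param year_m_shift Per-year midpoint shifts (cm), recycled to
#'   `n_years`.
#' @param bed_effect_cm Midpoint offset of bed 2 versus bed 1 (cm).
#' @param trend_amp_cm Amplitude of a smooth along-bed midpoint trend (cm).
#' @param u0 Mean per-row tracer uptake fraction at reference deep root
#'   length.
#' @param beta1 Elasticity of uptake with respect to realized root length
#'   in the injection interval (0 decouples uptake from rooting).
#' @param sigma_u Lognormal SD of row-level uptake noise.
#' @param h0 Mean 2H enrichment above the -90 permil floor.
#' @param beta2 Elasticity of 2H enrichment with respect to uptake.
#' @param sigma_h Lognormal SD of 2H noise.
#' @param c0 delta13C intercept (permil).
#' @param beta3 delta13C decrease per cm of expected DeepRoot40
#'   (permil/cm); multiplied by `year_severity`.
#' @param year_severity Drought-severity multipliers on `beta3`, recycled
#'   to `n_years` (the dry-year pattern).
#' @param sigma_c SD of delta13C noise (permil).
#' @param straw_c_offset delta13C offset of straw versus grain (permil).
#' @param grain_mass_mean,grain_mass_sd,grain_n_pct_mean,grain_n_pct_sd
#'   Grain sample dry mass (g) and N concentration (%).
#' @param straw_mass_mean,straw_mass_sd,straw_n_pct_mean,straw_n_pct_sd
#'   Straw sample dry mass (g) and N concentration (%).
#' @param grain_share Fraction of a row's tracer excess allocated to grain.
#' @param session Imaging session label.
#' @param b_g Optional vector of fixed (planted) genotype midpoint shifts
#'   in cm, recycled to the number of genotypes; when supplied it replaces
#'   the random `Normal(0, sigma_b)` draw, e.g. to plant a known
#'   genotype-mean contrast.
#' @return A list of class `simulation_config` (includes the derived
#'   reference deep-interval length `L_ref`).
#' @export
simulation_config <- function(n_core_genotypes = 9, core_reps = 10,
                              n_extra_genotypes = 39, extra_reps = 4,
                              n_years = 1,
                              geometry = tube_geometry(),
                              dose = tracer_dose(),
                              consts = isotope_constants(),
                              A = 2, sigma_A = 0.1,
                              k = 0.05, sigma_k = 0.15,
                              m0 = 120, sigma_b = 10, sigma_year = 4,
                              sigma_row = 4, sigma_obs = 0.3,
                              year_m_shift = c(0, -22, -5),
                              bed_effect_cm = 3, trend_amp_cm = 3,
                              u0 = 0.008, beta1 = 1, sigma_u = 0.3,
                              h0 = 38, beta2 = 0.5, sigma_h = 0.15,
                              c0 = -23.2, beta3 = 0.018,
                              year_severity = c(1, 0.4, 1.8), sigma_c = 0.25,
                              straw_c_offset = -1.9,
                              grain_mass_mean = 75, grain_mass_sd = 8,
                              grain_n_pct_mean = 2.1, grain_n_pct_sd = 0.15,
                              straw_mass_mean = 60, straw_mass_sd = 8,
                              straw_n_pct_mean = 0.55, straw_n_pct_sd = 0.06,
                              grain_share = 0.85,
                              session = "june",
                              b_g = NULL) {
  sds <- c(sigma_A, sigma_k, sigma_b, sigma_year, sigma_row, sigma_obs,
           sigma_u, sigma_h, sigma_c)
  if (any(sds < 0)) abort("all SD parameters must be non-negative", class = "deeproot_error")
  if (m0 < geometry$first_image_depth_m * 100 || m0 > geometry$last_image_depth_m * 100) {
    abort("m0 must lie within the imaged depth range (cm)", class = "deeproot_error")
  }
  cfg <- list(
    n_core_genotypes = n_core_genotypes, core_reps = core_reps,
    n_extra_genotypes = n_extra_genotypes, extra_reps = extra_reps,
    n_years = n_years, geometry = geometry, dose = dose, consts = consts,
    A = A, sigma_A = sigma_A, k = k, sigma_k = sigma_k,
    m0 = m0, sigma_b = sigma_b, sigma_year = sigma_year,
    sigma_row = sigma_row, sigma_obs = sigma_obs,
    year_m_shift = rep_len(year_m_shift, n_years),
    bed_effect_cm = bed_effect_cm, trend_amp_cm = trend_amp_cm,
    u0 = u0, beta1 = beta1, sigma_u = sigma_u,
    h0 = h0, beta2 = beta2, sigma_h = sigma_h,
    c0 = c0, beta3 = beta3,
    year_severity = rep_len(year_severity, n_years), sigma_c = sigma_c,
    straw_c_offset = straw_c_offset,
    grain_mass_mean = grain_mass_mean, grain_mass_sd = grain_mass_sd,
    grain_n_pct_mean = grain_n_pct_mean, grain_n_pct_sd = grain_n_pct_sd,
    straw_mass_mean = straw_mass_mean, straw_mass_sd = straw_mass_sd,
    straw_n_pct_mean = straw_n_pct_mean, straw_n_pct_sd = straw_n_pct_sd,
    grain_share = grain_share, session = session, b_g = b_g
  )
  # reference deep-interval root length of the baseline profile
  cfg$L_ref <- expected_profile(geometry, A, k, m0) |>
    interval_root_length(dose$injection_depth_m[1], dose$injection_depth_m[2])
  structure(cfg, class = "simulation_config")
}

# expected (noiseless) logistic profile on the image grid
expected_profile <- function(geom, A, k, m_cm) {
  img <- image_depths(geom)
  tibble(position_mm = img$position_mm, depth_m = img$depth_m,
         root_length_cm = A / (1 + exp(k * (img$depth_m * 100 - m_cm))))
}

rnorm_pos <- function(n, mean, sd, floor_at) pmax(rnorm(n, mean, sd), floor_at)

#' Simulate a complete synthetic trial
#'
#' Generates per-image root observations, per-row grain and straw tissue
#' samples, and a ground-truth table, in the exact schemas consumed by the
#' trait and isotope modules. Identical `(config, seed)` pairs give
#' identical output.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `deeproot_trial` with tibbles `roots`,
#'   `tissue`, `truth`, plus `config` and `seed`.
#' @export
simulate_trial <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(as.integer(seed), simulate_trial_impl(config, seed))
}

simulate_trial_impl <- function(cfg, seed) {
  geom <- cfg$geometry
  img <- image_depths(geom)
  d_cm <- img$depth_m * 100
  n_img <- nrow(img)
  n_g <- cfg$n_core_genotypes + cfg$n_extra_genotypes
  genotypes <- sprintf("G%02d", seq_len(n_g))
  core <- genotypes[seq_len(cfg$n_core_genotypes)]

  b_g <- if (is.null(cfg$b_g)) rnorm(n_g, 0, cfg$sigma_b) else rep_len(cfg$b_g, n_g)
  k_g <- cfg$k * exp(rnorm(n_g, 0, cfg$sigma_k))
  A_g <- cfg$A * exp(rnorm(n_g, 0, cfg$sigma_A))
  names(b_g) <- names(k_g) <- names(A_g) <- genotypes

  af0 <- delta_to_atom_fraction(cfg$consts$natural_15N_delta_baseline, cfg$consts$R_std_15N)
  inj <- cfg$dose$injection_depth_m
  years <- 2020 + seq_len(cfg$n_years)

  roots_l <- tissue_l <- truth_l <- vector("list", cfg$n_years)
  for (y in seq_len(cfg$n_years)) {
    b_gy <- b_g + if (cfg$n_years > 1) rnorm(n_g, 0, cfg$sigma_year) else 0
    # randomized complete blocks: each bed holds half of every genotype's reps
    reps_per_bed <- c(rep(cfg$core_reps / 2, cfg$n_core_genotypes),
                      rep(cfg$extra_reps / 2, cfg$n_extra_genotypes))
    bed_assign <- lapply(1:2, function(b) sample(rep(genotypes, times = reps_per_bed)))
    n_per_bed <- length(bed_assign[[1]])
    design <- tibble(
      genotype = c(bed_assign[[1]], bed_assign[[2]]),
      bed = rep(1:2, each = n_per_bed),
      bed_pos = c(seq_len(n_per_bed), seq_len(n_per_bed))
    )
    n_rows <- nrow(design)
    design$row_id <- sprintf("Y%d_R%03d", years[y], seq_len(n_rows))
    design$year <- years[y]

    m_row <- cfg$m0 + cfg$year_m_shift[y] + b_gy[design$genotype] +
      cfg$bed_effect_cm * (design$bed == 2) +
      cfg$trend_amp_cm * sin(2 * pi * design$bed_pos / n_per_bed) +
      rnorm(n_rows, 0, cfg$sigma_row)

    # per-row expected length matrix (images x rows)
    expected <- sapply(seq_len(n_rows), function(i) {
      A_g[design$genotype[i]] / (1 + exp(k_g[design$genotype[i]] * (d_cm - m_row[i])))
    })
    noise <- if (cfg$sigma_obs > 0) {
      matrix(rlnorm(n_img * n_rows, 0, cfg$sigma_obs), n_img, n_rows)
    } else {
      matrix(1, n_img, n_rows)
    }
    obs <- expected * noise

    roots_l[[y]] <- tibble(
      row_id = rep(design$row_id, each = n_img),
      genotype = rep(design$genotype, each = n_img),
      year = years[y],
      session = cfg$session,
      position_mm = rep(img$position_mm, n_rows),
      root_length_cm = as.numeric(obs)
    )

    in_inj <- img$depth_m >= inj[1] & img$depth_m < inj[2]
    L_obs <- colSums(obs[in_inj, , drop = FALSE])
    u <- cfg$u0 * (L_obs / cfg$L_ref)^cfg$beta1 * exp(rnorm(n_rows, 0, cfg$sigma_u))
    u <- pmin(pmax(u, 0), 1)

    # genotype-level expected traits for this year
    dr40_exp <- vapply(genotypes, function(g) {
      ep <- expected_profile(geom, A_g[g], k_g[g], cfg$m0 + cfg$year_m_shift[y] + b_gy[g])
      suppressMessages(deep_root_threshold(ep))
    }, numeric(1))
    L_exp <- vapply(genotypes, function(g) {
      ep <- expected_profile(geom, A_g[g], k_g[g], cfg$m0 + cfg$year_m_shift[y] + b_gy[g])
      interval_root_length(ep, inj[1], inj[2])
    }, numeric(1))

    excess <- u * cfg$dose$per_row_15N_g
    grain_mass <- rnorm_pos(n_rows, cfg$grain_mass_mean, cfg$grain_mass_sd, 10)
    grain_npct <- rnorm_pos(n_rows, cfg$grain_n_pct_mean, cfg$grain_n_pct_sd, 0.5)
    straw_mass <- rnorm_pos(n_rows, cfg$straw_mass_mean, cfg$straw_mass_sd, 10)
    straw_npct <- rnorm_pos(n_rows, cfg$straw_n_pct_mean, cfg$straw_n_pct_sd, 0.1)
    d15_grain <- atom_fraction_to_delta(
      af0 + cfg$grain_share * excess / (grain_mass * grain_npct / 100), cfg$consts$R_std_15N)
    d15_straw <- atom_fraction_to_delta(
      af0 + (1 - cfg$grain_share) * excess / (straw_mass * straw_npct / 100), cfg$consts$R_std_15N)
    d2h_grain <- -90 + cfg$h0 * (u / cfg$u0)^cfg$beta2 * exp(rnorm(n_rows, 0, cfg$sigma_h))
    sev <- cfg$year_severity[y]
    d13_grain <- cfg$c0 - cfg$beta3 * sev * dr40_exp[design$genotype] + rnorm(n_rows, 0, cfg$sigma_c)
    d13_straw <- cfg$c0 + cfg$straw_c_offset -
      cfg$beta3 * sev * dr40_exp[design$genotype] + rnorm(n_rows, 0, cfg$sigma_c)

    tissue_l[[y]] <- bind_rows(
      tibble(row_id = design$row_id, genotype = design$genotype, year = years[y],
             tissue = "grain", dry_mass_g = grain_mass, n_pct = grain_npct,
             delta15N = d15_grain, delta13C = d13_grain, delta2H = d2h_grain),
      tibble(row_id = design$row_id, genotype = design$genotype, year = years[y],
             tissue = "straw", dry_mass_g = straw_mass, n_pct = straw_npct,
             delta15N = d15_straw, delta13C = d13_straw, delta2H = NA_real_)
    )

    truth_l[[y]] <- tibble(
      row_id = design$row_id, genotype = design$genotype, year = years[y],
      bed = design$bed, bed_pos = design$bed_pos, is_core = design$genotype %in% core,
      b_g = unname(b_g[design$genotype]), b_gy = unname(b_gy[design$genotype]),
      k_g = unname(k_g[design$genotype]), A_g = unname(A_g[design$genotype]),
      m_row = m_row, uptake_fraction = u,
      dr40_expected_cm = unname(dr40_exp[design$genotype]),
      L_deep_expected_cm = unname(L_exp[design$genotype]),
      delta13C_expected = cfg$c0 - cfg$beta3 * sev * unname(dr40_exp[design$genotype])
    )
  }

  structure(list(
    roots = bind_rows(roots_l),
    tissue = bind_rows(tissue_l),
    truth = bind_rows(truth_l),
    config = cfg,
    seed = as.integer(seed)
  ), class = "deeproot_trial")
}

#' @export
print.deeproot_trial <- function(x, ...) {
  cat(sprintf("<deeproot_trial> seed %d: %d rows, %d root observations, %d tissue samples\n",
              x$seed, nrow(x$truth), nrow(x$roots), nrow(x$tissue)))
  invisible(x)
}

#' Write a synthetic trial to disk
#'
#' Writes `roots.csv`, `tissue.csv`, `truth.csv` and a `provenance.json`
#' recording the configuration, seed and package version. Missing values
#' are written as empty fields.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "deeproot_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("roots.csv", "tissue.csv", "truth.csv", "provenance.json"))
  readr::write_csv(trial$roots, paths[1], na = "")
  readr::write_csv(trial$tissue, paths[2], na = "")
  readr::write_csv(trial$truth, paths[3], na = "")
  cfg <- trial$config
  cfg$geometry <- unclass(cfg$geometry)
  cfg$dose <- unclass(cfg$dose)
  cfg$consts <- unclass(cfg$consts)
  jsonlite::write_json(
    list(config = unclass(cfg), seed = trial$seed,
         package = "deeproot",
         version = as.character(utils::packageVersion("deeproot"))),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

#' Check recovery of planted effects from pipeline estimates
#'
#' Compares ground truth with pipeline output: Spearman correlation of the
#' planted genotype depth shift `b_g` with estimated DeepRoot40 genotype
#' means, and the sign of the estimated trait-isotope correlations against
#' the planted coupling directions.
#'
#' @param trial A [simulate_trial()] result.
#' @param traits Per-row traits from [compute_root_traits()] (must carry
#'   matching `row_id`).
#' @return A list with `spearman_rho` and a tibble `couplings`
#'   (`pair`, `planted_sign`, `r`, `p`, `sign_match`).
#' @export
planted_effect_check <- function(trial, traits) {
  stopifnot(inherits(trial, "deeproot_trial"), is.data.frame(traits))
  if (!all(traits$row_id %in% trial$truth$row_id)) {
    abort("traits contain row_ids absent from the trial truth table", class = "deeproot_error")
  }
  truth_g <- trial$truth |>
    group_by(.data$genotype) |>
    summarise(b_g = mean(.data$b_g), .groups = "drop")
  est_g <- traits |>
    group_by(.data$genotype) |>
    summarise(dr = mean(.data$deep_root40_cm, na.rm = TRUE), .groups = "drop")
  if (!setequal(truth_g$genotype, est_g$genotype)) {
    abort("genotype labels of truth and estimates do not match", class = "deeproot_error")
  }
  j <- left_join(truth_g, est_g, by = "genotype")
  rho <- stats::cor(j$b_g, j$dr, method = "spearman")

  grain <- filter(trial$tissue, .data$tissue == "grain")
  iso_g <- grain |>
    group_by(.data$genotype) |>
    summarise(ln_d15 = mean(transform_for_model(.data$delta15N, "15N")),
              d13 = mean(.data$delta13C), .groups = "drop")
  xy <- left_join(est_g, iso_g, by = "genotype")
  c1 <- cultivar_mean_correlation(xy, dr, ln_d15)
  c2 <- cultivar_mean_correlation(xy, dr, d13)
  couplings <- tibble(
    pair = c("deep_root40 ~ ln_delta15N", "deep_root40 ~ delta13C"),
    planted_sign = c(sign(trial$config$beta1), -sign(trial$config$beta3)),
    r = c(c1$r, c2$r),
    p = c(c1$p, c2$p)
  )
  couplings$sign_match <- sign(couplings$r) == couplings$planted_sign |
    couplings$planted_sign == 0
  list(spearman_rho = rho, couplings = couplings)
}
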