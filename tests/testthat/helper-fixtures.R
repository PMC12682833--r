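# fixtures built in code; all randomness goes through withr::with_seed

# a random but realistic single-tube profile on the image grid of `geom`:
# logistic decay in expectation, multiplicative lognormal noise
random_profile <- function(seed, geom = tube_geometry(), A = 2, k = 0.05,
                           m_cm = 120, sdlog = 0.3) {
  withr::with_seed(seed, {
    img <- image_depths(geom)
    mu <- A / (1 + exp(k * (img$depth_m * 100 - m_cm)))
    tibble::tibble(
      position_mm = img$position_mm,
      depth_m = img$depth_m,
      root_length_cm = mu * stats::rlnorm(nrow(img), 0, sdlog)
    )
  })
}

# independent brute-force DeepRoot oracle: build the cumulative-from-bottom
# curve naively (one sum per image depth), interpolate with stats::approx
# onto a 1-mm grid, and scan for the deepest grid depth meeting the target
grid_scan_deep_root <- function(profile, target_cm = 40, grid_mm = 1) {
  d <- sort(profile$depth_m * 100)
  len <- profile$root_length_cm[order(profile$depth_m)]
  s <- vapply(d, function(dd) sum(len[d >= dd - 1e-12]), numeric(1))
  if (s[1] < target_cm) return(NA_real_)
  grid <- seq(min(d), max(d), by = grid_mm / 10)  # cm
  cgrid <- stats::approx(d, s, xout = grid, rule = 2)$y
  max(grid[cgrid >= target_cm])
}

# tissue sample with a prescribed excess-15N mass, for recovery bookkeeping
sample_with_excess <- function(row_id, excess_g, dry_mass_g = 100, n_pct = 2,
                               tissue = "grain",
                               consts = isotope_constants()) {
  af0 <- delta_to_atom_fraction(consts$natural_15N_delta_baseline, consts$R_std_15N)
  af <- af0 + excess_g / (dry_mass_g * n_pct / 100)
  tibble::tibble(
    row_id = row_id, genotype = "GX", tissue = tissue,
    dry_mass_g = dry_mass_g, n_pct = n_pct,
    delta15N = atom_fraction_to_delta(af, consts$R_std_15N),
    delta13C = -26, delta2H = -50
  )
}

# small balanced row-level trait table with planted genotype offsets
planted_trait_table <- function(offsets, reps, sd, seed) {
  withr::with_seed(seed, {
    g <- rep(names(offsets), each = reps)
    tibble::tibble(
      genotype = g,
      year = 1L,
      row_id = paste0("R", seq_along(g)),
      value = offsets[g] + stats::rnorm(length(g), 0, sd)
    )
  })
}
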