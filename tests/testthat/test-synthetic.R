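test_that("default design reproduces the trial arithmetic", {
  cfg <- simulation_config()
  trial <- simulate_trial(cfg, seed = 1)
  expect_identical(nrow(trial$truth), 246L)  # 9 x 10 + 39 x 4
  counts <- dplyr::count(trial$truth, genotype)
  expect_identical(sum(counts$n == 10), 9L)
  expect_identical(sum(counts$n == 4), 39L)
  expect_identical(nrow(trial$roots),
                   246L * nrow(image_depths(cfg$geometry)))
  expect_identical(nrow(trial$tissue), 2L * 246L)
})

test_that("simulation is deterministic under seed, on disk too", {
  cfg <- simulation_config(n_core_genotypes = 3, core_reps = 2,
                           n_extra_genotypes = 2, extra_reps = 2)
  t1 <- simulate_trial(cfg, seed = 7)
  t2 <- simulate_trial(cfg, seed = 7)
  expect_identical(t1$roots, t2$roots)
  expect_identical(t1$tissue, t2$tissue)
  expect_identical(t1$truth, t2$truth)
  t3 <- simulate_trial(cfg, seed = 8)
  expect_false(identical(t1$roots, t3$roots))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_trial(t1, d1)
  write_trial(t2, d2)
  for (f in c("roots.csv", "tissue.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("all variance components at zero give identical DeepRoot40 everywhere", {
  cfg <- simulation_config(sigma_A = 0, sigma_k = 0, sigma_b = 0, sigma_year = 0,
                           sigma_row = 0, sigma_obs = 0, sigma_u = 0,
                           sigma_h = 0, sigma_c = 0,
                           bed_effect_cm = 0, trend_amp_cm = 0,
                           n_core_genotypes = 4, core_reps = 2,
                           n_extra_genotypes = 4, extra_reps = 2)
  trial <- simulate_trial(cfg, seed = 2)
  traits <- compute_root_traits(trial$roots, cfg$geometry, fit_sigmoid = FALSE)
  expect_lt(diff(range(traits$deep_root40_cm)), 1e-9)
})

test_that("increasing genotype spread increases between-genotype trait variance", {
  vars <- vapply(c(2, 6, 10), function(sb) {
    cfg <- simulation_config(sigma_b = sb)
    trial <- simulate_trial(cfg, seed = 11)
    traits <- compute_root_traits(trial$roots, cfg$geometry, fit_sigmoid = FALSE)
    gm <- dplyr::summarise(dplyr::group_by(traits, genotype),
                           m = mean(deep_root40_cm, na.rm = TRUE))
    stats::var(gm$m[is.finite(gm$m)])
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("generated tracer bookkeeping is conserved through the isotope module", {
  cfg <- simulation_config()
  trial <- simulate_trial(cfg, seed = 4)
  rec <- recovery_percent(trial$tissue, cfg$dose, cfg$consts)
  expect_true(all(trial$truth$uptake_fraction >= 0 & trial$truth$uptake_fraction <= 1))
  agg <- mean(rec$recovery_pct_total)
  expect_equal(agg, 100 * mean(trial$truth$uptake_fraction), tolerance = 1e-6)
})

test_that("written trials round-trip through the validated readers", {
  cfg <- simulation_config(n_core_genotypes = 3, core_reps = 2,
                           n_extra_genotypes = 3, extra_reps = 2)
  trial <- simulate_trial(cfg, seed = 5)
  dir <- withr::local_tempdir()
  write_trial(trial, dir)
  expect_no_warning(obs <- suppressMessages(read_observations(file.path(dir, "roots.csv"), cfg$geometry)))
  expect_identical(nrow(obs), nrow(trial$roots))
  expect_no_warning(ts <- suppressMessages(read_tissue_samples(file.path(dir, "tissue.csv"))))
  expect_identical(nrow(ts), nrow(trial$tissue))
  expect_true(file.exists(file.path(dir, "provenance.json")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_identical(prov$seed, 5L)
})

test_that("multi-year trials keep genotype labels and persistent effects", {
  cfg <- simulation_config(n_years = 3)
  trial <- simulate_trial(cfg, seed = 6)
  expect_identical(nrow(trial$truth), 3L * 246L)
  expect_identical(dplyr::n_distinct(trial$truth$year), 3L)
  by_year <- split(trial$truth, trial$truth$year)
  for (y in by_year) expect_setequal(unique(y$genotype), unique(trial$truth$genotype))
  # b_g persists across years; year perturbations differ
  g1 <- dplyr::distinct(by_year[[1]], genotype, b_g, b_gy)
  g2 <- dplyr::distinct(by_year[[2]], genotype, b_g, b_gy)
  j <- dplyr::left_join(g1, g2, by = "genotype")
  expect_identical(j$b_g.x, j$b_g.y)
  expect_false(any(j$b_gy.x == j$b_gy.y))
})

test_that("planted effects are recovered and label mismatches refused", {
  cfg <- simulation_config()
  trial <- simulate_trial(cfg, seed = 12)
  traits <- compute_root_traits(trial$roots, cfg$geometry, fit_sigmoid = FALSE)
  chk <- planted_effect_check(trial, traits)
  expect_gt(chk$spearman_rho, 0.8)
  expect_true(all(chk$couplings$sign_match))
  bad <- dplyr::mutate(traits, row_id = paste0("zz", row_id))
  expect_error(planted_effect_check(trial, bad), "absent")
})
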