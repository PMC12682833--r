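test_that("deep root threshold handles point mass and shortfall", {
  geom <- tube_geometry()
  img <- image_depths(geom)
  len <- rep(0, nrow(img))
  at <- which.min(abs(img$depth_m - 1.5))
  len[at] <- 40
  pr <- tibble::tibble(depth_m = img$depth_m, root_length_cm = len)
  expect_equal(deep_root_threshold(pr), img$depth_m[at] * 100)

  short <- tibble::tibble(depth_m = img$depth_m,
                          root_length_cm = rep(39 / nrow(img), nrow(img)))
  expect_message(res <- deep_root_threshold(short), "below the 40")
  expect_true(is.na(res))
  expect_error(deep_root_threshold(pr[0, ]), "empty")
})

test_that("deep root threshold agrees with the grid-scan oracle", {
  geom <- tube_geometry()
  for (seed in 1:30) {
    pr <- random_profile(seed, geom)
    expect_equal(deep_root_threshold(pr), grid_scan_deep_root(pr), tolerance = 0.5 / 100)
  }
})

test_that("adding root length below the threshold never decreases it", {
  geom <- tube_geometry()
  img <- image_depths(geom)
  withr::with_seed(42, {
    for (i in 1:50) {
      pr <- random_profile(1000 + i, geom)
      d0 <- deep_root_threshold(pr)
      below <- which(img$depth_m * 100 > d0)
      j <- sample(below, 1)
      pr2 <- pr
      pr2$root_length_cm[j] <- pr2$root_length_cm[j] + runif(1, 0.1, 20)
      expect_gte(deep_root_threshold(pr2), d0 - 1e-9)
    }
  })
})

test_that("uniform scaling by c >= 1 never decreases the threshold", {
  geom <- tube_geometry()
  for (seed in 1:10) {
    pr <- random_profile(seed, geom)
    d0 <- deep_root_threshold(pr)
    for (cc in c(1, 1.5, 3)) {
      pr2 <- pr
      pr2$root_length_cm <- cc * pr2$root_length_cm
      expect_gte(deep_root_threshold(pr2), d0 - 1e-9)
    }
  }
})

test_that("sigmoid fit recovers exact logistic parameters", {
  geom <- tube_geometry()
  img <- image_depths(geom)
  A <- 2; k <- 0.05; m <- 120
  pr <- tibble::tibble(depth_m = img$depth_m,
                       root_length_cm = A / (1 + exp(k * (img$depth_m * 100 - m))))
  sf <- fit_root_sigmoid(pr)
  expect_true(sf$converged)
  expect_equal(sf$m_cm, m, tolerance = 0.1 / m)
  expect_equal(sf$A, A, tolerance = 1e-3)
  expect_equal(sf$k, k, tolerance = 1e-3)
  td <- tidy(sf)
  expect_identical(td$term, c("A", "k", "m"))
  expect_true(glance(sf)$converged)
})

test_that("sigmoid fit is undefined for flat or tiny profiles", {
  geom <- tube_geometry()
  img <- image_depths(geom)
  flat <- tibble::tibble(depth_m = img$depth_m, root_length_cm = 1.0)
  sf <- fit_root_sigmoid(flat)
  expect_false(sf$converged)
  expect_match(sf$reason, "no depth transition")
  expect_message(expect_true(is.na(sigmoid_inflection(flat))), "undefined")

  tiny <- tibble::tibble(depth_m = img$depth_m[1:5], root_length_cm = c(5, 4, 3, 2, 1))
  expect_false(fit_root_sigmoid(tiny)$converged)
})

test_that("compute_root_traits returns one row per tube with all traits", {
  cfg <- simulation_config(n_core_genotypes = 3, core_reps = 2,
                           n_extra_genotypes = 2, extra_reps = 2)
  trial <- simulate_trial(cfg, seed = 9)
  traits <- compute_root_traits(trial$roots, cfg$geometry,
                                intervals = list(c(1.6, 1.8), c(1.0, 1.3)))
  expect_identical(nrow(traits), nrow(trial$truth))
  expect_true(all(c("deep_root40_cm", "si_cm", "L1.6_1.8", "L1_1.3") %in% names(traits)))
  # interval columns agree with the scalar operation
  pr <- build_profile(dplyr::filter(trial$roots, row_id == traits$row_id[1]), cfg$geometry)
  expect_equal(traits$L1.6_1.8[1], interval_root_length(pr, 1.6, 1.8))
  expect_equal(traits$deep_root40_cm[1], deep_root_threshold(pr))
})

test_that("interval screen flags zero-variance isotopes and needs 3 cultivars", {
  cfg <- simulation_config(n_core_genotypes = 4, core_reps = 2,
                           n_extra_genotypes = 0, extra_reps = 2)
  trial <- simulate_trial(cfg, seed = 3)
  iso <- dplyr::transmute(dplyr::filter(trial$tissue, tissue == "grain"),
                          row_id, genotype, value = 5.0)
  out <- interval_screen(trial$roots, iso, list(c(1.0, 1.4), c(1.6, 1.8)), cfg$geometry)
  expect_true(all(out$note == "zero variance"))
  expect_true(all(is.na(out$r)))

  iso2 <- iso[iso$genotype %in% unique(iso$genotype)[1:2], ]
  obs2 <- trial$roots[trial$roots$genotype %in% unique(iso2$genotype), ]
  expect_error(interval_screen(obs2, iso2, list(c(1.6, 1.8)), cfg$geometry),
               "fewer than 3")
})

test_that("permuting cultivar labels destroys the deep-interval correlation", {
  cfg <- simulation_config()
  trial <- simulate_trial(cfg, seed = 5)
  iso <- dplyr::transmute(dplyr::filter(trial$tissue, tissue == "grain"),
                          row_id, genotype,
                          value = transform_for_model(delta15N, "15N"))
  real <- interval_screen(trial$roots, iso, list(c(1.6, 1.8)), cfg$geometry)
  expect_gt(real$r, 0.5)
  perm_r <- withr::with_seed(8, vapply(1:20, function(i) {
    g <- unique(iso$genotype)
    relab <- setNames(sample(g), g)
    iso_p <- dplyr::mutate(iso, genotype = relab[genotype])
    interval_screen(trial$roots, iso_p, list(c(1.6, 1.8)), cfg$geometry)$r
  }, numeric(1)))
  expect_lt(median(abs(perm_r)), 0.3)
})
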