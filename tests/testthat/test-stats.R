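make_rep_table <- function(counts) {
  # counts: named list genotype -> vector of reps per year
  purrr::map_dfr(names(counts), function(g) {
    purrr::map_dfr(seq_along(counts[[g]]), function(y) {
      n <- counts[[g]][y]
      if (n == 0) return(NULL)
      tibble::tibble(genotype = g, year = 2020 + y,
                     row_id = sprintf("%s_%d_%d", g, y, seq_len(n)),
                     value = stats::rnorm(n))
    })
  })
}

test_that("replication filter counts rows per scope", {
  d <- withr::with_seed(1, make_rep_table(list(A = c(4, 4, 4), B = c(4, 4, 3), C = c(2, 5, 5))))
  per_year <- replication_filter(d, min_reps = 4, scope = "per-year")
  kept <- attr(per_year, "retained")
  expect_setequal(kept$genotype[kept$year == 2023], c("A", "C"))
  expect_false(any(per_year$genotype == "B" & per_year$year == 2023))
  expect_true(all(per_year$genotype[per_year$year == 2021] %in% c("A", "B")))

  all_years <- replication_filter(d, min_reps = 4, scope = "all-years")
  expect_setequal(unique(all_years$genotype), "A")

  expect_identical(nrow(replication_filter(d, min_reps = 1)), nrow(d))
  expect_error(replication_filter(d, min_reps = 10), "relax")
})

test_that("cultivar-mean correlation matches a from-scratch formula", {
  d <- tibble::tibble(x = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3),
                      y = c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8))
  res <- cultivar_mean_correlation(d, x, y)
  n <- nrow(d)
  sx <- sum(d$x); sy <- sum(d$y)
  r_hand <- (n * sum(d$x * d$y) - sx * sy) /
    sqrt((n * sum(d$x^2) - sx^2) * (n * sum(d$y^2) - sy^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), n - 2)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_identical(res$n, n)
})

test_that("correlation handles identity, reflection, missing and degenerate input", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5))
  expect_equal(cultivar_mean_correlation(dplyr::mutate(d, y = x), x, y)$r, 1)
  expect_lt(cultivar_mean_correlation(dplyr::mutate(d, y = x), x, y)$p, 1e-10)
  expect_equal(cultivar_mean_correlation(dplyr::mutate(d, y = -x), x, y)$r, -1)
  dm <- tibble::tibble(x = c(1, 2, 3, 4, NA), y = c(2, 1, 4, NA, 5))
  expect_identical(cultivar_mean_correlation(dm, x, y)$n, 3L)
  expect_error(cultivar_mean_correlation(dm[3:5, ], x, y), "fewer than 3")
  dz <- tibble::tibble(x = c(1, 1, 1, 1), y = c(1, 2, 3, 4))
  expect_identical(cultivar_mean_correlation(dz, x, y)$note, "zero variance")
})

test_that("pearson r is affine invariant with sign flip under negative scale", {
  d <- withr::with_seed(4, tibble::tibble(x = rnorm(20), y = rnorm(20) + 0.5 * x))
  r0 <- cultivar_mean_correlation(d, x, y)$r
  d2 <- dplyr::mutate(d, x = 3 * x + 7)
  expect_equal(cultivar_mean_correlation(d2, x, y)$r, r0, tolerance = 1e-12)
  d3 <- dplyr::mutate(d, y = -2 * y + 1)
  expect_equal(cultivar_mean_correlation(d3, x, y)$r, -r0, tolerance = 1e-12)
})

test_that("year-by-year correlation matrix matches labels pairwise", {
  d <- tibble::tibble(genotype = rep(letters[1:6], 2),
                      year = rep(c(2021, 2022), each = 6),
                      v = c(1:6, 1:6))
  out <- correlation_matrix(d, v)
  expect_identical(nrow(out), 1L)
  expect_equal(out$r, 1)

  d2 <- tibble::tibble(genotype = c("a", "b", "c", "x", "y", "z"),
                       year = rep(c(2021, 2022), each = 3),
                       v = rnorm(6))
  out2 <- correlation_matrix(d2, v)
  expect_true(is.na(out2$r))
  expect_match(out2$note, "overlapping")
  expect_error(correlation_matrix(d[d$year == 2021, ], v), "2 years")
})

test_that("genotype means recover planted values exactly on balanced noiseless data", {
  offsets <- c(A = 100, B = 110, C = 125)
  d <- planted_trait_table(offsets, reps = 4, sd = 0, seed = 1)
  gm <- suppressWarnings(estimate_genotype_means(d, value))  # zero-residual fit
  td <- tidy(gm)
  expect_equal(setNames(td$mean, td$genotype), offsets, tolerance = 1e-10)
  expect_identical(length(unique(td$letters)), 3L)  # zero noise separates all
  expect_identical(gm$adjust, "tukey")
})

test_that("adding a constant shifts means and leaves letters unchanged", {
  offsets <- c(A = 100, B = 104, C = 125, D = 126)
  d <- planted_trait_table(offsets, reps = 6, sd = 5, seed = 2)
  gm1 <- estimate_genotype_means(d, value)
  gm2 <- estimate_genotype_means(dplyr::mutate(d, value = value + 50), value)
  expect_equal(tidy(gm2)$mean, tidy(gm1)$mean + 50, tolerance = 1e-9)
  expect_identical(tidy(gm2)$letters, tidy(gm1)$letters)
})

test_that("compact letters are a clique cover of the non-significance graph", {
  # hand-constructed chain: A~B n.s., B~C n.s., A-C significant
  p <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p["A", "C"] <- p["C", "A"] <- 0.001
  lab <- compact_letters(c("A", "B", "C"), p, c(A = 3, B = 2, C = 1), alpha = 0.05)
  expect_identical(nchar(lab[["B"]]), 2L)  # B shares with both
  expect_true(substr(lab[["A"]], 1, 1) != substr(lab[["C"]], nchar(lab[["C"]]), nchar(lab[["C"]])))

  # property: sharing a letter iff adjusted p >= alpha, on fitted data
  d <- planted_trait_table(c(A = 0, B = 6, C = 7, D = 14, E = 30), reps = 5, sd = 6, seed = 3)
  gm <- estimate_genotype_means(d, value)
  td <- tidy(gm)
  lab <- setNames(td$letters, td$genotype)
  g <- names(lab)
  for (i in seq_along(g)) {
    for (j in seq_len(i - 1)) {
      share <- length(intersect(strsplit(lab[[g[i]]], "")[[1]],
                                strsplit(lab[[g[j]]], "")[[1]])) > 0
      expect_identical(share, gm$p_matrix[g[i], g[j]] >= gm$alpha)
    }
  }
})

test_that("genotype model errors on aliasing and tiny designs", {
  d <- tibble::tibble(genotype = rep(c("A", "B"), each = 4),
                      bed = rep(c(1, 2), each = 4),
                      value = rnorm(8))
  expect_error(estimate_genotype_means(d, value), "aliased")
  expect_error(estimate_genotype_means(d[c(1, 5), ], value), "at least 2")
})

test_that("independent cultivar means reject at close to the nominal rate", {
  rej <- withr::with_seed(99, vapply(1:400, function(i) {
    d <- tibble::tibble(x = rnorm(48), y = rnorm(48))
    cultivar_mean_correlation(d, x, y)$p < 0.05
  }, logical(1)))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
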