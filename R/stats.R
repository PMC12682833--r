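#' Filter genotypes by replication count
#'
#' Retains genotypes with at least `min_reps` replicate rows, either within
#' each experimental year separately (`scope = "per-year"`, the rule used
#' for correlation analyses) or in every year (`scope = "all-years"`, the
#' rule used for the genotype-mean models).
#'
#' @param data Row-level table with `genotype` and `year` columns (`row_id`,
#'   when present, is used to count distinct replicate rows).
#' @param min_reps Minimum replicate count (default 4).
#' @param scope `"per-year"` or `"all-years"`.
#' @return The filtered tibble, with the retained genotype-by-year table in
#'   attribute `"retained"`.
#' @export
replication_filter <- function(data, min_reps = 4, scope = c("per-year", "all-years")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(data))
  if (!all(c("genotype", "year") %in% names(data))) {
    abort("data needs genotype and year columns", class = "deeproot_error")
  }
  counts <- data |>
    group_by(.data$genotype, .data$year) |>
    summarise(n_reps = if ("row_id" %in% names(data)) dplyr::n_distinct(.data$row_id) else n(),
              .groups = "drop")
  if (scope == "per-year") {
    keep <- filter(counts, .data$n_reps >= min_reps)
    out <- dplyr::semi_join(as_tibble(data), keep, by = c("genotype", "year"))
  } else {
    n_years <- dplyr::n_distinct(data$year)
    keep_g <- counts |>
      filter(.data$n_reps >= min_reps) |>
      count(.data$genotype) |>
      filter(.data$n == n_years) |>
      pull(.data$genotype)
    keep <- filter(counts, .data$genotype %in% keep_g)
    out <- filter(as_tibble(data), .data$genotype %in% keep_g)
  }
  if (nrow(out) == 0) {
    abort(sprintf("no genotype reaches %d replications (%s); relax the threshold",
                  min_reps, scope), class = "deeproot_error")
  }
  attr(out, "retained") <- keep
  out
}

#' Pearson correlation of cultivar means
#'
#' Pearson correlation between two per-genotype mean series with a
#' two-sided p-value from the t distribution on n - 2 degrees of freedom.
#' Genotypes with a missing value in either series are dropped pairwise.
#' Zero variance in either series gives an undefined (flagged) result
#' rather than NaN propagation.
#'
#' @param data Data frame of per-genotype means.
#' @param x,y Columns (tidy evaluation) holding the two mean series.
#' @return A one-row tibble: `r`, `p`, `n`, `note` (`NA` unless undefined).
#' @export
cultivar_mean_correlation <- function(data, x, y) {
  stopifnot(is.data.frame(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]
  yv <- yv[ok]
  n <- length(xv)
  if (n < 3) {
    abort("fewer than 3 paired cultivar means", class = "deeproot_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = n, note = "zero variance"))
  }
  ct <- stats::cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = n, note = NA_character_)
}

#' Year-by-year correlation matrix of cultivar means
#'
#' All pairwise correlations between years of a per-genotype mean series,
#' matching genotypes by label with pairwise-complete deletion.
#'
#' @param data Long table with columns `genotype`, `year` and the value
#'   column named by `value`.
#' @param value Column (tidy evaluation) holding the per-genotype means.
#' @return A tibble with one row per unordered year pair: `year_x`,
#'   `year_y`, `r`, `p`, `n`, `note`.
#' @export
correlation_matrix <- function(data, value) {
  stopifnot(is.data.frame(data))
  if (!all(c("genotype", "year") %in% names(data))) {
    abort("data needs genotype and year columns", class = "deeproot_error")
  }
  wide <- data |>
    dplyr::select("genotype", "year", v = {{ value }}) |>
    tidyr::pivot_wider(names_from = "year", values_from = "v", values_fn = mean)
  years <- setdiff(names(wide), "genotype")
  if (length(years) < 2) abort("need at least 2 years", class = "deeproot_error")
  pairs_idx <- utils::combn(years, 2, simplify = FALSE)
  purrr::map_dfr(pairs_idx, function(pr) {
    ok <- is.finite(wide[[pr[1]]]) & is.finite(wide[[pr[2]]])
    if (sum(ok) < 3) {
      return(tibble(year_x = pr[1], year_y = pr[2], r = NA_real_, p = NA_real_,
                    n = sum(ok), note = "fewer than 3 overlapping genotypes"))
    }
    res <- cultivar_mean_correlation(wide[ok, ], !!rlang::sym(pr[1]), !!rlang::sym(pr[2]))
    tibble(year_x = pr[1], year_y = pr[2], r = res$r, p = res$p, n = res$n, note = res$note)
  })
}

# Compact letter display by insert-and-absorb on the significance graph.
# groups: character vector; p_mat: symmetric matrix of adjusted p-values
# with dimnames = groups; means: named estimates used only to order letters
# (largest mean gets "a"). Two groups share a letter iff adjusted p >= alpha.
compact_letters <- function(groups, p_mat, means, alpha = 0.05) {
  cols <- list(groups)
  sig <- which(p_mat < alpha & upper.tri(p_mat), arr.ind = TRUE)
  if (nrow(sig)) {
    for (s in seq_len(nrow(sig))) {
      gi <- rownames(p_mat)[sig[s, 1]]
      gj <- colnames(p_mat)[sig[s, 2]]
      new_cols <- list()
      for (col in cols) {
        if (all(c(gi, gj) %in% col)) {
          new_cols <- c(new_cols, list(setdiff(col, gi)), list(setdiff(col, gj)))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[a] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  ord <- order(-vapply(cols, function(col) max(means[col]), numeric(1)))
  cols <- cols[ord]
  lab <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1)))], collapse = "")
  }, character(1))
  lab
}

#' Estimate genotype means with design covariates
#'
#' Fits a fixed-effects linear model for a trait with genotype plus the
#' available design covariates (`year`, `bed`, and a quadratic along-bed
#' position term when a `bed_pos` column is present), then extracts
#' marginal genotype means averaged over the other factors, pairwise
#' genotype comparisons with multiplicity adjustment, and a compact letter
#' display. This is a deliberately simplified surrogate for a generalized
#' least squares fit with an explicit spatial correlation structure; the
#' divergence is recorded in the returned object.
#'
#' @param data Row-level table with `genotype`, the trait column, and
#'   optionally `year`, `bed`, `bed_pos`.
#' @param trait Trait column (tidy evaluation).
#' @param design Character vector of extra right-hand-side model terms; by
#'   default built from the covariate columns present.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param adjust Multiplicity adjustment for pairwise comparisons;
#'   `"tukey"` when the genotype design is balanced, `"holm"` otherwise
#'   (the default picks automatically).
#' @return An object of class `genotype_means`; `tidy()` returns the
#'   per-genotype table (`genotype`, `mean`, `se`, `df`, `letters`),
#'   `glance()` the model-level summary.
#' @export
estimate_genotype_means <- function(data, trait, design = NULL, alpha = 0.05,
                                    adjust = NULL) {
  stopifnot(is.data.frame(data))
  if (!"genotype" %in% names(data)) abort("data needs a genotype column", class = "deeproot_error")
  d <- as_tibble(data)
  d$.y <- dplyr::pull(d, {{ trait }})
  trait_name <- rlang::as_name(rlang::enquo(trait))
  d <- filter(d, is.finite(.data$.y), !is.na(.data$genotype))
  d$genotype <- factor(d$genotype)
  counts <- table(d$genotype)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("need at least 2 genotypes with at least 2 replicates each", class = "deeproot_error")
  }
  if (is.null(design)) {
    design <- character(0)
    for (v in c("year", "bed")) {
      if (v %in% names(d) && dplyr::n_distinct(d[[v]]) > 1) {
        d[[v]] <- factor(d[[v]])
        design <- c(design, v)
      }
    }
    if ("bed_pos" %in% names(d) && dplyr::n_distinct(d$bed_pos) > 2) {
      design <- c(design, "poly(bed_pos, 2)")
    }
  }
  rhs <- paste(c("genotype", design), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    abort(paste0("rank-deficient design: genotype aliased with covariates (",
                 paste(aliased, collapse = ", "), ")"), class = "deeproot_error")
  }
  balanced <- length(unique(counts)) == 1
  if (is.null(adjust)) adjust <- if (balanced) "tukey" else "holm"

  em <- emmeans::emmeans(fit, "genotype")
  em_tab <- as.data.frame(em)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  glev <- levels(d$genotype)
  p_mat <- matrix(1, length(glev), length(glev), dimnames = list(glev, glev))
  cn <- strsplit(as.character(pr$contrast), " - ", fixed = TRUE)
  for (i in seq_along(cn)) {
    a <- gsub("^\\(|\\)$", "", cn[[i]][1])
    b <- gsub("^\\(|\\)$", "", cn[[i]][2])
    pv <- pr$p.value[i]
    if (is.nan(pv)) pv <- 1  # zero-variance fits: no evidence of a difference
    p_mat[a, b] <- p_mat[b, a] <- pv
  }
  means <- setNames(em_tab$emmean, as.character(em_tab$genotype))
  lab <- compact_letters(glev, p_mat, means, alpha = alpha)
  means_tbl <- tibble(
    genotype = as.character(em_tab$genotype),
    mean = em_tab$emmean,
    se = em_tab$SE,
    df = em_tab$df,
    letters = unname(lab[as.character(em_tab$genotype)])
  )
  structure(list(
    means = means_tbl,
    pairwise = as_tibble(pr),
    p_matrix = p_mat,
    fit = fit,
    trait = trait_name,
    design = design,
    adjust = adjust,
    alpha = alpha,
    balanced = balanced,
    note = "fixed-effects surrogate for gls with spatial correlation structure"
  ), class = "genotype_means")
}

#' @export
print.genotype_means <- function(x, ...) {
  cat(sprintf("<genotype_means> trait: %s, %d genotypes, adjust: %s (alpha = %g)\n",
              x$trait, nrow(x$means), x$adjust, x$alpha))
  print(x$means)
  invisible(x)
}

#' @export
tidy.genotype_means <- function(x, ...) x$means

#' @export
glance.genotype_means <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    trait = x$trait,
    n = length(sm$residuals),
    n_genotypes = nrow(x$means),
    sigma = sm$sigma,
    df.residual = x$fit$df.residual,
    adjust = x$adjust,
    alpha = x$alpha,
    balanced = x$balanced,
    note = x$note
  )
}

#' Per-genotype trait means
#'
#' Simple cultivar means of a per-row column, the inputs to the
#' correlation analyses.
#'
#' @param data Per-row table with a `genotype` column.
#' @param value Column (tidy evaluation) to average.
#' @return Tibble with `genotype` and `mean` (NA values dropped).
#' @export
cultivar_means <- function(data, value) {
  stopifnot(is.data.frame(data))
  data |>
    group_by(.data$genotype) |>
    summarise(mean = mean({{ value }}, na.rm = TRUE), .groups = "drop")
}
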