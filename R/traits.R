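#' DeepRoot threshold depth (DeepRoot40)
#'
#' The soil depth below which a target amount of cumulative root length
#' (default 40 cm) is observed along the minirhizotron. Writing C(d) for
#' the root length observed at depths >= d, the trait is the greatest depth
#' d* with C(d*) >= target; larger values mean deeper rooting. Each image's
#' length is anchored at its image depth and the cumulative-from-bottom
#' curve is taken piecewise linear between adjacent image depths, so the
#' crossing depth is interpolated within the crossing image rather than
#' quantized to the 35-mm image grid.
#'
#' @param profile A [build_profile()] result (or any data frame with
#'   `depth_m` and `root_length_cm`).
#' @param target_cm Cumulative root length target in cm (default 40).
#' @return Depth in cm, or `NA` when the whole tube holds less than
#'   `target_cm` of root (a message reports the shortfall).
#' @export
deep_root_threshold <- function(profile, target_cm = 40) {
  stopifnot(is.data.frame(profile), target_cm > 0)
  if (nrow(profile) == 0) abort("empty profile", class = "deeproot_error")
  d <- profile$depth_m * 100
  len <- profile$root_length_cm
  if (is.unsorted(d)) {
    o <- order(d)
    d <- d[o]
    len <- len[o]
  }
  out <- dr_threshold_cm(d, len, target_cm)
  if (is.na(out)) {
    message(sprintf("total root length %.2f cm is below the %g cm target",
                    sum(len), target_cm))
  }
  out
}

# core crossing solve on sorted depth (cm) / length vectors; NA on shortfall
dr_threshold_cm <- function(d_cm, len, target_cm) {
  s <- rev(cumsum(rev(len)))  # s[j] = root length at depths >= d[j]
  if (s[1] < target_cm) {
    return(NA_real_)
  }
  j <- max(which(s >= target_cm))
  if (j == length(d_cm)) {
    return(d_cm[j])
  }
  # descend the linear segment from (d[j], s[j]) to (d[j+1], s[j+1])
  d_cm[j] + (s[j] - target_cm) / len[j] * (d_cm[j + 1] - d_cm[j])
}

#' Fit a sigmoid (logistic decay) to root length versus depth
#'
#' Fits `y(d) = A / (1 + exp(k (d - m)))` to per-image root length against
#' soil depth (cm) by bounded Levenberg-Marquardt least squares. The curve
#' decreases with depth, capturing the transition from dense shallow roots
#' to sparse deep roots; the inflection depth `m` is a rooting-depth proxy.
#'
#' Initialisation: `A0` = 95th percentile of y, `m0` = length-weighted
#' median depth, `k0` = 4 / depth range. `m` is constrained to the observed
#' depth range; a fit pinned at a bound, a non-converging fit, or a
#' near-constant profile (coefficient of variation < 0.05) yields an
#' undefined result.
#'
#' @inheritParams deep_root_threshold
#' @return An object of class `root_sigmoid` with elements `converged`,
#'   `m_cm`, `A`, `k`, `reason`, `n`, and the underlying `nls` fit (or
#'   `NULL`). Use [sigmoid_inflection()] for just the inflection depth;
#'   `tidy()` and `glance()` methods are provided.
#' @export
fit_root_sigmoid <- function(profile) {
  stopifnot(is.data.frame(profile))
  d <- profile$depth_m * 100
  y <- profile$root_length_cm
  ok <- is.finite(d) & is.finite(y)
  d <- d[ok]
  y <- y[ok]
  fail <- function(reason) {
    structure(list(converged = FALSE, m_cm = NA_real_, A = NA_real_, k = NA_real_,
                   reason = reason, n = length(d), fit = NULL),
              class = "root_sigmoid")
  }
  if (length(d) < 8) return(fail("fewer than 8 observations"))
  if (diff(range(d)) < 50) return(fail("depth span below 0.5 m"))
  if (mean(y) <= 0 || stats::sd(y) / mean(y) < 0.05) return(fail("no depth transition (near-constant profile)"))
  a0 <- as.numeric(quantile(y, 0.95))
  m0 <- as.numeric(quantile(rep(d, times = pmax(1, round(y * 100))), 0.5, type = 1))
  if (!is.finite(m0)) m0 <- stats::median(d)
  k0 <- 4 / diff(range(d))
  lo <- c(A = 1e-9, k = 1e-9, m = min(d))
  hi <- c(A = Inf, k = 5, m = max(d))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / (1 + exp(k * (d - m))),
      start = list(A = a0, k = k0, m = m0),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail("fit did not converge"))
  est <- coef(fit)
  tol <- 1e-6 * max(1, diff(range(d)))
  if (est["m"] <= lo["m"] + tol || est["m"] >= hi["m"] - tol) {
    return(fail("inflection pinned at a depth bound"))
  }
  structure(list(converged = TRUE, m_cm = unname(est["m"]), A = unname(est["A"]),
                 k = unname(est["k"]), reason = NA_character_, n = length(d), fit = fit),
            class = "root_sigmoid")
}

#' Sigmoid inflection depth of a root profile
#'
#' @inheritParams deep_root_threshold
#' @return Inflection depth in cm, or `NA` when the fit is undefined (the
#'   diagnostic reason is reported as a message).
#' @export
sigmoid_inflection <- function(profile) {
  sf <- fit_root_sigmoid(profile)
  if (!sf$converged) message("sigmoid inflection undefined: ", sf$reason)
  sf$m_cm
}

#' @export
print.root_sigmoid <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<root_sigmoid> m = %.1f cm, A = %.3f cm, k = %.4f /cm (n = %d)\n",
                x$m_cm, x$A, x$k, x$n))
  } else {
    cat(sprintf("<root_sigmoid> undefined: %s (n = %d)\n", x$reason, x$n))
  }
  invisible(x)
}

#' @export
tidy.root_sigmoid <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = c("A", "k", "m"), estimate = NA_real_, std.error = NA_real_))
  }
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, "Estimate"], std.error = sm[, "Std. Error"])
}

#' @export
glance.root_sigmoid <- function(x, ...) {
  tibble(
    converged = x$converged,
    m_cm = x$m_cm,
    sigma = if (x$converged) summary(x$fit)$sigma else NA_real_,
    n = x$n,
    reason = x$reason
  )
}

#' Deep-rooting traits for every tube and session in an observation table
#'
#' Groups a long observation table by crop row and imaging session, builds
#' each depth profile, and computes the deep-rooting traits: the DeepRoot
#' threshold depth, optionally the sigmoid inflection depth, and total root
#' length within each requested depth interval.
#'
#' @param observations Long-format table with columns `row_id`, `session`,
#'   `position_mm`, `root_length_cm` (a `genotype` and/or `year` column is
#'   carried through).
#' @param geom A [tube_geometry()].
#' @param target_cm Cumulative target for [deep_root_threshold()].
#' @param intervals A list of two-element numeric vectors `(d_lo, d_hi)` in
#'   metres; each adds a column `L<d_lo>_<d_hi>` of interval root length.
#' @param fit_sigmoid Fit the sigmoid inflection trait (default `TRUE`;
#'   skipping it is markedly faster for large simulations).
#' @return A tibble with one row per `row_id` x `session`, columns
#'   `deep_root40_cm`, `si_cm` (if fitted) and one column per interval.
#'   Undefined traits are `NA`.
#' @export
compute_root_traits <- function(observations, geom = tube_geometry(),
                                target_cm = 40,
                                intervals = list(c(1.6, 1.8)),
                                fit_sigmoid = TRUE) {
  stopifnot(is.data.frame(observations))
  req <- c("row_id", "session", "position_mm", "root_length_cm")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    abort(paste0("observations lack column(s): ", paste(missing_cols, collapse = ", ")),
          class = "deeproot_error")
  }
  obs <- as_tibble(observations)
  obs$depth_m <- depth_at_position(obs$position_mm, geom)
  carry <- intersect(c("genotype", "year"), names(obs))
  key_tbl <- distinct(obs, across(all_of(c("row_id", "session", carry))))

  int_names <- vapply(intervals, function(iv) sprintf("L%g_%g", iv[1], iv[2]), character(1))
  obs <- arrange(obs, .data$row_id, .data$session, .data$depth_m)
  key <- paste(obs$row_id, obs$session, sep = "\r")
  idx <- split(seq_len(nrow(obs)), factor(key, levels = unique(key)))
  d_cm <- obs$depth_m * 100
  len <- obs$root_length_cm
  traits <- tibble(
    row_id = obs$row_id[vapply(idx, `[`, integer(1), 1L)],
    session = obs$session[vapply(idx, `[`, integer(1), 1L)],
    deep_root40_cm = vapply(idx, function(i) dr_threshold_cm(d_cm[i], len[i], target_cm),
                            numeric(1), USE.NAMES = FALSE)
  )
  if (fit_sigmoid) {
    traits$si_cm <- vapply(idx, function(i) {
      fit_root_sigmoid(tibble(depth_m = obs$depth_m[i], root_length_cm = len[i]))$m_cm
    }, numeric(1), USE.NAMES = FALSE)
  }
  for (j in seq_along(intervals)) {
    iv <- intervals[[j]]
    in_iv <- obs$depth_m >= iv[1] & obs$depth_m < iv[2]
    traits[[int_names[j]]] <- vapply(idx, function(i) sum(len[i][in_iv[i]]),
                                     numeric(1), USE.NAMES = FALSE)
  }
  left_join(key_tbl, traits, by = c("row_id", "session"))
}

#' Screen depth intervals for association with an isotope measurement
#'
#' For each depth interval, computes cultivar (genotype) means of interval
#' root length and of an isotope value, and their Pearson correlation
#' across cultivars. Used to identify the soil depths whose root length
#' best predicts tracer uptake.
#'
#' @param observations Long observation table (see [compute_root_traits()])
#'   with a `genotype` column.
#' @param isotope Per-row table with columns `row_id`, `genotype`, `value`.
#' @param intervals List of `(d_lo, d_hi)` depth intervals in metres.
#' @param geom A [tube_geometry()].
#' @return A tibble with one row per interval: `d_lo`, `d_hi`, `r`, `p`,
#'   `n`, `note`.
#' @export
interval_screen <- function(observations, isotope, intervals, geom = tube_geometry()) {
  stopifnot(is.data.frame(observations), is.data.frame(isotope))
  if (!"genotype" %in% names(observations)) {
    abort("observations need a genotype column for cultivar means", class = "deeproot_error")
  }
  obs <- as_tibble(observations)
  obs$depth_m <- depth_at_position(obs$position_mm, geom)
  iso_means <- isotope |>
    group_by(.data$genotype) |>
    summarise(iso = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (nrow(iso_means) < 3) {
    abort("fewer than 3 cultivar means available for the interval screen", class = "deeproot_error")
  }
  purrr::map_dfr(intervals, function(iv) {
    len <- obs |>
      group_by(.data$row_id, .data$genotype) |>
      summarise(L = sum(.data$root_length_cm[.data$depth_m >= iv[1] & .data$depth_m < iv[2]]),
                .groups = "drop") |>
      group_by(.data$genotype) |>
      summarise(L = mean(.data$L), .groups = "drop")
    xy <- left_join(len, iso_means, by = "genotype")
    res <- cultivar_mean_correlation(xy, L, iso)
    tibble(d_lo = iv[1], d_hi = iv[2], r = res$r, p = res$p, n = res$n, note = res$note)
  })
}
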