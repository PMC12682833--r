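#' Build a depth-ordered root profile for one tube and session
#'
#' Takes the per-image observations of a single crop row (tube) at a single
#' imaging session, registers tube positions to soil depth, and returns the
#' observations ordered by increasing depth.
#'
#' @param observations A data frame with columns `position_mm` and
#'   `root_length_cm` (optionally `row_id`, `session`, `genotype`, carried
#'   through). All rows must belong to one tube and session.
#' @param geom A [tube_geometry()].
#' @return A tibble of class `root_profile` with columns `position_mm`,
#'   `depth_m`, `root_length_cm`, sorted by depth.
#' @export
build_profile <- function(observations, geom = tube_geometry()) {
  stopifnot(is.data.frame(observations))
  req <- c("position_mm", "root_length_cm")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    abort(paste0("observations lack column(s): ", paste(missing_cols, collapse = ", ")),
          class = "deeproot_error")
  }
  if (nrow(observations) == 0) abort("empty observation set", class = "deeproot_error")
  for (key in c("row_id", "session")) {
    if (key %in% names(observations) && dplyr::n_distinct(observations[[key]]) > 1) {
      abort(sprintf("observations span multiple values of %s; build one profile per tube and session", key),
            class = "deeproot_error")
    }
  }
  dup <- observations$position_mm[duplicated(observations$position_mm)]
  if (length(dup)) {
    abort(paste0("duplicate tube positions: ", paste(unique(dup), collapse = ", ")),
          class = "deeproot_error")
  }
  if (any(observations$root_length_cm < 0, na.rm = TRUE)) {
    abort("root lengths must be non-negative", class = "deeproot_error")
  }
  out <- as_tibble(observations)
  out$depth_m <- depth_at_position(out$position_mm, geom)
  out <- arrange(out, .data$depth_m)
  class(out) <- c("root_profile", class(out))
  out
}

#' Bin a root profile into depth intervals (planar root length density)
#'
#' Sums per-image root length within half-open depth bins and divides by the
#' observation area of each bin to give planar root length density (pRLD,
#' cm of root per cm^2 of image). Bins containing no image are reported
#' with `NA` pRLD (undefined), not zero.
#'
#' @param profile A [build_profile()] result (or any data frame with
#'   `depth_m` and `root_length_cm`).
#' @param geom A [tube_geometry()].
#' @param bin_width_m Bin width in metres (default 0.30).
#' @return A tibble of class `binned_profile` with columns `depth_lo`,
#'   `depth_hi`, `n_images`, `root_length_cm`, `area_cm2`, `prld`.
#' @export
bin_profile <- function(profile, geom = tube_geometry(), bin_width_m = 0.30) {
  stopifnot(is.data.frame(profile), bin_width_m > 0)
  lo0 <- geom$first_image_depth_m
  n_bins <- ceiling((geom$last_image_depth_m - lo0) / bin_width_m - 1e-9)
  edges <- lo0 + bin_width_m * seq(0, n_bins)
  img <- image_depths(geom)$depth_m
  bin_of <- function(d) pmin(pmax(findInterval(d, edges), 1L), n_bins)
  n_img <- tabulate(bin_of(img), nbins = n_bins)
  len <- tapply(profile$root_length_cm, factor(bin_of(profile$depth_m), levels = seq_len(n_bins)), sum)
  len <- as.numeric(ifelse(is.na(len), 0, len))
  area_cm2 <- n_img * geom$image_step_mm * geom$image_width_mm / 100  # mm^2 -> cm^2
  out <- tibble(
    depth_lo = edges[-length(edges)],
    depth_hi = edges[-1],
    n_images = n_img,
    root_length_cm = len,
    area_cm2 = area_cm2,
    prld = ifelse(area_cm2 > 0, len / area_cm2, NA_real_)
  )
  class(out) <- c("binned_profile", class(out))
  out
}

#' Total root length observed within a depth interval
#'
#' Sum of per-image root lengths at depths in the half-open interval
#' `[d_lo, d_hi)`.
#'
#' @inheritParams bin_profile
#' @param d_lo,d_hi Interval bounds in metres, `d_lo < d_hi`.
#' @return Length in cm (0 when no image falls in the interval).
#' @export
interval_root_length <- function(profile, d_lo, d_hi) {
  stopifnot(is.data.frame(profile))
  if (d_lo >= d_hi) abort("inverted interval: d_lo must be smaller than d_hi", class = "deeproot_error")
  sum(profile$root_length_cm[profile$depth_m >= d_lo & profile$depth_m < d_hi])
}
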