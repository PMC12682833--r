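#' Plot a binned root profile (pRLD against depth)
#'
#' @param object A [bin_profile()] result.
#' @param ... Unused.
#' @return A ggplot with depth increasing downwards.
#' @export
autoplot.binned_profile <- function(object, ...) {
  df <- filter(as_tibble(object), !is.na(.data$prld))
  df$depth_mid <- (df$depth_lo + df$depth_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prld, y = .data$depth_mid)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "planar root length density (cm cm⁻²)",
                  y = "soil depth (m)") +
    ggplot2::theme_minimal()
}

#' Plot mean pRLD profiles by genotype
#'
#' Bins every tube profile and averages pRLD per genotype and depth bin.
#'
#' @param observations Long observation table (see [compute_root_traits()])
#'   with a `genotype` column.
#' @param geom A [tube_geometry()].
#' @param bin_width_m Depth bin width in metres.
#' @param genotypes Optional subset of genotypes to display.
#' @return A ggplot.
#' @export
plot_root_profiles <- function(observations, geom = tube_geometry(),
                               bin_width_m = 0.30, genotypes = NULL) {
  stopifnot(is.data.frame(observations))
  obs <- as_tibble(observations)
  if (!is.null(genotypes)) obs <- filter(obs, .data$genotype %in% genotypes)
  binned <- obs |>
    group_by(.data$row_id, .data$genotype) |>
    dplyr::group_modify(~ bin_profile(build_profile(.x, geom), geom, bin_width_m)) |>
    ungroup() |>
    group_by(.data$genotype, .data$depth_lo, .data$depth_hi) |>
    summarise(prld = mean(.data$prld, na.rm = TRUE), .groups = "drop") |>
    filter(is.finite(.data$prld))
  binned$depth_mid <- (binned$depth_lo + binned$depth_hi) / 2
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$prld, y = .data$depth_mid,
                                       colour = .data$genotype)) +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "planar root length density (cm cm⁻²)",
                  y = "soil depth (m)", colour = "genotype") +
    ggplot2::theme_minimal()
}

#' Plot estimated genotype means with letters
#'
#' @param object An [estimate_genotype_means()] result.
#' @param ... Unused.
#' @return A ggplot of means, standard-error bars and compact letters.
#' @export
autoplot.genotype_means <- function(object, ...) {
  df <- object$means
  df$genotype <- stats::reorder(df$genotype, df$mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters), vjust = -1.2, size = 3) +
    ggplot2::labs(x = NULL, y = object$trait) +
    ggplot2::theme_minimal()
}
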