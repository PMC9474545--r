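#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_tile
#'   geom_vline labs theme_minimal scale_fill_gradient2 facet_wrap
#'   stat_function
NULL

#' Plot a metagene profile
#'
#' Mean enrichment (or normalised coverage) per bin with dashed lines at
#' the 5'UTR/CDS and CDS/3'UTR boundaries.
#'
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  bounds <- as_tibble(object) |>
    group_by(.data$region) |>
    summarise(last = max(.data$bin), .groups = "drop") |>
    arrange(.data$last)
  ggplot(as_tibble(object), aes(x = .data$bin, y = .data$mean)) +
    geom_line() +
    geom_vline(xintercept = head(bounds$last, -1) + 0.5, linetype = "dashed") +
    labs(x = "metagene bin (5'UTR | CDS | 3'UTR)", y = "mean value") +
    theme_minimal()
}

#' Heatmap of row-z-scored bin values
#'
#' @param x Output of [zscore_rows()].
#' @return A ggplot object.
#' @export
plot_zscore_heatmap <- function(x) {
  ggplot(as_tibble(x), aes(x = .data$bin, y = .data$gene_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "metagene bin", y = NULL, fill = "row z") +
    theme_minimal()
}

#' Bar chart of the regional peak distribution
#'
#' @param x Output of [region_distribution()].
#' @return A ggplot object.
#' @export
plot_region_distribution <- function(x) {
  ggplot(as_tibble(x), aes(
    x = factor(.data$region, levels = REGIONS), y = .data$pct
  )) +
    geom_col() +
    labs(x = NULL, y = "% of peaks") +
    theme_minimal()
}

#' Plot a decay series with its fitted curve
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  k <- object$k
  n0 <- object$n0
  ggplot(object$series, aes(x = .data$time, y = .data$level)) +
    geom_point() +
    stat_function(fun = function(t) n0 * exp(-k * t)) +
    labs(x = "time (h)", y = "relative RNA level") +
    theme_minimal()
}
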