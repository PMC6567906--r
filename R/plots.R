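#' Plot the ISG score distribution
#'
#' Histogram of log10 ISG scores with the positivity threshold marked,
#' the standard way the bimodality of the score is displayed.
#'
#' @param scores Classified score tibble (from [classify_samples()]) or an
#'   `ifn_analysis`.
#' @param threshold Threshold to mark; defaults to the `"threshold"`
#'   attribute of `scores`.
#' @param bins Number of histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, threshold = NULL, bins = 30) {
  if (inherits(scores, "ifn_analysis")) {
    threshold <- threshold %||% scores$manifest$threshold
    scores <- scores$scores
  }
  threshold <- threshold %||% attr(scores, "threshold")
  dat <- dplyr::filter(scores, !is.na(.data$score), .data$score > 0)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = log10(.data$score))) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70",
                            colour = "grey30") +
    ggplot2::labs(x = "log10 ISG score", y = "patients") +
    ggplot2::theme_minimal()
  if (!is.null(threshold) && is.finite(threshold) && threshold > 0) {
    p <- p + ggplot2::geom_vline(xintercept = log10(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' @describeIn fit_mixture_em Density overlay of the fitted components on
#'   the score histogram.
#' @export
autoplot.ifn_mixture <- function(object, bins = 30, ...) {
  x <- object$data
  grid <- seq(min(x), max(x), length.out = 200)
  dens <- tibble::tibble(
    x = rep(grid, 2),
    component = rep(c("IFN-low", "IFN-high"), each = length(grid)),
    density = c(
      object$weights[1] * stats::dnorm(grid, object$means[1], object$sds[1]),
      object$weights[2] * stats::dnorm(grid, object$means[2], object$sds[2])
    )
  )
  ggplot2::ggplot(tibble::tibble(x = x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component),
      linewidth = 1
    ) +
    ggplot2::labs(x = "log10 ISG score", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn spearman_matrix Dot-style correlation heatmap; only pairs
#'   significant at the mask level are drawn.
#' @param object A `spearman_matrix`.
#' @export
autoplot.spearman_matrix <- function(object, ...) {
  dat <- tidy(object) |> dplyr::filter(.data$significant)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$var1, y = .data$var2)) +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$r),
                                     colour = .data$r)) +
    ggplot2::scale_colour_gradient2(low = "firebrick", mid = "white",
                                    high = "steelblue", limits = c(-1, 1)) +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, colour = "Spearman r",
                  size = "|r|") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' NAR expression heatmap ordered by cluster
#'
#' Tile heatmap of per-gene z-scored log10 RQ, rows (patients) ordered by
#' k-means cluster.
#'
#' @param nar_rq NAR RQ tibble (`sample_id`, `gene`, `rq`).
#' @param clusters A `nar_clusters` object from [cluster_patients()].
#' @return A ggplot object.
#' @export
plot_nar_heatmap <- function(nar_rq, clusters) {
  stopifnot(inherits(clusters, "nar_clusters"))
  dat <- nar_rq |>
    dplyr::filter(.data$rq > 0) |>
    dplyr::mutate(l10 = log10(.data$rq)) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(z = as.numeric(scale(.data$l10))) |>
    dplyr::ungroup() |>
    dplyr::inner_join(clusters$assignments, by = "sample_id") |>
    dplyr::arrange(.data$cluster, .data$sample_id) |>
    dplyr::mutate(sample_id = factor(.data$sample_id,
                                     levels = unique(.data$sample_id)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$sample_id,
                                    fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z(log10 RQ)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
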