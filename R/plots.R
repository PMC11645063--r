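#' Plot an embedding, optionally colored by class
#'
#' @param coords A coordinates tibble `(.row_id, c1, c2)` or a
#'   `psdg_embedding` (its training coordinates are used).
#' @param labels Optional per-row class labels.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels = NULL, title = "2D embedding") {
  if (inherits(coords, "psdg_embedding")) coords <- coords$training_coords
  df <- as_tibble(coords)
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$c1, y = .data$c2))
  } else {
    df$class <- as.character(labels)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$c1, y = .data$c2, colour = .data$class))
  }
  p +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "c1", y = "c2") +
    ggplot2::theme_minimal()
}

#' Plot cluster areas over a reference embedding
#'
#' @param object A `psdg_clusters` table.
#' @param coords Optional reference coordinates drawn underneath.
#' @param labels Optional labels for the reference points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psdg_clusters <- function(object, coords = NULL, labels = NULL, ...) {
  theta <- seq(0, 2 * pi, length.out = 181)
  circles <- purrr::pmap_dfr(
    list(object$label, object$c1, object$c2, object$radius),
    function(lb, x0, y0, r) {
      tibble(label = lb, c1 = x0 + r * cos(theta), c2 = y0 + r * sin(theta))
    }
  )
  p <- ggplot2::ggplot()
  if (!is.null(coords)) {
    df <- as_tibble(coords)
    if (!is.null(labels)) df$class <- as.character(labels)
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(
        x = .data$c1, y = .data$c2,
        colour = if (is.null(labels)) NULL else .data$class
      ),
      alpha = 0.4, size = 0.8
    )
  }
  p +
    ggplot2::geom_path(
      data = circles,
      ggplot2::aes(x = .data$c1, y = .data$c2, group = .data$label)
    ) +
    ggplot2::geom_point(
      data = as_tibble(object),
      ggplot2::aes(x = .data$c1, y = .data$c2), shape = 4, size = 3
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "c1", y = "c2") +
    ggplot2::theme_minimal()
}

#' Plot a cluster validation curve
#'
#' Percentage of points assigned per class (and in total) against the
#' density threshold; assigned percentages are non-increasing in the
#' threshold.
#'
#' @param curve Output of [validation_curve()].
#' @return A ggplot object.
#' @export
plot_validation_curve <- function(curve) {
  ggplot2::ggplot(
    curve,
    ggplot2::aes(
      x = .data$density_threshold, y = .data$pct,
      colour = .data$label, group = .data$label
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "density threshold (points per unit area)",
      y = "% of points cluster-validated"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a rotation evaluation report
#'
#' Mean correct-imputation percentage per method; the generation pipeline
#' appears once per reliability threshold.
#'
#' @param object A `psdg_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psdg_report <- function(object, ...) {
  td <- generics::tidy(object)
  td$label <- ifelse(is.na(td$r_min), td$method, sprintf("%s (r_min=%.1f)", td$method, td$r_min))
  td$label <- factor(td$label, levels = td$label)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$label, y = .data$mean_pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% rows correctly imputed (mean over rotations)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
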