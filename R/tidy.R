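#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a rotation evaluation report
#'
#' One row per method (and reliability threshold for the generation
#' pipeline), with correct-imputation counts and percentages averaged
#' across the rotations.
#'
#' @param x A `psdg_report`.
#' @param ... Unused.
#' @return A tibble `(method, r_min, mean_n_correct, mean_pct)`.
#' @export
tidy.psdg_report <- function(x, ...) {
  x$methods |>
    dplyr::group_by(.data$method, .data$r_min) |>
    dplyr::summarise(
      mean_n_correct = mean(.data$n_correct),
      mean_pct = mean(.data$pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$method, c("psdg", "mean", "knn")), dplyr::desc(dplyr::coalesce(.data$r_min, -1)))
}

#' @rdname tidy.psdg_report
#' @export
glance.psdg_report <- function(x, ...) {
  td <- tidy.psdg_report(x)
  tibble(
    feature = x$feature,
    n_groups = x$n_groups,
    group_size = x$group_size,
    psdg_pct_rmin1 = td$mean_pct[td$method == "psdg" & td$r_min == max(x$r_min_ladder)],
    mean_pct = td$mean_pct[td$method == "mean"],
    knn_pct = td$mean_pct[td$method == "knn"]
  )
}

#' Tidy a fitted embedding (its training coordinates)
#'
#' @param x A `psdg_embedding`.
#' @param ... Unused.
#' @return The training coordinates tibble `(.row_id, c1, c2)`.
#' @export
tidy.psdg_embedding <- function(x, ...) x$training_coords

#' @rdname tidy.psdg_embedding
#' @export
glance.psdg_embedding <- function(x, ...) {
  tibble(
    backend = x$backend,
    n_features = length(x$feature_order),
    n_training_rows = nrow(x$training_coords),
    n_neighbors = x$hyperparameters$n_neighbors,
    seed = x$seed
  )
}

#' Tidy a validated dataset (per-source-row validation counts)
#'
#' @param x A `psdg_validated`.
#' @param ... Unused.
#' @return A tibble `(.source_id, n_validated, best_r_c)`.
#' @export
tidy.psdg_validated <- function(x, ...) {
  if (!".source_id" %in% names(x)) {
    return(as_tibble(x))
  }
  tbl <- as_tibble(x)
  has_rc <- "r_c" %in% names(tbl)
  tbl |>
    dplyr::group_by(.source_id = .data$.source_id) |>
    dplyr::summarise(
      n_validated = dplyr::n(),
      best_r_c = if (has_rc) max(.data$r_c) else NA_real_,
      .groups = "drop"
    )
}

#' @rdname tidy.psdg_validated
#' @export
glance.psdg_validated <- function(x, ...) {
  counts <- attr(x, "counts") %||% list()
  tibble(
    n_reference = counts$n_reference %||% NA_integer_,
    n_incomplete = counts$n_incomplete %||% NA_integer_,
    m = counts$m %||% NA_integer_,
    n_generated = counts$n_generated %||% NA_integer_,
    n_validated = nrow(x)
  )
}
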