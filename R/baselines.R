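#' Classical imputation baselines
#'
#' `mean_impute()` assigns the reference column mean to every missing cell
#' of the feature (snapped to the nearest grid value for non-continuous
#' kinds). `knn_impute()` assigns the mean of the feature over the `k`
#' nearest reference rows, with Euclidean distance computed in the
#' *normalized known-feature space* (not the 2D embedding), grid-snapped the
#' same way; ties at the k-th distance break by ascending reference id.
#'
#' @param reference A complete `psdg_dataset`.
#' @param incomplete A `psdg_dataset` whose `feature` column is missing.
#' @param feature The feature to impute.
#' @param k Neighbor count for `knn_impute()`.
#' @return The incomplete dataset with the feature column filled.
#' @export
mean_impute <- function(reference, incomplete, feature) {
  value <- mean(reference[[feature]])
  value <- snap_for_kind(value, reference, feature)
  fill_feature(incomplete, feature, rep(value, nrow(incomplete)))
}

#' @rdname mean_impute
#' @export
knn_impute <- function(reference, incomplete, feature, k = 10L) {
  k <- assert_scalar_int(k, "k")
  if (k > nrow(reference)) abort(sprintf("k = %d exceeds the %d reference rows.", k, nrow(reference)))
  known <- intersect(known_features(incomplete), dataset_features(reference))
  known <- setdiff(known, feature)
  if (length(known) == 0) abort("No known features shared with the reference.")

  ref_known <- select_features(reference, known)
  normalizer <- fit_normalizer(ref_known)
  rx <- as.matrix(apply_normalizer(ref_known, normalizer)[known])
  qx <- as.matrix(apply_normalizer(as.data.frame(incomplete), normalizer, features = known)[known])

  ord <- stable_order(reference$.row_id) # deterministic tie-break by id
  rx <- rx[ord, , drop = FALSE]
  rv <- reference[[feature]][ord]

  # column-by-column squared differences, matching a per-pair computation
  # float-for-float so distance ties resolve identically everywhere
  d2 <- 0
  for (j in seq_len(ncol(rx))) d2 <- d2 + outer(qx[, j], rx[, j], "-")^2
  values <- apply(sqrt(d2), 1, function(row) {
    nb <- stable_order(row)[seq_len(k)]
    mean(rv[nb])
  })
  values <- snap_for_kind(values, reference, feature)
  fill_feature(incomplete, feature, values)
}

snap_for_kind <- function(values, reference, feature) {
  spec <- schema_feature(dataset_schema(reference), feature)
  if (spec$kind == "continuous") {
    return(values)
  }
  snap_to_grid(values, enumerate_values(reference, feature))
}

fill_feature <- function(incomplete, feature, values) {
  out <- as_tibble(as.data.frame(incomplete))
  out[[feature]] <- ifelse(is.na(out[[feature]]), values, out[[feature]])
  psdg_dataset(out, dataset_schema(incomplete),
    label_name = dataset_label(incomplete), id_col = ".row_id", strict = FALSE
  )
}

#' Rotation validation harness
#'
#' Evaluates the generation pipeline against ground truth by holding data
#' out of a complete table: the rows are split into `n_groups` equal random
#' groups (remainder rows dropped with a warning); each group in turn
#' serves as the reference while the remaining rows, with the evaluation
#' feature blanked, serve as incomplete data. Per rotation the candidates
#' are scored once and filtered across the whole `r_min` ladder; a
#' validated candidate is *correctly imputed* when its value equals the
#' held-out truth (truth is first snapped onto the candidate grid), all
#' other validated candidates are purely synthetic. Both classical
#' baselines run on the same splits, and all counts are averaged across the
#' rotations.
#'
#' @param complete A complete `psdg_dataset` containing the evaluation
#'   feature (ground truth).
#' @param feature The feature to hold out and evaluate.
#' @param config A [psdg_config()]; its seed drives the group assignment.
#' @param n_groups Number of rotation groups.
#' @param r_min_ladder Reliability thresholds to evaluate.
#' @param baseline_k `k` for the k-NN baseline.
#' @return A `psdg_report` with components `summary` (per rotation and
#'   `r_min`: validated / correctly imputed / synthetic counts and the
#'   percentage of rows correctly imputed), `methods` (per-method per-
#'   rotation correct-imputation percentages), `detail` (per-row outcomes,
#'   used by [range_table()]), and the protocol parameters.
#' @export
rotation_validate <- function(complete, feature, config, n_groups = 5L,
                              r_min_ladder = seq(0.5, 1, by = 0.1),
                              baseline_k = 10L) {
  n_groups <- assert_scalar_int(n_groups, "n_groups", min = 2L)
  n <- nrow(complete)
  size <- n %/% n_groups
  if (size * n_groups < n) {
    warn(sprintf(
      "Dropping %d remainder row(s) to form %d equal groups of %d.",
      n - size * n_groups, n_groups, size
    ))
  }
  if (size <= config$n_neighbors || size < config$k) {
    abort("Group size too small for the embedding/scoring neighborhoods.")
  }
  r_min_ladder <- sort(r_min_ladder)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  perm <- sample.int(n)
  groups <- split(perm[seq_len(size * n_groups)], rep(seq_len(n_groups), each = size))

  summary_rows <- list()
  method_rows <- list()
  detail_rows <- list()

  for (g in seq_len(n_groups)) {
    ref <- complete[groups[[g]], ]
    ref <- psdg_dataset(as_tibble(as.data.frame(ref)), dataset_schema(complete),
      label_name = dataset_label(complete), id_col = ".row_id"
    )
    hold_idx <- sort(unlist(groups[-g], use.names = FALSE))
    inc_tbl <- as_tibble(as.data.frame(complete[hold_idx, ]))
    truth_raw <- inc_tbl[[feature]]
    inc_tbl[[feature]] <- NA_real_
    inc <- psdg_dataset(inc_tbl, dataset_schema(complete),
      label_name = dataset_label(complete), id_col = ".row_id"
    )

    stage <- pipeline_score(ref, inc, config)
    truth <- snap_to_grid(truth_raw, stage$grid)
    truth_by_id <- stats::setNames(truth, inc_tbl$.row_id)
    n_inc <- nrow(inc)

    scored <- stage$scored
    scored$correct <- scored$x_hat == truth_by_id[scored$.row_id]

    for (rm in r_min_ladder) {
      val <- filter_validated(scored, rm)
      n_correct <- sum(val$correct)
      correct_ids <- unique(val$.row_id[val$correct])
      summary_rows[[length(summary_rows) + 1L]] <- tibble(
        rotation = g, r_min = rm,
        n_validated = nrow(val),
        correctly_imputed = n_correct,
        synthetic = nrow(val) - n_correct,
        n_rows = n_inc,
        rows_correct = length(correct_ids),
        pct_correct = 100 * length(correct_ids) / n_inc
      )
      method_rows[[length(method_rows) + 1L]] <- tibble(
        method = "psdg", r_min = rm, rotation = g,
        n_correct = length(correct_ids), n_rows = n_inc,
        pct = 100 * length(correct_ids) / n_inc
      )
      detail_rows[[length(detail_rows) + 1L]] <- tibble(
        rotation = g, method = "psdg", r_min = rm,
        .row_id = inc_tbl$.row_id, truth = truth,
        correct = inc_tbl$.row_id %in% correct_ids
      )
    }

    for (m in c("mean", "knn")) {
      imp <- if (m == "mean") {
        mean_impute(ref, inc, feature)
      } else {
        knn_impute(ref, inc, feature, k = baseline_k)
      }
      imputed <- snap_to_grid(imp[[feature]], stage$grid)
      correct <- imputed == truth
      method_rows[[length(method_rows) + 1L]] <- tibble(
        method = m, r_min = NA_real_, rotation = g,
        n_correct = sum(correct), n_rows = n_inc,
        pct = 100 * sum(correct) / n_inc
      )
      detail_rows[[length(detail_rows) + 1L]] <- tibble(
        rotation = g, method = m, r_min = NA_real_,
        .row_id = inc_tbl$.row_id, truth = truth, correct = correct
      )
    }
  }

  structure(
    list(
      summary = dplyr::bind_rows(summary_rows),
      methods = dplyr::bind_rows(method_rows),
      detail = dplyr::bind_rows(detail_rows),
      feature = feature, n_groups = n_groups, group_size = size,
      r_min_ladder = r_min_ladder,
      config_hash = config_hash(unclass(config))
    ),
    class = "psdg_report"
  )
}

#' @export
print.psdg_report <- function(x, ...) {
  cat(sprintf(
    "<psdg_report> feature '%s': %d rotations x %d rows held out\n",
    x$feature, x$n_groups, x$group_size * (x$n_groups - 1)
  ))
  print(generics::tidy(x))
  invisible(x)
}

#' Per-value-range correct-imputation table
#'
#' Reshapes a rotation report into the familiar method-comparison grid:
#' one row per method (the generation pipeline at each reliability
#' threshold, then the mean and k-NN baselines), one column per value range
#' of the held-out feature, plus a `mean_pct` column averaging the defined
#' range percentages. A range containing no true rows is `NA`, not 0.
#'
#' @param report A `psdg_report`.
#' @param bin_edges Increasing numeric vector of range boundaries; values
#'   are binned into `[e1, e2), [e2, e3), ..., [e_{n-1}, e_n]`.
#' @return A tibble with columns `method`, `r_min`, one column per range,
#'   and `mean_pct`.
#' @export
range_table <- function(report, bin_edges) {
  stopifnot(inherits(report, "psdg_report"), length(bin_edges) >= 2)
  det <- report$detail
  labs <- paste0(
    "[", bin_edges[-length(bin_edges)], ",", bin_edges[-1],
    c(rep(")", length(bin_edges) - 2), "]")
  )
  det$bin <- labs[findInterval(det$truth, bin_edges, rightmost.closed = TRUE)]
  det <- det[!is.na(det$bin), ]

  per <- det |>
    dplyr::group_by(.data$method, .data$r_min, .data$bin) |>
    dplyr::summarise(pct = 100 * sum(.data$correct) / dplyr::n(), .groups = "drop")
  grid <- tidyr::crossing(
    dplyr::distinct(det, .data$method, .data$r_min),
    bin = labs
  )
  wide <- grid |>
    dplyr::left_join(per, by = c("method", "r_min", "bin")) |>
    tidyr::pivot_wider(names_from = "bin", values_from = "pct")
  wide$mean_pct <- rowMeans(as.matrix(wide[labs]), na.rm = TRUE)
  meth_rank <- match(wide$method, c("psdg", "mean", "knn"))
  wide[stable_order(meth_rank, dplyr::coalesce(wide$r_min, -1)), ]
}
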