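#' Pipeline configuration
#'
#' One object carrying every tunable of the generation pipelines: embedding
#' backend and hyperparameters, reliability scoring settings, cluster
#' validation settings, and grid construction choices. The seed is
#' mandatory — every pipeline is deterministic under a fixed configuration.
#'
#' @param seed Integer master seed (required).
#' @param backend,n_neighbors,min_dist Embedding settings, see
#'   [fit_embedding()].
#' @param k,epsilon,r_min,bands Reliability settings, see
#'   [reliability_config()]; `epsilon = NULL` takes each grid's default
#'   band width (1 for integer/ordinal features, half the minimum level gap
#'   for categorical/binary, the bin width for quantized features).
#' @param density_threshold,r_start,r_step,r_max,density Cluster validation
#'   settings, see [fit_radius()].
#' @param n_levels Quantization levels for continuous candidate grids.
#' @param feature_order Optional feature sequence for iterative full
#'   synthesis; defaults to descending absolute correlation with the label
#'   computed on the reference.
#' @param unit_equivalences Passed to [align_schemas()].
#' @return A `psdg_config` list.
#' @export
psdg_config <- function(seed,
                        backend = "pca", n_neighbors = 15L, min_dist = 0.1,
                        k = 10L, epsilon = NULL, r_min = 1,
                        bands = reliability_bands(),
                        density_threshold = 6, r_start = 0.05, r_step = 0.05,
                        r_max = NULL, density = "area",
                        n_levels = 10L, feature_order = NULL,
                        unit_equivalences = NULL) {
  if (missing(seed)) abort("`seed` is mandatory: pipelines must be reproducible.")
  cfg <- list(
    seed = assert_scalar_int(seed, "seed", min = 0L),
    backend = backend, n_neighbors = n_neighbors, min_dist = min_dist,
    k = k, epsilon = epsilon, r_min = r_min, bands = bands,
    density_threshold = density_threshold,
    r_start = r_start, r_step = r_step, r_max = r_max, density = density,
    n_levels = n_levels, feature_order = feature_order,
    unit_equivalences = unit_equivalences
  )
  structure(cfg, class = "psdg_config")
}

# Shared stage driver for case 1/2 and the evaluation harness: align, build
# the grid, expand, embed, project, score. Returns every intermediate so
# callers can filter at several thresholds without recomputation.
pipeline_score <- function(reference, incomplete, config) {
  stopifnot(inherits(config, "psdg_config"))
  pair <- align_schemas(reference, incomplete, config$unit_equivalences)
  reference <- pair$reference
  incomplete <- pair$incomplete

  unknown <- unknown_features(incomplete)
  if (length(unknown) != 1) {
    abort(sprintf(
      "Expected exactly one unknown feature, found %d (%s).",
      length(unknown), paste(unknown, collapse = ", ")
    ))
  }
  feature <- unknown
  feats_used <- c(intersect(known_features(incomplete), dataset_features(reference)), feature)
  ref_used <- select_features(reference, feats_used)

  grid <- candidate_grid(ref_used, feature, n_levels = config$n_levels)
  rconfig <- reliability_config(
    k = config$k,
    epsilon = config$epsilon %||% grid$epsilon_default,
    r_min = config$r_min,
    bands = config$bands
  )

  generated <- expand_candidates(select_features(incomplete, feats_used), grid)
  model <- fit_embedding(ref_used,
    n_neighbors = config$n_neighbors,
    min_dist = config$min_dist,
    seed = config$seed, backend = config$backend
  )
  coords_g <- project(model, materialize(generated))
  scored <- score_candidates(
    generated, coords_g,
    model$training_coords, ref_used[[feature]], rconfig
  )

  list(
    reference = reference, incomplete = incomplete, feature = feature,
    grid = grid, rconfig = rconfig, generated = generated,
    model = model, coords_g = coords_g, scored = scored,
    counts = list(
      n_reference = nrow(reference), n_incomplete = nrow(incomplete),
      m = length(grid$values), n_generated = nrow(generated)
    )
  )
}

# Assemble the validated output table: real known features, the synthetic
# value in the feature's own column, score metadata, coordinates.
build_validated <- function(stage, validated, label_tbl = NULL) {
  base <- stage$incomplete
  feats <- dataset_features(stage$incomplete)
  feats <- intersect(feats, c(known_features(base), stage$feature))
  idx <- match(validated$.row_id, base$.row_id)

  out <- tibble(
    .row_id = paste0(validated$.row_id, "#", validated$.candidate),
    .source_id = validated$.row_id
  )
  for (nm in feats) {
    out[[nm]] <- if (nm == stage$feature) validated$x_hat else base[[nm]][idx]
  }
  lab <- dataset_label(base)
  if (!is.null(lab) && !all(is.na(base[[lab]]))) out[[lab]] <- base[[lab]][idx]
  if (!is.null(label_tbl)) {
    out$.label_assigned <- label_tbl$label[match(out$.row_id, label_tbl$.row_id)]
  }
  out$r_c <- validated$r_c
  out$neighbor_mean <- validated$neighbor_mean
  out$f_disp <- validated$f_disp
  out$c1 <- validated$c1
  out$c2 <- validated$c2
  out
}

finalize_run <- function(out, stage, config, extra_counts = list()) {
  counts <- c(stage$counts, list(n_validated = nrow(out)), extra_counts)
  structure(out,
    counts = counts,
    config_hash = config_hash(unclass(config)),
    grid = stage$grid, embedding = stage$model,
    class = c("psdg_validated", class(out))
  )
}

#' Generate a partially synthetic dataset (known label, one missing feature)
#'
#' The core pipeline: align the two tables, enumerate/quantize the missing
#' feature's candidate values, expand every incomplete row over the grid,
#' project reference and candidates through the reference-trained 2D
#' embedding, score each candidate against its embedding neighborhood, and
#' keep the candidates with `r_c >= r_min`. Known feature values of every
#' output row are bit-equal to their source row: only the missing feature's
#' column is synthetic.
#'
#' @param reference A complete `psdg_dataset`.
#' @param incomplete A `psdg_dataset` missing exactly one feature.
#' @param config A [psdg_config()].
#' @return A `psdg_validated` tibble (one row per validated candidate) with
#'   columns: composite `.row_id`, `.source_id`, the features, the label
#'   when present, `r_c`, `neighbor_mean`, `f_disp`, `c1`, `c2`. Stage
#'   counts, the grid and the fitted embedding ride along as attributes.
#' @export
run_case1 <- function(reference, incomplete, config) {
  stage <- pipeline_score(reference, incomplete, config)
  validated <- filter_validated(stage$scored, config$r_min)
  finalize_run(build_validated(stage, validated), stage, config)
}

#' Assign class labels to a complete but unlabeled dataset
#'
#' All features are known but the label is not: the rows are projected
#' through the reference-trained embedding (no candidate expansion), and
#' each projected point falling inside a density-validated cluster area
#' receives that cluster's label. Rows outside every area are excluded.
#'
#' @param reference A complete, labeled `psdg_dataset`.
#' @param incomplete A `psdg_dataset` with all features known and no label.
#' @param config A [psdg_config()].
#' @return A `psdg_validated` tibble of the label-assigned rows, with a
#'   `.label_assigned` column and the projected coordinates.
#' @export
run_case0 <- function(reference, incomplete, config) {
  lab <- dataset_label(reference)
  if (is.null(lab)) abort("run_case0() needs a labeled reference.")
  if (length(unknown_features(incomplete)) != 0) {
    abort("run_case0() expects all features known in the incomplete dataset.")
  }
  pair <- align_schemas(reference, incomplete, config$unit_equivalences)
  reference <- pair$reference
  incomplete <- pair$incomplete
  feats <- intersect(dataset_features(incomplete), dataset_features(reference))

  ref_used <- select_features(reference, feats)
  model <- fit_embedding(ref_used,
    n_neighbors = config$n_neighbors, min_dist = config$min_dist,
    seed = config$seed, backend = config$backend
  )
  clusters <- fit_clusters(
    model$training_coords, reference[[lab]],
    config$density_threshold,
    r_start = config$r_start, r_step = config$r_step, r_max = config$r_max,
    density = config$density
  )
  coords <- project(model, select_features(incomplete, feats))
  asg <- assign_labels(coords, clusters)
  keep <- !is.na(asg$label)

  out <- tibble(.row_id = incomplete$.row_id[keep], .source_id = incomplete$.row_id[keep])
  for (nm in feats) out[[nm]] <- incomplete[[nm]][keep]
  out$.label_assigned <- asg$label[keep]
  out$c1 <- coords$c1[keep]
  out$c2 <- coords$c2[keep]
  structure(out,
    counts = list(
      n_reference = nrow(reference), n_incomplete = nrow(incomplete),
      n_assigned = nrow(out)
    ),
    config_hash = config_hash(unclass(config)),
    clusters = clusters, embedding = model,
    class = c("psdg_validated", class(out))
  )
}

#' Generate both a missing feature and the missing label
#'
#' Runs the reliability pipeline first (as in [run_case1()]), then assigns
#' labels to the surviving candidates through density-validated cluster
#' areas; candidates failing either filter are dropped. The output is a
#' subset of the [run_case1()] output restricted to label-assigned rows.
#'
#' @inheritParams run_case1
#' @return A `psdg_validated` tibble with both the synthetic feature value
#'   and a `.label_assigned` column.
#' @export
run_case2 <- function(reference, incomplete, config) {
  lab <- dataset_label(reference)
  if (is.null(lab)) abort("run_case2() needs a labeled reference.")
  stage <- pipeline_score(reference, incomplete, config)
  validated <- filter_validated(stage$scored, config$r_min)

  clusters <- fit_clusters(
    stage$model$training_coords, stage$reference[[lab]],
    config$density_threshold,
    r_start = config$r_start, r_step = config$r_step, r_max = config$r_max,
    density = config$density
  )
  vcoords <- tibble(
    .row_id = paste0(validated$.row_id, "#", validated$.candidate),
    c1 = validated$c1, c2 = validated$c2
  )
  asg <- assign_labels(vcoords, clusters)
  keep <- !is.na(asg$label)
  out <- build_validated(stage, validated[keep, ], label_tbl = asg[keep, ])
  out <- finalize_run(out, stage, config,
    extra_counts = list(n_label_assigned = sum(keep))
  )
  attr(out, "clusters") <- clusters
  out
}

#' Iterative fully synthetic generation
#'
#' Generates several missing features one at a time. At each iteration the
#' next target feature is *added to the reference feature set*, the
#' embedding is refitted on the enlarged set, and the current dataset
#' (whose previously generated features now count as known) is expanded,
#' scored and filtered. Because multiple candidates per row can validate,
#' the row count may grow at every iteration. When the incomplete dataset
#' also lacks the label, cluster validation on the final embedding assigns
#' one.
#'
#' The default feature order is descending absolute correlation with the
#' label, computed on the reference.
#'
#' @inheritParams run_case1
#' @return A `psdg_validated` tibble of the final iteration, with an
#'   `iterations` attribute recording per-iteration counts.
#' @export
run_full_synthesis <- function(reference, incomplete, config) {
  targets <- config$feature_order %||% default_feature_order(reference, incomplete)
  bad <- setdiff(targets, dataset_features(reference))
  if (length(bad)) {
    abort(sprintf("feature_order names absent from reference: %s", paste(bad, collapse = ", ")))
  }
  if (length(targets) == 0) {
    return(incomplete)
  }

  sch_ref <- dataset_schema(reference)
  lab <- dataset_label(incomplete)
  if (!is.null(lab) && all(is.na(incomplete[[lab]]))) lab <- NULL
  known_now <- known_features(incomplete)
  cur_tbl <- as_tibble(as.data.frame(incomplete))[c(".row_id", known_now, lab)]
  iterations <- list()
  last <- NULL

  for (t_feat in targets) {
    feats_used <- c(known_now, t_feat)
    sch_cur <- sch_ref[match(feats_used, sch_ref$name), ]
    class(sch_cur) <- class(sch_ref)

    cur_tbl[[t_feat]] <- NA_real_
    cur_ds <- psdg_dataset(cur_tbl, sch_cur, label_name = lab, id_col = ".row_id")

    step <- run_case1(reference, cur_ds, config)
    iterations[[t_feat]] <- attr(step, "counts")
    last <- step
    # validated rows become the next iteration's input
    known_now <- feats_used
    cur_tbl <- as_tibble(as.data.frame(step))[c(".row_id", known_now, lab)]
  }

  out <- last
  # label assignment on the final embedding when the label is missing
  ref_lab <- dataset_label(reference)
  need_label <- !is.null(ref_lab) && (is.null(lab) || all(is.na(incomplete[[lab]])))
  if (need_label) {
    model <- attr(last, "embedding")
    clusters <- fit_clusters(
      model$training_coords, reference[[ref_lab]],
      config$density_threshold,
      r_start = config$r_start, r_step = config$r_step, r_max = config$r_max,
      density = config$density
    )
    asg <- assign_labels(tibble(.row_id = out$.row_id, c1 = out$c1, c2 = out$c2), clusters)
    keep <- !is.na(asg$label)
    out <- out[keep, ]
    out$.label_assigned <- asg$label[keep]
    attr(out, "clusters") <- clusters
  }
  attr(out, "iterations") <- iterations
  out
}

default_feature_order <- function(reference, incomplete) {
  lab <- dataset_label(reference)
  missing_feats <- setdiff(dataset_features(reference), known_features(incomplete))
  if (is.null(lab) || length(missing_feats) == 0) {
    return(missing_feats)
  }
  y <- reference[[lab]]
  y_num <- suppressWarnings(as.numeric(y))
  if (anyNA(y_num)) y_num <- as.numeric(factor(y, levels = sort(unique(y))))
  cors <- vapply(missing_feats, function(nm) {
    stats::cor(reference[[nm]], y_num)
  }, numeric(1))
  missing_feats[order(-abs(cors), missing_feats, method = "radix")]
}

#' Impute missing cells across arbitrary missingness patterns
#'
#' Rows are partitioned by their missing-feature pattern; each subset is run
#' through the reliability pipeline per missing feature (using only that
#' pattern's observed features), and each missing cell receives the single
#' validated candidate with the highest reliability score (ties: smallest
#' disparity, then smallest candidate value). Cells with no validated
#' candidate stay missing and are reported in the `unimputed` attribute.
#' With `top_n > 1` the per-cell runner-up candidates are additionally
#' returned in the `mi_candidates` attribute, as raw material for a
#' multiple-imputation style analysis.
#'
#' @param incomplete A `psdg_dataset` built with `strict = FALSE` (mixed
#'   missingness allowed).
#' @param reference A complete `psdg_dataset`. To impute a table from its
#'   own complete rows, pass that complete-row subset as the reference.
#' @param config A [psdg_config()].
#' @param top_n Candidates retained per cell (1 = single imputation).
#' @return The incomplete dataset with missing cells filled where possible.
#' @export
run_imputation <- function(incomplete, reference, config, top_n = 1L) {
  feats <- dataset_features(incomplete)
  na_mat <- is.na(as.matrix(as.data.frame(incomplete)[feats]))
  pattern <- apply(na_mat, 1, function(r) paste(feats[r], collapse = "|"))

  out <- as_tibble(as.data.frame(incomplete))
  unimputed <- list()
  mi_candidates <- list()

  for (pat in sort(setdiff(unique(pattern), ""))) {
    rows <- which(pattern == pat)
    missing_feats <- strsplit(pat, "|", fixed = TRUE)[[1]]
    observed <- setdiff(feats, missing_feats)

    for (f in missing_feats) {
      feats_used <- c(observed, f)
      sch <- dataset_schema(incomplete)
      sch_sub <- sch[match(feats_used, sch$name), ]
      class(sch_sub) <- class(sch)
      sub_df <- out[rows, c(".row_id", feats_used)]
      sub <- psdg_dataset(sub_df, sch_sub, id_col = ".row_id")
      ref_sub <- select_features(reference, feats_used)

      stage <- pipeline_score(ref_sub, sub, config)
      validated <- filter_validated(stage$scored, config$r_min)
      if (nrow(validated)) {
        ranked <- validated |>
          dplyr::arrange(
            .data$.row_id, dplyr::desc(.data$r_c),
            .data$f_disp, .data$x_hat
          ) |>
          dplyr::group_by(.data$.row_id)
        best <- dplyr::slice_head(ranked, n = 1L) |> dplyr::ungroup()
        if (top_n > 1L) {
          mi_candidates[[paste(pat, f)]] <- dplyr::slice_head(ranked, n = top_n) |>
            dplyr::ungroup() |>
            dplyr::mutate(feature = f, .before = 1)
        }
        fill <- best$x_hat[match(out$.row_id[rows], best$.row_id)]
        out[[f]][rows] <- ifelse(is.na(fill), out[[f]][rows], fill)
      }
      still <- rows[is.na(out[[f]][rows])]
      if (length(still)) {
        unimputed[[paste(pat, f)]] <- tibble(.row_id = out$.row_id[still], feature = f)
      }
    }
  }

  res <- psdg_dataset(out, dataset_schema(incomplete),
    label_name = dataset_label(incomplete), id_col = ".row_id", strict = FALSE
  )
  attr(res, "unimputed") <- if (length(unimputed)) dplyr::bind_rows(unimputed) else tibble(.row_id = character(), feature = character())
  if (top_n > 1L) attr(res, "mi_candidates") <- dplyr::bind_rows(mi_candidates)
  attr(res, "config_hash") <- config_hash(unclass(config))
  res
}
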