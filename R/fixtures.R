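#' Specify a synthetic labeled fixture
#'
#' Describes a generator for tables with the statistical structure the
#' generation method assumes: each class is a Gaussian component in a 2D
#' latent space (components `class_separation` within-class standard
#' deviations apart), observed features are full-rank affine maps of the
#' latent coordinates plus noise, and one designated *hidden* feature is an
#' affine function of the latent position plus noise, clipped and rounded
#' to its declared range/kind. Clusters therefore separate in embedding
#' space and the hidden feature varies smoothly across it — the regime in
#' which neighborhood-mean validation is informative.
#'
#' The defaults emulate a prostate-cancer-registry-like table: 1500 rows,
#' three features (an age-like integer hidden feature on 35–92 plus two
#' positive continuous markers), two classes, so a five-group rotation
#' yields groups of exactly 300.
#'
#' @param n_rows Number of rows.
#' @param n_features Total number of features including the hidden one
#'   (3–6).
#' @param n_classes Number of classes (label column `"class"`).
#' @param class_separation Distance between adjacent class means in units
#'   of the within-class standard deviation.
#' @param hidden_feature Name of the hidden feature.
#' @param hidden_kind `"integer"` or `"continuous"`.
#' @param hidden_range Length-2 numeric range of the hidden feature.
#' @param hidden_noise_sd Noise added to the hidden feature, in its own
#'   units.
#' @param feature_noise_sd Noise added to each observed feature, relative
#'   to its latent signal scale.
#' @param seed Integer seed; the fixture is a pure function of
#'   `(spec, seed)`.
#' @return A `psdg_fixture_spec` list.
#' @export
fixture_spec <- function(n_rows = 1500L, n_features = 3L, n_classes = 2L,
                         class_separation = 4, hidden_feature = "age",
                         hidden_kind = c("integer", "continuous"),
                         hidden_range = c(35, 92), hidden_noise_sd = 1.5,
                         feature_noise_sd = 0.15, seed = 1L) {
  hidden_kind <- match.arg(hidden_kind)
  if (n_features < 3 || n_features > 6) abort("`n_features` must be between 3 and 6.")
  structure(
    list(
      n_rows = assert_scalar_int(n_rows, "n_rows"),
      n_features = as.integer(n_features),
      n_classes = assert_scalar_int(n_classes, "n_classes"),
      class_separation = class_separation,
      hidden_feature = hidden_feature, hidden_kind = hidden_kind,
      hidden_range = as.numeric(hidden_range),
      hidden_noise_sd = hidden_noise_sd,
      feature_noise_sd = feature_noise_sd,
      seed = assert_scalar_int(seed, "seed", min = 0L)
    ),
    class = "psdg_fixture_spec"
  )
}

#' Generate a complete labeled reference table from a fixture spec
#'
#' @param spec A [fixture_spec()].
#' @return A complete `psdg_dataset` with label column `"class"`; the
#'   latent coordinates are attached as attribute `"latent"` for
#'   diagnostics.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "psdg_fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  n <- spec$n_rows
  cls <- sort(rep_len(seq_len(spec$n_classes) - 1L, n)) # balanced classes
  mu <- cbind((cls %% 2) * spec$class_separation, (cls %/% 2) * spec$class_separation)
  z <- mu + matrix(stats::rnorm(2 * n), n, 2)

  # hidden feature: affine in the latent coordinates, spanning its range
  w <- c(1, 0.6) / sqrt(1 + 0.36)
  u <- as.vector(z %*% w)
  span_lo <- sum(pmin(w * 0, w * spec$class_separation)) - 3
  span_hi <- sum(pmax(w * 0, w * spec$class_separation)) + 3
  lo <- spec$hidden_range[1]
  hi <- spec$hidden_range[2]
  hidden <- lo + (hi - lo) * (u - span_lo) / (span_hi - span_lo) +
    stats::rnorm(n, sd = spec$hidden_noise_sd)
  hidden <- pmin(pmax(hidden, lo), hi)
  if (spec$hidden_kind == "integer") hidden <- round(hidden)

  # observed features: full-rank affine maps of the latent position
  others <- generic_feature_defs(spec$n_features - 1L)
  cols <- list()
  cols[[spec$hidden_feature]] <- hidden
  for (i in seq_along(others)) {
    def <- others[[i]]
    signal <- def$offset + z %*% def$weights
    noise_sd <- spec$feature_noise_sd * stats::sd(signal)
    v <- as.vector(signal) + stats::rnorm(n, sd = max(noise_sd, 1e-6))
    cols[[def$name]] <- pmax(v, def$floor)
  }

  specs <- c(
    list(feature_spec(
      spec$hidden_feature, spec$hidden_kind,
      unit = if (spec$hidden_feature == "age") "years" else NA_character_
    )),
    lapply(others, function(def) feature_spec(def$name, "continuous", unit = def$unit))
  )
  sch <- psdg_schema(specs)

  df <- as_tibble(cols)
  df$class <- as.character(cls)
  out <- psdg_dataset(df, sch, label_name = "class")
  attr(out, "latent") <- z
  out
}

# Deterministic affine feature definitions (psa/volume-like, then generic).
generic_feature_defs <- function(k) {
  base <- list(
    list(name = "psa", unit = "ng/mL", offset = 8, weights = c(2.0, -1.0), floor = 0.1),
    list(name = "volume", unit = "mL", offset = 45, weights = c(2.5, 3.0), floor = 1),
    list(name = "marker1", unit = NA_character_, offset = 20, weights = c(-1.5, 2.0), floor = -Inf),
    list(name = "marker2", unit = NA_character_, offset = 5, weights = c(1.0, 1.5), floor = -Inf),
    list(name = "marker3", unit = NA_character_, offset = 0, weights = c(-2.0, -0.5), floor = -Inf)
  )
  base[seq_len(k)]
}

#' Split a fixture into reference / incomplete / ground truth
#'
#' Stages the two-institution scenario: a disjoint split into a (typically
#' small) complete reference and a larger incomplete table whose listed
#' features — and optionally the label — are blanked, with the blanked
#' truth retained separately for evaluation.
#'
#' @param spec A [fixture_spec()] (the table is generated from it).
#' @param reference_fraction Fraction of rows forming the reference.
#' @param drop_features Character vector of features to blank in the
#'   incomplete part.
#' @param drop_label Whether to blank the label too.
#' @return A list `(reference, incomplete, truth)`; `truth` holds
#'   `.row_id`, the blanked feature columns, and the label.
#' @export
make_split <- function(spec, reference_fraction = 0.2,
                       drop_features = spec$hidden_feature,
                       drop_label = FALSE) {
  full <- make_reference(spec)
  n <- nrow(full)
  n_ref <- round(reference_fraction * n)
  if (n_ref < 2 || n_ref >= n) abort("reference_fraction leaves too few rows on one side.")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  ref_idx <- sort(sample.int(n, n_ref))
  inc_idx <- setdiff(seq_len(n), ref_idx)

  sch <- dataset_schema(full)
  tbl <- as_tibble(as.data.frame(full))
  ref <- psdg_dataset(tbl[ref_idx, ], sch, label_name = "class", id_col = ".row_id")

  inc_tbl <- tbl[inc_idx, ]
  truth <- inc_tbl[c(".row_id", drop_features, "class")]
  for (f in drop_features) inc_tbl[[f]] <- NA_real_
  label_name <- "class"
  if (drop_label) {
    inc_tbl$class <- NULL
    label_name <- NULL
  }
  inc <- psdg_dataset(inc_tbl, sch, label_name = label_name, id_col = ".row_id")
  list(reference = ref, incomplete = inc, truth = truth)
}

#' A hand-checkable worked example
#'
#' A fixed micro-instance whose neighborhood means and reliability scores
#' can be verified by hand: four reference points on the unit square, all
#' carrying feature value 10, and seven candidate points at the square's
#' center whose trial values sit 0.5, 1.5, ..., 6.5 above the neighborhood
#' mean — one per disparity band at `epsilon = 1` (the last falls beyond
#' the final band and scores 0). The same tables ship as plain CSV under
#' `inst/extdata/` for use from the command line.
#'
#' @return A list with `reference_coords`, `reference_values`,
#'   `candidates` (`.row_id`, `c1`, `c2`, `x_hat`), the scoring `config`,
#'   and the `expected` scored table.
#' @export
make_worked_example <- function() {
  reference_coords <- tibble(
    .row_id = c("a", "b", "c", "d"),
    c1 = c(0, 1, 0, 1), c2 = c(0, 0, 1, 1)
  )
  reference_values <- c(10, 10, 10, 10)
  offsets <- seq(0.5, 6.5, by = 1)
  candidates <- tibble(
    .row_id = sprintf("q%d", seq_along(offsets)),
    c1 = 0.5, c2 = 0.5, x_hat = 10 + offsets
  )
  config <- reliability_config(k = 4L, epsilon = 1, r_min = 1)
  expected <- tibble(
    .row_id = candidates$.row_id,
    x_hat = candidates$x_hat,
    neighbor_mean = 10,
    f_disp = offsets,
    r_c = c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0)
  )
  list(
    reference_coords = reference_coords,
    reference_values = reference_values,
    candidates = candidates,
    config = config,
    expected = expected
  )
}
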