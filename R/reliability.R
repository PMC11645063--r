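#' Reliability scoring configuration
#'
#' Bundles the neighbor count `k`, the disparity band width `epsilon`
#' (always on the *original* feature scale — embeddings are trained on
#' normalized features, but the disparity between a candidate value and its
#' neighborhood mean is a quantity in the feature's own units), the
#' validation threshold `r_min`, and the band table.
#'
#' The default band table maps disparity `f` to a score in 0.1 steps:
#' `f <= eps -> 1`, `eps < f <= 2 eps -> 0.9`, ... , `5 eps < f <= 6 eps ->
#' 0.5`, and `f > 6 eps -> 0` (a disparity beyond six band widths can never
#' validate). Boundaries are closed on the right.
#'
#' @param k Number of reference neighbors for the neighborhood mean.
#' @param epsilon Band width on the original feature scale.
#' @param r_min Minimum score for validation, typically in `[0.5, 1]`.
#' @param bands A tibble `(upper, score)` of band upper bounds in units of
#'   `epsilon`, strictly increasing in `upper` and strictly decreasing in
#'   `score`; the default is `reliability_bands()`.
#' @return A `psdg_reliability_config` list.
#' @export
reliability_config <- function(k = 10L, epsilon = 1, r_min = 1,
                               bands = reliability_bands()) {
  k <- assert_scalar_int(k, "k")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    abort("`epsilon` must be a single positive number.")
  }
  if (!is.numeric(r_min) || length(r_min) != 1 || r_min < 0 || r_min > 1) {
    abort("`r_min` must be in [0, 1].")
  }
  stopifnot(
    is.data.frame(bands), all(c("upper", "score") %in% names(bands)),
    !is.unsorted(bands$upper, strictly = TRUE),
    !is.unsorted(rev(bands$score), strictly = TRUE)
  )
  structure(
    list(k = k, epsilon = epsilon, r_min = r_min, bands = bands),
    class = "psdg_reliability_config"
  )
}

#' @rdname reliability_config
#' @export
reliability_bands <- function() {
  tibble(upper = 1:6, score = c(1, 0.9, 0.8, 0.7, 0.6, 0.5))
}

#' Mean of a reference feature over embedding nearest neighbors
#'
#' For each query point, finds its `k` nearest reference points in the 2D
#' embedding (Euclidean distance) and returns the arithmetic mean of the
#' reference feature over them. Ties at the k-th distance are broken by
#' ascending reference identifier, so results are deterministic.
#'
#' @param reference_coords Coordinates tibble `(.row_id, c1, c2)` of the
#'   reference embedding.
#' @param reference_values Numeric vector of the feature's original-scale
#'   values, aligned with `reference_coords` rows.
#' @param query_coords Coordinates tibble of the query points.
#' @param k Neighbor count, `1 <= k <=` number of reference points.
#' @return A tibble `(.row_id, neighbor_mean)` aligned with the queries.
#' @export
knn_mean <- function(reference_coords, reference_values, query_coords, k) {
  k <- assert_scalar_int(k, "k")
  nr <- nrow(reference_coords)
  if (nr == 0) abort("Empty reference coordinates.")
  if (k > nr) abort(sprintf("k = %d exceeds the %d reference points.", k, nr))
  if (length(reference_values) != nr) {
    abort("reference_values must align with reference_coords.")
  }
  # Resolve ties at the k-th distance deterministically: pre-sort the
  # reference by id so that among equal distances the smaller id wins.
  ord <- stable_order(reference_coords$.row_id)
  rc1 <- reference_coords$c1[ord]
  rc2 <- reference_coords$c2[ord]
  rv <- reference_values[ord]

  n <- nrow(query_coords)
  q1 <- query_coords$c1
  q2 <- query_coords$c2
  means <- numeric(n)
  chunk <- max(1L, floor(5e6 / nr))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    # plain elementwise differences: distances (hence ties) are exactly the
    # floats a direct per-pair computation would produce
    d <- sqrt(outer(q1[s:e], rc1, "-")^2 + outer(q2[s:e], rc2, "-")^2)
    means[s:e] <- apply(d, 1, function(row) {
      nb <- stable_order(row)[seq_len(k)] # radix order is stable: id order kept on ties
      mean(rv[nb])
    })
  }
  tibble(.row_id = query_coords$.row_id, neighbor_mean = means)
}

#' Band a feature disparity into a reliability score
#'
#' Piecewise-constant scoring of the disparity between a candidate value and
#' its neighborhood mean, in multiples of `epsilon`. Vectorized over
#' `f_disp`. Invariant under joint rescaling of `(f_disp, epsilon)`.
#'
#' @param f_disp Nonnegative disparity value(s) on the original feature
#'   scale.
#' @param config A [reliability_config()] (or anything with `epsilon` and
#'   `bands`).
#' @return Numeric score(s) in `{1, 0.9, ..., 0.5, 0}`.
#' @export
#' @examples
#' cfg <- reliability_config(epsilon = 1)
#' score_disparity(c(0.4, 2.5, 7), cfg) # 1, 0.8, 0
score_disparity <- function(f_disp, config) {
  if (any(f_disp < 0, na.rm = TRUE)) abort("Disparity must be nonnegative.")
  uppers <- config$bands$upper * config$epsilon
  scores <- config$bands$score
  idx <- findInterval(f_disp, uppers, left.open = TRUE) + 1L # closed on the right
  out <- c(scores, 0)[idx]
  out[is.na(f_disp)] <- NA_real_
  out
}

#' Score every expanded candidate
#'
#' Composes [knn_mean()] and [score_disparity()]: each candidate's trial
#' value is compared with the mean of the feature over its `k` nearest
#' reference points in the embedding, and the absolute disparity (original
#' feature scale) is banded into a reliability score.
#'
#' @param generated A `psdg_generated` from [expand_candidates()].
#' @param coords_g Coordinates of the materialized candidates (ids
#'   `"<row_id>#<candidate>"`, aligned with `generated`).
#' @param reference_coords,reference_values Reference embedding coordinates
#'   and the feature's original-scale reference values.
#' @param config A [reliability_config()].
#' @return A tibble of scored candidates: `(.row_id, .candidate, x_hat, c1,
#'   c2, neighbor_mean, f_disp, r_c)`.
#' @export
score_candidates <- function(generated, coords_g, reference_coords,
                             reference_values, config) {
  expected_ids <- paste0(generated$.row_id, "#", generated$.candidate)
  if (!identical(as.character(coords_g$.row_id), expected_ids)) {
    abort("coords_g ids are not aligned with the generated candidates.")
  }
  nm <- knn_mean(reference_coords, reference_values, coords_g, config$k)
  f_disp <- abs(generated$x_hat - nm$neighbor_mean)
  tibble(
    .row_id = generated$.row_id,
    .candidate = generated$.candidate,
    x_hat = generated$x_hat,
    c1 = coords_g$c1, c2 = coords_g$c2,
    neighbor_mean = nm$neighbor_mean,
    f_disp = f_disp,
    r_c = score_disparity(f_disp, config)
  )
}

#' Keep candidates meeting the reliability threshold
#'
#' Returns the validated subset `D_v`: candidates with `r_c >= r_min`.
#' Multiple candidates of one source row may validate simultaneously; no
#' deduplication happens here — that is what turns validated candidates into
#' synthetic data augmentation rather than single imputation.
#'
#' @param scored Output of [score_candidates()].
#' @param r_min Minimum reliability score.
#' @return The validated subset, same columns as `scored`.
#' @export
filter_validated <- function(scored, r_min) {
  dplyr::filter(scored, .data$r_c >= r_min, .data$r_c > 0)
}
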