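#' Expand an incomplete dataset over a candidate grid
#'
#' Builds the generated dataset: the Cartesian product of the incomplete
#' rows with every candidate value of the missing feature, so that each of
#' the `N_i` source rows yields `M` candidate rows (`|D_g| = N_i * M`).
#' Known features are copied verbatim; ordering is deterministic (row-major
#' by source row, then ascending candidate value), so downstream outputs are
#' reproducible byte-for-byte.
#'
#' @param incomplete A `psdg_dataset` whose single unknown feature matches
#'   `grid$feature`.
#' @param grid A `psdg_grid`.
#' @return A `psdg_generated` object: a tibble `(.row_id, .candidate,
#'   x_hat)` with the source dataset and grid attached as attributes.
#' @export
#' @examples
#' sch <- psdg_schema(
#'   feature_spec("age", "integer", unit = "years"),
#'   feature_spec("psa", "continuous")
#' )
#' ref <- psdg_dataset(data.frame(age = c(40, 42), psa = c(4, 6)), sch)
#' inc <- psdg_dataset(data.frame(age = NA_real_, psa = c(5, 7)), sch)
#' gen <- expand_candidates(inc, enumerate_values(ref, "age"))
#' nrow(gen) # 2 rows x 3 ages = 6
expand_candidates <- function(incomplete, grid) {
  stopifnot(inherits(grid, "psdg_grid"))
  unknown <- unknown_features(incomplete)
  if (!identical(unknown, grid$feature)) {
    abort(sprintf(
      "Grid is for '%s' but the incomplete dataset's unknown feature set is {%s}.",
      grid$feature, paste(unknown, collapse = ", ")
    ))
  }
  if (length(grid$values) == 0) abort("Empty candidate grid.")

  m <- length(grid$values)
  out <- tibble(
    .row_id = rep(incomplete$.row_id, each = m),
    .candidate = rep(seq_len(m), times = nrow(incomplete)),
    x_hat = rep(grid$values, times = nrow(incomplete))
  )
  structure(out,
    base = incomplete, grid = grid,
    class = c("psdg_generated", class(out))
  )
}

#' Materialize generated candidates as a full-width table
#'
#' Joins each candidate back to its source row's known features, producing a
#' table with all `d` features per candidate row (`d - 1` real plus one
#' synthetic), ready for projection. Composite identifiers are
#' `"<row_id>#<candidate_index>"`.
#'
#' @param generated A `psdg_generated` from [expand_candidates()].
#' @return A tibble with columns `.row_id` (composite), `.source_id`,
#'   `.candidate`, every feature, and the label column when present.
#' @export
materialize <- function(generated) {
  base <- attr(generated, "base")
  grid <- attr(generated, "grid")
  feats <- dataset_features(base)
  known <- setdiff(feats, grid$feature)
  idx <- match(generated$.row_id, base$.row_id)

  out <- tibble(
    .row_id = paste0(generated$.row_id, "#", generated$.candidate),
    .source_id = generated$.row_id,
    .candidate = generated$.candidate
  )
  for (nm in feats) {
    out[[nm]] <- if (nm == grid$feature) generated$x_hat else base[[nm]][idx]
  }
  lab <- dataset_label(base)
  if (!is.null(lab)) out[[lab]] <- base[[lab]][idx]
  out
}
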