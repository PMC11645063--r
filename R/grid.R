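#' Candidate value grids for a missing feature
#'
#' The candidate grid is the finite set of M values tried for a missing
#' feature when expanding an incomplete dataset. Non-continuous features are
#' enumerated; continuous features are quantized into M uniform intervals
#' whose midpoints form the grid. Each grid also carries a default disparity
#' band width `epsilon` on the original feature scale: 1 for integer and
#' ordinal kinds, half the minimum gap between encoded levels for
#' categorical/binary kinds, and the bin width for quantized features.
#'
#' @param reference A complete `psdg_dataset` supplying the observed range.
#' @param feature Name of the feature to build the grid for.
#' @param n_levels Number of quantization levels (continuous features only).
#'
#' @return A `psdg_grid`: a list with `feature`, numeric `values` (sorted,
#'   duplicate-free), `epsilon_default`, and `origin`
#'   (`"enumerated"`/`"quantized"`).
#' @export
#' @examples
#' sch <- psdg_schema(feature_spec("age", "integer", unit = "years"))
#' ref <- psdg_dataset(data.frame(age = c(35, 50, 92)), sch)
#' enumerate_values(ref, "age") # 58 values, 35..92
enumerate_values <- function(reference, feature) {
  spec <- schema_feature(dataset_schema(reference), feature)
  if (spec$kind == "continuous") {
    abort(sprintf("Feature '%s' is continuous; use quantize_values().", feature))
  }
  v <- reference[[feature]]
  v <- v[!is.na(v)]
  if (length(v) == 0) abort(sprintf("Feature '%s' has no observed values.", feature))

  if (spec$kind == "integer") {
    values <- seq(min(v), max(v))
    eps <- 1
  } else {
    values <- sort(unique(v))
    if (spec$kind == "ordinal") {
      eps <- 1
    } else {
      lv <- spec$levels[[1]]
      eps <- if (length(lv) >= 2) min(diff(lv)) / 2 else 1
    }
  }
  new_grid(feature, values, eps, "enumerated")
}

#' @rdname enumerate_values
#' @export
quantize_values <- function(reference, feature, n_levels) {
  spec <- schema_feature(dataset_schema(reference), feature)
  if (spec$kind != "continuous") {
    abort(sprintf("Feature '%s' is not continuous; use enumerate_values().", feature))
  }
  n_levels <- assert_scalar_int(n_levels, "n_levels")
  v <- reference[[feature]]
  v <- v[!is.na(v)]
  if (length(v) == 0) abort(sprintf("Feature '%s' has no observed values.", feature))
  lo <- min(v)
  hi <- max(v)
  if (lo == hi && n_levels > 1) {
    abort(sprintf("Degenerate range [%s, %s] for '%s' with n_levels > 1.", lo, hi, feature))
  }
  width <- (hi - lo) / n_levels
  mids <- lo + width * (seq_len(n_levels) - 0.5)
  new_grid(feature, mids, if (width > 0) width else 1, "quantized")
}

#' Build the grid appropriate to a feature's kind
#'
#' Dispatches to [enumerate_values()] for non-continuous kinds and to
#' [quantize_values()] for continuous kinds.
#'
#' @inheritParams enumerate_values
#' @param n_levels Quantization levels used when the feature is continuous.
#' @export
candidate_grid <- function(reference, feature, n_levels = 10L) {
  spec <- schema_feature(dataset_schema(reference), feature)
  if (spec$kind == "continuous") {
    quantize_values(reference, feature, n_levels)
  } else {
    enumerate_values(reference, feature)
  }
}

new_grid <- function(feature, values, epsilon_default, origin) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, !anyDuplicated(values), !is.unsorted(values))
  structure(
    list(
      feature = feature, values = values,
      epsilon_default = epsilon_default, origin = origin
    ),
    class = "psdg_grid"
  )
}

#' @export
print.psdg_grid <- function(x, ...) {
  cat(sprintf(
    "<psdg_grid> feature '%s': M = %d %s values in [%s, %s], epsilon = %s\n",
    x$feature, length(x$values), x$origin,
    format(min(x$values)), format(max(x$values)), format(x$epsilon_default)
  ))
  invisible(x)
}

# Map arbitrary values onto the nearest grid value (ties -> smaller value).
snap_to_grid <- function(x, grid) {
  vals <- grid$values
  idx <- vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    d <- abs(vals - v)
    which(d == min(d))[1]
  }, integer(1))
  vals[idx]
}
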