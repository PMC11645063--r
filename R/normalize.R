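#' Fit a standard-scaling normalizer on a complete reference dataset
#'
#' Per-feature location is the sample mean and scale is the population
#' (divide-by-N) standard deviation, so transforming the fitting reference
#' yields exactly mean 0 and unit standard deviation per column. Constant
#' columns have zero scale and are rejected.
#'
#' @param reference A complete `psdg_dataset` (no unknown feature).
#' @return A tibble (feature, center, scale) with class `psdg_normalizer`.
#' @export
#' @examples
#' sch <- psdg_schema(feature_spec("x", "continuous"))
#' ref <- psdg_dataset(data.frame(x = c(1, 2, 3)), sch)
#' fit_normalizer(ref) # center 2, scale sqrt(2/3)
fit_normalizer <- function(reference) {
  feats <- dataset_features(reference)
  if (length(unknown_features(reference)) > 0) {
    abort("fit_normalizer() requires a complete reference (no unknown feature).")
  }
  stats <- purrr::map_dfr(feats, function(nm) {
    v <- reference[[nm]]
    if (anyNA(v)) abort(sprintf("Column '%s' contains missing values.", nm))
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    tibble(feature = nm, center = mu, scale = sdev)
  })
  bad <- stats$feature[stats$scale <= 0]
  if (length(bad)) {
    abort(sprintf("Constant column(s) cannot be scaled: %s", paste(bad, collapse = ", ")))
  }
  structure(stats, class = c("psdg_normalizer", class(stats)))
}

#' Apply (or invert) a fitted normalizer
#'
#' `apply_normalizer()` maps each feature value to
#' `(value - center) / scale`; `invert_normalizer()` is its exact inverse.
#' Missing markers pass through unchanged. Columns of `data` that the
#' normalizer does not cover are an error; extra normalizer entries are
#' ignored.
#'
#' @param data A data frame whose feature columns appear in `stats`.
#' @param stats A `psdg_normalizer`.
#' @param features Columns to transform; defaults to every `stats` feature
#'   present in `data`.
#' @return `data` with the selected columns transformed.
#' @export
apply_normalizer <- function(data, stats, features = NULL) {
  transform_normalizer(data, stats, features, invert = FALSE)
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(data, stats, features = NULL) {
  transform_normalizer(data, stats, features, invert = TRUE)
}

transform_normalizer <- function(data, stats, features, invert) {
  if (is.null(features)) features <- intersect(stats$feature, names(data))
  missing_ <- setdiff(features, stats$feature)
  if (length(missing_)) {
    abort(sprintf("No normalizer statistics for: %s", paste(missing_, collapse = ", ")))
  }
  for (nm in features) {
    i <- match(nm, stats$feature)
    data[[nm]] <- if (invert) {
      data[[nm]] * stats$scale[i] + stats$center[i]
    } else {
      (data[[nm]] - stats$center[i]) / stats$scale[i]
    }
  }
  data
}
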