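#' Two-party reliability scoring over file exchange
#'
#' In the two-institution workflow, the reference holder (H1) owns the
#' trained embedding, the reference coordinates and the reference values of
#' the feature being generated, while the incomplete-data holder (H2) owns
#' the candidate values. After H2 transmits the candidate coordinates
#' (see [export_coords()]), scoring can be completed two ways with identical
#' results:
#'
#' * **Option 1** — H2 additionally shares the candidate values `(id,
#'   x_hat)`; H1 computes disparities and returns `(id, r_c)`.
#'   Use [exchange_score_option1()].
#' * **Option 2** — H1 shares the per-candidate neighborhood means `(id,
#'   neighbor_mean)` (via [exchange_neighbor_means()]); H2 computes
#'   disparities and scores locally with [exchange_score_option2()].
#'
#' All exchange artifacts are two-column CSV files written with full float
#' precision, so the two routes agree bit-for-bit.
#'
#' @param coords_path Path to the candidate coordinates CSV exported by H2.
#' @param values_path Path to the `(id, x_hat)` CSV shared by H2 (option 1).
#' @param means_path Path to the `(id, neighbor_mean)` CSV shared by H1
#'   (option 2).
#' @param reference_coords,reference_values H1's reference embedding
#'   coordinates and original-scale feature values.
#' @param config A [reliability_config()].
#' @param k Neighbor count (option-2 mean export).
#' @param out_path Optional path to write the result CSV.
#' @return A tibble; `(id, r_c)` for scoring calls, `(id, neighbor_mean)`
#'   for the mean export.
#' @name two_party
NULL

#' @rdname two_party
#' @export
exchange_score_option1 <- function(coords_path, values_path, reference_coords,
                                   reference_values, config, out_path = NULL) {
  coords <- import_coords(coords_path)
  vals <- read_pair_file(values_path, "x_hat")
  vals <- vals[match(coords$.row_id, vals$.row_id), ]
  if (anyNA(vals$.row_id)) abort("Candidate value file does not cover every transmitted coordinate id.")
  nm <- knn_mean(reference_coords, reference_values, coords, config$k)
  out <- tibble(
    .row_id = coords$.row_id,
    r_c = score_disparity(abs(vals$x_hat - nm$neighbor_mean), config)
  )
  if (!is.null(out_path)) write_pair_file(out, "r_c", out_path)
  out
}

#' @rdname two_party
#' @export
exchange_neighbor_means <- function(coords_path, reference_coords,
                                    reference_values, k, out_path = NULL) {
  coords <- import_coords(coords_path)
  nm <- knn_mean(reference_coords, reference_values, coords, k)
  if (!is.null(out_path)) write_pair_file(nm, "neighbor_mean", out_path)
  nm
}

#' @rdname two_party
#' @export
exchange_score_option2 <- function(means_path, values_path, config,
                                   out_path = NULL) {
  nm <- read_pair_file(means_path, "neighbor_mean")
  vals <- read_pair_file(values_path, "x_hat")
  vals <- vals[match(nm$.row_id, vals$.row_id), ]
  if (anyNA(vals$.row_id)) abort("Candidate value file does not cover every neighborhood-mean id.")
  out <- tibble(
    .row_id = nm$.row_id,
    r_c = score_disparity(abs(vals$x_hat - nm$neighbor_mean), config)
  )
  if (!is.null(out_path)) write_pair_file(out, "r_c", out_path)
  out
}

#' Read or write a two-column `(id, value)` exchange CSV
#'
#' @param x Tibble whose first column is `.row_id` and second the value.
#' @param value_name Header name of the value column.
#' @param path File path.
#' @return `write_pair_file()` returns `path` invisibly; `read_pair_file()`
#'   a tibble `(.row_id, <value_name>)`.
#' @export
write_pair_file <- function(x, value_name, path) {
  lines <- c(
    paste0("id,", value_name),
    sprintf("%s,%s", x$.row_id, fmt_num(x[[2]]))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pair_file
#' @export
read_pair_file <- function(path, value_name) {
  if (!file.exists(path)) abort(sprintf("Exchange file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) abort(sprintf("Empty exchange file: %s", path))
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) abort(sprintf("Malformed row at line %d of '%s'.", bad[1] + 1L, path))
  out <- tibble(
    .row_id = vapply(parts, `[[`, "", 1),
    value = as.numeric(vapply(parts, `[[`, "", 2))
  )
  names(out)[2] <- value_name
  out
}
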