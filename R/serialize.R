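#' Save or load a fitted embedding model
#'
#' Models are stored as a single JSON document with a plain-text header part
#' (format version, backend, hyperparameters, seed, feature order, normalizer
#' statistics) followed by the fitted state and the training coordinates.
#' Every double is rendered with 17 significant digits, so a load/save
#' round-trip reproduces projections bit-identically. This file is what the
#' reference institution shares in the two-party workflow: the trained map,
#' never the reference rows themselves (the PCA state is a 2-column rotation;
#' the graph backend stores normalized coordinates only).
#'
#' @param model A `psdg_embedding`.
#' @param path File path (conventionally `.json`).
#' @return `save_embedding()` returns `path` invisibly; `load_embedding()`
#'   returns the `psdg_embedding`.
#' @export
save_embedding <- function(model, path) {
  stopifnot(inherits(model, "psdg_embedding"))
  num <- function(x) {
    if (is.matrix(x)) {
      list(dim = dim(x), data = fmt_num(as.vector(x)))
    } else {
      fmt_num(x)
    }
  }
  state <- model$state
  state_out <- switch(state$type,
    pca = list(type = "pca", rotation = num(state$rotation)),
    laplacian = list(
      type = "laplacian", n_neighbors = state$n_neighbors,
      train_x = num(state$train_x), train_coords = num(state$train_coords)
    )
  )
  doc <- list(
    format_version = model$format_version,
    backend = model$backend,
    hyperparameters = model$hyperparameters,
    seed = model$seed,
    feature_order = model$feature_order,
    normalizer = list(
      feature = model$normalizer$feature,
      center = fmt_num(model$normalizer$center),
      scale = fmt_num(model$normalizer$scale)
    ),
    state = state_out,
    training_coords = list(
      .row_id = model$training_coords$.row_id,
      c1 = fmt_num(model$training_coords$c1),
      c2 = fmt_num(model$training_coords$c2)
    )
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort(sprintf("Corrupt or truncated model file '%s': %s", path, conditionMessage(e)))
  )
  if (is.null(doc$format_version) || doc$format_version != 1L) {
    abort(sprintf(
      "Unsupported model format version '%s' in %s.",
      doc$format_version %||% "<missing>", path
    ))
  }
  unnum <- function(x) {
    if (is.list(x)) {
      matrix(as.numeric(x$data), nrow = x$dim[1], ncol = x$dim[2])
    } else {
      as.numeric(x)
    }
  }
  state <- if (doc$state$type == "pca") {
    list(type = "pca", rotation = unnum(doc$state$rotation))
  } else {
    list(
      type = "laplacian", n_neighbors = as.integer(doc$state$n_neighbors),
      train_x = unnum(doc$state$train_x), train_coords = unnum(doc$state$train_coords)
    )
  }
  normalizer <- tibble(
    feature = doc$normalizer$feature,
    center = as.numeric(doc$normalizer$center),
    scale = as.numeric(doc$normalizer$scale)
  )
  class(normalizer) <- c("psdg_normalizer", class(normalizer))
  structure(
    list(
      format_version = 1L,
      backend = doc$backend,
      hyperparameters = list(
        n_neighbors = as.integer(doc$hyperparameters$n_neighbors),
        min_dist = as.numeric(doc$hyperparameters$min_dist),
        n_components = 2L, metric = "euclidean"
      ),
      seed = as.integer(doc$seed),
      normalizer = normalizer,
      feature_order = doc$feature_order,
      state = state,
      training_coords = tibble(
        .row_id = doc$training_coords$.row_id,
        c1 = as.numeric(doc$training_coords$c1),
        c2 = as.numeric(doc$training_coords$c2)
      )
    ),
    class = "psdg_embedding"
  )
}

#' Exchange coordinate sets as CSV
#'
#' Writes/reads `(id, c1, c2)` coordinate files with full float precision —
#' the artifact the incomplete-data institution transmits to the reference
#' institution in the two-party workflow. Round-trips are exact and preserve
#' row order.
#'
#' @param coords A tibble with columns `.row_id`, `c1`, `c2`.
#' @param path File path.
#' @return `export_coords()` returns `path` invisibly; `import_coords()`
#'   returns the coordinates tibble.
#' @export
export_coords <- function(coords, path) {
  stopifnot(all(c(".row_id", "c1", "c2") %in% names(coords)))
  lines <- c(
    "id,c1,c2",
    sprintf("%s,%s,%s", coords$.row_id, fmt_num(coords$c1), fmt_num(coords$c2))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname export_coords
#' @export
import_coords <- function(path) {
  if (!file.exists(path)) abort(sprintf("Coordinates file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "id,c1,c2") {
    abort(sprintf("File '%s' is not a coordinates file (bad header).", path))
  }
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad)) {
    abort(sprintf("Malformed coordinates row at line %d of '%s'.", bad[1] + 1L, path))
  }
  c1 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  c2 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(c1) | is.na(c2))
  if (length(bad)) {
    abort(sprintf("Non-numeric coordinate at line %d of '%s'.", bad[1] + 1L, path))
  }
  tibble(.row_id = vapply(parts, `[[`, "", 1), c1 = c1, c2 = c2)
}
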