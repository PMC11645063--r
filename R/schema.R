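#' Declare a feature of a tabular dataset
#'
#' A feature specification records the feature's name, its measurement kind,
#' an optional unit, and — for every non-continuous kind — the ordered set of
#' admissible encoded values. All values are stored numerically; categorical
#' and binary features use the numeric encoding declared through `levels`.
#'
#' @param name Feature name (single string, must match the CSV header).
#' @param kind One of `"continuous"`, `"integer"`, `"ordinal"`,
#'   `"categorical"`, `"binary"`.
#' @param unit Optional unit string (e.g. `"ng/mL"`, `"years"`). Units take
#'   part in schema alignment: two datasets may only be combined when the
#'   units of shared features agree or are declared equivalent.
#' @param levels Ordered numeric vector of admissible encoded values.
#'   Required for all kinds except `"continuous"`, which must not have one.
#'   `"integer"` features may omit it (the admissible set is then the closed
#'   observed range of the reference data).
#'
#' @return A one-row tibble with class `psdg_feature`.
#' @export
#' @examples
#' feature_spec("patient_age", "integer", unit = "years")
#' feature_spec("deg_malig", "ordinal", levels = c(1, 2, 3))
feature_spec <- function(name, kind, unit = NA_character_, levels = NULL) {
  kinds <- c("continuous", "integer", "ordinal", "categorical", "binary")
  if (!is.character(name) || length(name) != 1 || is.na(name) || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  kind <- match.arg(kind, kinds)
  if (kind == "continuous" && !is.null(levels)) {
    abort(sprintf("Continuous feature '%s' must not declare levels.", name))
  }
  if (kind %in% c("ordinal", "categorical", "binary") && is.null(levels)) {
    abort(sprintf("Feature '%s' (%s) requires admissible `levels`.", name, kind))
  }
  if (!is.null(levels)) {
    levels <- as.numeric(levels)
    if (length(levels) == 0 || anyNA(levels) || anyDuplicated(levels)) {
      abort(sprintf("`levels` of '%s' must be non-empty, finite and duplicate-free.", name))
    }
    if (is.unsorted(levels, strictly = TRUE)) {
      abort(sprintf("`levels` of '%s' must be strictly increasing.", name))
    }
    if (kind == "binary" && length(levels) != 2) {
      abort(sprintf("Binary feature '%s' must have exactly 2 levels.", name))
    }
  }
  out <- tibble(
    name = name, kind = kind, unit = as.character(unit),
    levels = list(levels)
  )
  class(out) <- c("psdg_feature", class(out))
  out
}

#' Assemble a dataset schema from feature specifications
#'
#' @param ... `feature_spec()` rows (or a single list of them).
#' @return A tibble of features with class `psdg_schema`.
#' @export
#' @examples
#' psdg_schema(
#'   feature_spec("psa", "continuous", unit = "ng/mL"),
#'   feature_spec("patient_age", "integer", unit = "years")
#' )
psdg_schema <- function(...) {
  specs <- list(...)
  if (length(specs) == 1 && is.list(specs[[1]]) && !inherits(specs[[1]], "psdg_feature")) {
    specs <- specs[[1]]
  }
  if (length(specs) == 0) abort("A schema needs at least one feature.")
  out <- dplyr::bind_rows(specs)
  if (anyDuplicated(out$name)) {
    abort(sprintf(
      "Duplicate feature names in schema: %s",
      paste(unique(out$name[duplicated(out$name)]), collapse = ", ")
    ))
  }
  class(out) <- c("psdg_schema", setdiff(class(out), "psdg_feature"))
  out
}

schema_feature <- function(schema, name) {
  i <- match(name, schema$name)
  if (is.na(i)) abort(sprintf("Feature '%s' is not in the schema.", name))
  schema[i, ]
}

#' Read or write a schema sidecar file
#'
#' Schemas are stored as YAML: a list of features (`name`, `kind`, optional
#' `unit` and `levels`) plus an optional top-level `label` entry naming the
#' class column.
#'
#' @param path File path.
#' @param schema A `psdg_schema`.
#' @param label_name Optional label column name stored alongside the schema.
#' @return `read_schema()` returns a list with elements `schema` and
#'   `label_name`; `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(sprintf("Schema file not found: %s", path))
  raw <- yaml::read_yaml(path)
  feats <- raw$features %||% abort("Schema file lacks a `features` list.")
  specs <- lapply(feats, function(f) {
    feature_spec(
      name = f$name, kind = f$kind,
      unit = f$unit %||% NA_character_,
      levels = if (!is.null(f$levels)) as.numeric(f$levels) else NULL
    )
  })
  list(schema = psdg_schema(specs), label_name = raw$label %||% NULL)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path, label_name = NULL) {
  feats <- lapply(seq_len(nrow(schema)), function(i) {
    f <- list(name = schema$name[i], kind = schema$kind[i])
    if (!is.na(schema$unit[i])) f$unit <- schema$unit[i]
    lv <- schema$levels[[i]]
    if (!is.null(lv)) f$levels <- as.numeric(lv)
    f
  })
  out <- list(features = feats)
  if (!is.null(label_name)) out$label <- label_name
  yaml::write_yaml(out, path)
  invisible(path)
}
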