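#' Construct a typed tabular dataset
#'
#' A `psdg_dataset` is a tibble of encoded numeric feature columns plus a
#' stable `.row_id` column and an optional class-label column, carrying its
#' `psdg_schema` as an attribute. A feature that is `NA` in *every* row is
#' "unknown" (uniform missingness); by default a feature that is `NA` in only
#' some rows is rejected — mixed missingness patterns belong to
#' [run_imputation()], which partitions rows by pattern first.
#'
#' @param data A data frame with one column per schema feature (plus the
#'   optional label column and optional id column).
#' @param schema A [psdg_schema()].
#' @param label_name Optional name of the class-label column in `data`.
#' @param id_col Optional name of a column holding unique row identifiers;
#'   when absent, identifiers `r000001, ...` are generated.
#' @param strict If `TRUE` (default), reject features missing in only some
#'   rows.
#'
#' @return A tibble with class `psdg_dataset`: columns `.row_id`, the schema
#'   features (numeric), and the label column (character) when present.
#' @export
#' @examples
#' sch <- psdg_schema(
#'   feature_spec("age", "integer", unit = "years"),
#'   feature_spec("psa", "continuous", unit = "ng/mL")
#' )
#' psdg_dataset(data.frame(age = c(55, 61), psa = c(4.1, 8.9)), sch)
psdg_dataset <- function(data, schema, label_name = NULL, id_col = NULL,
                         strict = TRUE) {
  data <- as_tibble(data)
  missing_feats <- setdiff(schema$name, names(data))
  if (length(missing_feats)) {
    abort(sprintf("Columns missing from data: %s", paste(missing_feats, collapse = ", ")))
  }
  if (!is.null(label_name) && !label_name %in% names(data)) {
    abort(sprintf("Label column '%s' not found in data.", label_name))
  }

  if (!is.null(id_col)) {
    ids <- as.character(data[[id_col]])
  } else if (".row_id" %in% names(data)) {
    ids <- as.character(data$.row_id)
  } else {
    ids <- sprintf("r%06d", seq_len(nrow(data)))
  }
  if (anyDuplicated(ids)) abort("Row identifiers must be unique.")

  feats <- lapply(schema$name, function(nm) {
    parse_feature_column(data[[nm]], schema_feature(schema, nm))
  })
  names(feats) <- schema$name

  out <- tibble(.row_id = ids)
  out <- dplyr::bind_cols(out, as_tibble(feats))
  if (!is.null(label_name)) {
    lab <- data[[label_name]]
    out[[label_name]] <- ifelse(is.na(lab) | (is.character(lab) & !nzchar(as.character(lab))),
      NA_character_, as.character(lab)
    )
  }

  if (strict) {
    n_na <- vapply(out[schema$name], function(col) sum(is.na(col)), integer(1))
    partial <- schema$name[n_na > 0 & n_na < nrow(out)]
    if (length(partial)) {
      abort(sprintf(
        paste0(
          "Feature(s) %s are missing in only some rows. The core data model ",
          "requires uniform missingness per feature; use run_imputation() for ",
          "mixed patterns, or strict = FALSE."
        ),
        paste(sprintf("'%s'", partial), collapse = ", ")
      ))
    }
  }

  structure(out,
    schema = schema, label_name = label_name,
    class = c("psdg_dataset", class(out))
  )
}

parse_feature_column <- function(col, spec) {
  if (is.character(col)) {
    col[!nzchar(trimws(col))] <- NA_character_
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(parsed))
    if (length(bad)) {
      abort(sprintf(
        "Unparseable value '%s' in column '%s', row %d.",
        col[bad[1]], spec$name, bad[1]
      ))
    }
    col <- parsed
  }
  col <- as.numeric(col)
  ok <- !is.na(col)
  if (spec$kind == "integer" && any(col[ok] != round(col[ok]))) {
    bad <- which(ok & col != round(col))[1]
    abort(sprintf("Non-integer value %s in integer column '%s', row %d.", col[bad], spec$name, bad))
  }
  lv <- spec$levels[[1]]
  if (!is.null(lv) && any(!col[ok] %in% lv)) {
    bad <- which(ok & !col %in% lv)[1]
    abort(sprintf(
      "Value %s in column '%s' (row %d) is not an admissible level.",
      col[bad], spec$name, bad
    ))
  }
  col
}

#' @export
`[.psdg_dataset` <- function(x, ...) {
  sch <- attr(x, "schema")
  lab <- attr(x, "label_name")
  out <- NextMethod()
  if (is.data.frame(out) && all(sch$name %in% names(out)) && ".row_id" %in% names(out)) {
    attr(out, "schema") <- sch
    attr(out, "label_name") <- if (!is.null(lab) && lab %in% names(out)) lab else NULL
    class(out) <- unique(c("psdg_dataset", class(out)))
  } else if (is.data.frame(out)) {
    class(out) <- setdiff(class(out), "psdg_dataset")
  }
  out
}

#' @export
print.psdg_dataset <- function(x, ...) {
  cat(sprintf(
    "<psdg_dataset> %d rows, %d features (%d known, %d unknown)%s\n",
    nrow(x), length(dataset_features(x)),
    length(known_features(x)), length(unknown_features(x)),
    if (!is.null(attr(x, "label_name"))) paste0(", label '", attr(x, "label_name"), "'") else ""
  ))
  NextMethod()
}

#' Dataset accessors
#'
#' `dataset_schema()`, `dataset_features()`, `dataset_label()` return the
#' schema, the feature names, and the label column name. `known_features()` /
#' `unknown_features()` split features by the uniform-missingness mask (a
#' feature is unknown when it is `NA` in every row). `is_reference()` tests
#' for a complete dataset (no unknown feature).
#'
#' @param x A `psdg_dataset`.
#' @return Character vectors (or a schema / logical scalar).
#' @export
dataset_schema <- function(x) attr(x, "schema")

#' @rdname dataset_schema
#' @export
dataset_features <- function(x) dataset_schema(x)$name

#' @rdname dataset_schema
#' @export
dataset_label <- function(x) attr(x, "label_name")

#' @rdname dataset_schema
#' @export
known_features <- function(x) {
  feats <- dataset_features(x)
  feats[vapply(feats, function(nm) !all(is.na(x[[nm]])), logical(1))]
}

#' @rdname dataset_schema
#' @export
unknown_features <- function(x) setdiff(dataset_features(x), known_features(x))

#' @rdname dataset_schema
#' @export
is_reference <- function(x) {
  length(unknown_features(x)) == 0 && !anyNA(as.matrix(x[dataset_features(x)]))
}

#' Read a typed CSV table
#'
#' Comma-separated, UTF-8, header row; empty cells are the missing marker.
#' The header must contain every schema feature (plus the optional label and
#' id columns); unknown columns are an error.
#'
#' @inheritParams psdg_dataset
#' @param path CSV file path.
#' @return A `psdg_dataset`.
#' @export
read_dataset <- function(path, schema, label_name = NULL, id_col = NULL,
                         strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.csv(path,
    colClasses = "character", check.names = FALSE,
    na.strings = NULL, fileEncoding = "UTF-8"
  )
  expected <- c(".row_id", schema$name, label_name, id_col)
  extra <- setdiff(names(raw), expected)
  if (length(extra)) {
    abort(sprintf("Unknown column(s) in %s: %s", path, paste(extra, collapse = ", ")))
  }
  psdg_dataset(raw, schema, label_name = label_name, id_col = id_col, strict = strict)
}

#' Write a dataset (or any tibble) as full-precision CSV
#'
#' Numeric cells are rendered with 17 significant digits so that reading the
#' file back reproduces every double bit-for-bit; `NA` becomes the empty
#' string. Output bytes are a pure function of the input, which is what makes
#' whole pipeline runs byte-identical under a fixed seed.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param header_lines Optional character vector written as `#`-prefixed
#'   comment lines before the header (used for provenance stamps).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, header_lines = NULL) {
  cols <- lapply(x, function(col) {
    if (is.numeric(col)) fmt_num(col) else {
      out <- as.character(col)
      out[is.na(out)] <- ""
      out
    }
  })
  mat <- do.call(cbind, cols)
  lines <- c(
    if (!is.null(header_lines)) paste0("# ", header_lines),
    paste(names(x), collapse = ","),
    if (nrow(x)) apply(mat, 1, paste, collapse = ",")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Align an incomplete dataset against a reference
#'
#' Checks that every known feature of the incomplete dataset exists in the
#' reference with the same kind and unit (units may be declared equivalent,
#' e.g. mL and cc), and returns both datasets with features reordered
#' known-first. Reordering is a pure permutation: no values change.
#'
#' @param reference A complete `psdg_dataset`.
#' @param incomplete A `psdg_dataset` with one or more unknown features.
#' @param unit_equivalences Optional list of character vectors, each grouping
#'   unit spellings to treat as identical, e.g. `list(c("mL", "cc"))`.
#' @return A list with elements `reference` and `incomplete`.
#' @export
align_schemas <- function(reference, incomplete, unit_equivalences = NULL) {
  rs <- dataset_schema(reference)
  is_ <- dataset_schema(incomplete)
  common <- intersect(is_$name, rs$name)
  if (length(common) == 0) abort("No common features between the datasets.")

  canon_unit <- function(u) {
    if (is.na(u)) return(NA_character_)
    for (grp in unit_equivalences) if (u %in% grp) return(grp[[1]])
    u
  }
  for (nm in common) {
    fr <- schema_feature(rs, nm)
    fi <- schema_feature(is_, nm)
    if (fr$kind != fi$kind) {
      abort(sprintf("Kind mismatch for '%s': %s vs %s.", nm, fr$kind, fi$kind))
    }
    ur <- canon_unit(fr$unit)
    ui <- canon_unit(fi$unit)
    if (!identical(is.na(ur), is.na(ui)) || (!is.na(ur) && ur != ui)) {
      abort(sprintf(
        "Unit mismatch for '%s': '%s' vs '%s' (declare equivalents via unit_equivalences).",
        nm, fr$unit, fi$unit
      ))
    }
  }

  list(
    reference = reorder_known_first(reference),
    incomplete = reorder_known_first(incomplete)
  )
}

# Known features first, then unknown, preserving within-group schema order.
reorder_known_first <- function(x) {
  sch <- dataset_schema(x)
  known <- known_features(x)
  ord <- c(intersect(sch$name, known), setdiff(sch$name, known))
  sch2 <- sch[match(ord, sch$name), ]
  class(sch2) <- class(sch)
  cols <- c(".row_id", ord, dataset_label(x))
  out <- x[, cols]
  structure(out,
    schema = sch2, label_name = dataset_label(x),
    class = class(x)
  )
}

# Restrict a dataset to a subset of schema features (keeps id + label).
select_features <- function(x, feats) {
  sch <- dataset_schema(x)
  sch2 <- sch[match(feats, sch$name), ]
  class(sch2) <- class(sch)
  out <- x[, c(".row_id", feats, dataset_label(x))]
  structure(out, schema = sch2, label_name = dataset_label(x), class = class(x))
}
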