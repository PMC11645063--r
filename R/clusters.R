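#' Per-class centroids of a reference embedding
#'
#' @param reference_coords Coordinates tibble `(.row_id, c1, c2)`.
#' @param labels Per-row class labels aligned with `reference_coords`
#'   (coerced to character); every label must have at least one member.
#' @return A tibble `(label, c1, c2, n_members)` sorted by label.
#' @export
compute_centroids <- function(reference_coords, labels) {
  labels <- as.character(labels)
  if (length(labels) != nrow(reference_coords)) {
    abort("labels must align with reference_coords.")
  }
  if (length(labels) == 0 || anyNA(labels)) {
    abort("Every reference row needs a non-missing label.")
  }
  tibble(label = labels, c1 = reference_coords$c1, c2 = reference_coords$c2) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      c1 = mean(.data$c1), c2 = mean(.data$c2),
      n_members = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$label)
}

#' Fit a density-thresholded cluster radius
#'
#' Scans an increasing radius grid around the centroid and returns the
#' largest grid radius whose member density still meets the threshold,
#' where density is the member count per unit embedding area,
#' `|members within r| / (pi r^2)` (a raw-count interpretation is available
#' via `density = "count"`). Returns 0 when no grid radius qualifies.
#' Raising the threshold never increases the fitted radius.
#'
#' @param centroid Numeric length-2 centroid `(c1, c2)`.
#' @param member_coords Tibble or matrix of the cluster members' 2D
#'   coordinates.
#' @param density_threshold Positive density threshold (points per unit
#'   area, or a raw count when `density = "count"`).
#' @param r_start,r_step,r_max Radius search grid; `r_max` defaults to the
#'   largest member distance plus one step.
#' @param density `"area"` (default) or `"count"`.
#' @return The fitted radius (single number).
#' @export
fit_radius <- function(centroid, member_coords, density_threshold,
                       r_start = 0.05, r_step = 0.05, r_max = NULL,
                       density = c("area", "count")) {
  density <- match.arg(density)
  if (r_step <= 0) abort("`r_step` must be positive.")
  m <- as.matrix(as.data.frame(member_coords))
  if (nrow(m) == 0) abort("Empty member coordinate set.")
  d <- sqrt((m[, 1] - centroid[1])^2 + (m[, 2] - centroid[2])^2)
  if (is.null(r_max)) r_max <- max(d) + r_step
  radii <- seq(r_start, r_max, by = r_step)
  counts <- vapply(radii, function(r) sum(d <= r), numeric(1))
  dens <- if (density == "area") counts / (pi * radii^2) else counts
  ok <- which(dens >= density_threshold)
  if (length(ok) == 0) return(0)
  radii[max(ok)]
}

#' Fit all per-label cluster areas
#'
#' Combines [compute_centroids()] and [fit_radius()] into the cluster table
#' the reference institution shares for label assignment: one row per class
#' with centroid, validated radius, threshold, and member count.
#'
#' @inheritParams compute_centroids
#' @inheritParams fit_radius
#' @return A `psdg_clusters` tibble `(label, c1, c2, radius,
#'   density_threshold, n_members)`.
#' @export
fit_clusters <- function(reference_coords, labels, density_threshold,
                         r_start = 0.05, r_step = 0.05, r_max = NULL,
                         density = c("area", "count")) {
  density <- match.arg(density)
  labels <- as.character(labels)
  cents <- compute_centroids(reference_coords, labels)
  radii <- vapply(seq_len(nrow(cents)), function(i) {
    members <- labels == cents$label[i]
    fit_radius(
      c(cents$c1[i], cents$c2[i]),
      cbind(reference_coords$c1[members], reference_coords$c2[members]),
      density_threshold,
      r_start = r_start, r_step = r_step, r_max = r_max, density = density
    )
  }, numeric(1))
  out <- tibble(
    label = cents$label, c1 = cents$c1, c2 = cents$c2,
    radius = radii, density_threshold = density_threshold,
    n_members = cents$n_members
  )
  structure(out, class = c("psdg_clusters", class(out)))
}

#' Assign class labels by cluster area membership
#'
#' A query point inside exactly one cluster area receives that label; a
#' point inside several areas goes to the nearest centroid (distance ties to
#' the lexicographically smallest label); a point outside every area stays
#' unassigned (`NA`, a value — not an error).
#'
#' @param query_coords Coordinates tibble `(.row_id, c1, c2)`.
#' @param clusters A `psdg_clusters` table.
#' @return A tibble `(.row_id, label)` with `NA` for unassigned queries.
#' @export
assign_labels <- function(query_coords, clusters) {
  if (nrow(clusters) == 0) abort("Empty cluster table.")
  cl <- dplyr::arrange(as_tibble(clusters), .data$label) # lexicographic tie-break
  q1 <- query_coords$c1
  q2 <- query_coords$c2
  d <- sapply(seq_len(nrow(cl)), function(i) {
    sqrt((q1 - cl$c1[i])^2 + (q2 - cl$c2[i])^2)
  })
  d <- matrix(d, nrow = length(q1))
  inside <- sweep(d, 2, cl$radius, "<=")
  d_masked <- ifelse(inside, d, Inf)
  best <- apply(d_masked, 1, which.min)
  hit <- rowSums(inside) > 0
  tibble(
    .row_id = query_coords$.row_id,
    label = ifelse(hit, cl$label[best], NA_character_)
  )
}

#' Cluster validation percentages across density thresholds
#'
#' For each threshold, refits all cluster radii and reports the percentage
#' of query points assigned to each label and in total. Assigned sets are
#' nested: raising the threshold never validates a point that a lower
#' threshold rejected.
#'
#' @param query_coords Coordinates of the generated/projected points.
#' @param reference_coords,labels Reference embedding and per-row labels.
#' @param thresholds Numeric vector of density thresholds.
#' @inheritParams fit_radius
#' @return A tibble `(density_threshold, label, n_assigned, pct)`, where
#'   `label = "(total)"` rows aggregate over classes.
#' @export
validation_curve <- function(query_coords, reference_coords, labels,
                             thresholds, r_start = 0.05, r_step = 0.05,
                             r_max = NULL, density = c("area", "count")) {
  density <- match.arg(density)
  labels <- as.character(labels)
  n_q <- nrow(query_coords)
  purrr::map_dfr(thresholds, function(th) {
    cl <- fit_clusters(reference_coords, labels, th,
      r_start = r_start, r_step = r_step, r_max = r_max, density = density
    )
    asg <- assign_labels(query_coords, cl)
    per <- tibble(label = cl$label) |>
      dplyr::left_join(
        dplyr::count(dplyr::filter(asg, !is.na(.data$label)), .data$label, name = "n_assigned"),
        by = "label"
      ) |>
      dplyr::mutate(n_assigned = dplyr::coalesce(.data$n_assigned, 0L))
    dplyr::bind_rows(
      per,
      tibble(label = "(total)", n_assigned = sum(per$n_assigned))
    ) |>
      dplyr::mutate(
        density_threshold = th,
        pct = 100 * .data$n_assigned / n_q,
        .before = 1
      )
  })
}

#' Write or read a cluster table CSV
#'
#' The `(label, centroid, radius, threshold, n_members)` file is exactly
#' what the reference institution shares for label-only completion.
#'
#' @param clusters A `psdg_clusters` table.
#' @param path File path.
#' @export
write_clusters <- function(clusters, path) {
  write_dataset(as_tibble(clusters), path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#")
  out <- tibble(
    label = raw$label,
    c1 = as.numeric(raw$c1), c2 = as.numeric(raw$c2),
    radius = as.numeric(raw$radius),
    density_threshold = as.numeric(raw$density_threshold),
    n_members = as.integer(raw$n_members)
  )
  structure(out, class = c("psdg_clusters", class(out)))
}
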