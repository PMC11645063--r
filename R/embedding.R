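#' Fit a reference-trained 2D embedding
#'
#' Trains a two-dimensional Euclidean embedding on the normalized feature
#' matrix of a complete reference dataset, *excluding* the label column, and
#' stores everything needed to project new rows out-of-sample through the
#' same map: the reference-fitted normalizer, the feature order, the backend
#' state, and the training coordinates.
#'
#' The embedding backend is a contract, not an identity: any trained 2D
#' Euclidean embedding exposing fit + out-of-sample transform fits the
#' pipeline. Two backends ship with the package:
#' \describe{
#'   \item{`"pca"` (default)}{Seeded principal-component projection onto the
#'     first two components, with deterministic sign convention. Exact,
#'     bit-reproducible out-of-sample transform; for the 3–6 feature tables
#'     this method targets it retains most of the variance.}
#'   \item{`"laplacian"`}{Nonlinear neighbor-graph embedding: a fuzzy
#'     k-nearest-neighbor graph with smoothed local connectivity is built on
#'     the normalized features and embedded by the eigenvectors of its
#'     symmetric normalized graph Laplacian; new points are placed at the
#'     membership-weighted mean of their neighbors' coordinates.}
#' }
#' Refitting with the same data, hyperparameters and seed reproduces the
#' training coordinates bit-identically for both backends.
#'
#' @param reference A complete `psdg_dataset` (`d_U = 0`).
#' @param n_neighbors Neighborhood size of the embedding graph (ignored by
#'   the PCA backend but always recorded).
#' @param min_dist Packing parameter recorded for audit; the shipped
#'   backends do not use it.
#' @param seed Integer seed; mandatory, because reproducibility of the
#'   projection is a design requirement of the whole method.
#' @param backend `"pca"` or `"laplacian"`.
#'
#' @return A `psdg_embedding` object.
#' @export
fit_embedding <- function(reference, n_neighbors = 15L, min_dist = 0.1,
                          seed, backend = c("pca", "laplacian")) {
  backend <- match.arg(backend)
  seed <- assert_scalar_int(seed, "seed", min = 0L)
  n_neighbors <- assert_scalar_int(n_neighbors, "n_neighbors")
  if (length(unknown_features(reference)) > 0) {
    abort("fit_embedding() requires a complete reference dataset.")
  }
  feats <- dataset_features(reference)
  if (length(feats) < 2) abort("Need at least two features to embed in 2D.")
  if (nrow(reference) <= n_neighbors) {
    abort(sprintf(
      "Reference has %d rows; need more than n_neighbors = %d.",
      nrow(reference), n_neighbors
    ))
  }

  normalizer <- fit_normalizer(reference)
  x <- as.matrix(apply_normalizer(reference, normalizer)[feats])
  storage.mode(x) <- "double"

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  state <- switch(backend,
    pca = fit_backend_pca(x),
    laplacian = fit_backend_laplacian(x, n_neighbors)
  )
  coords <- backend_transform(backend, state, x, training = TRUE)

  structure(
    list(
      format_version = 1L,
      backend = backend,
      hyperparameters = list(
        n_neighbors = n_neighbors, min_dist = min_dist,
        n_components = 2L, metric = "euclidean"
      ),
      seed = seed,
      normalizer = normalizer,
      feature_order = feats,
      state = state,
      training_coords = tibble(
        .row_id = reference$.row_id,
        c1 = coords[, 1], c2 = coords[, 2]
      )
    ),
    class = "psdg_embedding"
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.psdg_embedding <- function(x, ...) {
  cat(sprintf(
    "<psdg_embedding> backend '%s', %d features, %d training rows, seed %d\n",
    x$backend, length(x$feature_order), nrow(x$training_coords), x$seed
  ))
  invisible(x)
}

#' Project rows through a fitted embedding
#'
#' Applies the model's reference-fitted normalizer and the trained 2D map to
#' new rows. Every feature in the model's feature order must be present and
#' non-missing (candidates fill the unknown slot with their trial value
#' before projection). Pure with respect to the fitted state, and
#' deterministic: projecting the same rows twice yields identical
#' coordinates.
#'
#' @param model A `psdg_embedding`.
#' @param data A `psdg_dataset` or plain data frame containing the model's
#'   features and (optionally) a `.row_id` column.
#' @param chunk_size Rows per projection block; results are independent of
#'   chunking (blocks only bound the size of intermediate distance
#'   matrices).
#' @return A coordinates tibble `(.row_id, c1, c2)`.
#' @export
project <- function(model, data, chunk_size = 50000L) {
  stopifnot(inherits(model, "psdg_embedding"))
  feats <- model$feature_order
  missing_ <- setdiff(feats, names(data))
  if (length(missing_)) {
    abort(sprintf("Data lack feature(s): %s", paste(missing_, collapse = ", ")))
  }
  ids <- if (".row_id" %in% names(data)) as.character(data$.row_id) else sprintf("q%06d", seq_len(nrow(data)))
  x <- as.matrix(as.data.frame(data)[feats])
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    abort("Cannot project rows containing missing values; fill or expand them first.")
  }
  x <- sweep(x, 2, model$normalizer$center[match(feats, model$normalizer$feature)], "-")
  x <- sweep(x, 2, model$normalizer$scale[match(feats, model$normalizer$feature)], "/")

  n <- nrow(x)
  coords <- matrix(0, n, 2)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    coords[s:e, ] <- backend_transform(model$backend, model$state, x[s:e, , drop = FALSE])
  }
  tibble(.row_id = ids, c1 = coords[, 1], c2 = coords[, 2])
}

# ---- PCA backend -----------------------------------------------------------

fit_backend_pca <- function(x) {
  sv <- svd(x, nu = 0, nv = 2)
  rot <- sv$v
  # deterministic sign: largest-magnitude loading of each axis is positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(type = "pca", rotation = rot)
}

# ---- fuzzy kNN-graph Laplacian backend -------------------------------------

fit_backend_laplacian <- function(x, n_neighbors) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  memb <- fuzzy_memberships(d, n_neighbors, self = TRUE)
  w <- memb$w
  w <- w + t(w) - w * t(w) # probabilistic t-conorm symmetrization
  deg <- pmax(rowSums(w), .Machine$double.eps)
  dhalf <- 1 / sqrt(deg)
  lsym <- diag(n) - (dhalf * w) * rep(dhalf, each = n)
  eig <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  # eigenvalues ascend from the back; skip the trivial constant mode
  ord <- rev(seq_len(n))
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  coords <- vecs[, 2:3, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  scale <- sqrt(mean(rowSums(coords^2)) / 2)
  coords <- coords / scale
  list(
    type = "laplacian", n_neighbors = n_neighbors,
    train_x = x, train_coords = coords
  )
}

# UMAP-style smoothed local connectivity: per row i, rho_i is the distance
# to the nearest neighbor and sigma_i solves
# sum_j exp(-(d_ij - rho_i)/sigma_i) = log2(k) over the k nearest neighbors.
fuzzy_memberships <- function(d, k, self = FALSE) {
  n <- nrow(d)
  m <- ncol(d)
  w <- matrix(0, n, m)
  target <- log2(k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    if (self) di[i] <- Inf
    nb <- order(di, method = "radix")[seq_len(min(k, m - as.integer(self)))]
    dn <- di[nb]
    rho <- dn[1]
    lo <- 1e-10
    hi <- max(dn[length(dn)] - rho, 1e-10) * 10 + 1
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-pmax(dn - rho, 0) / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    sigma <- (lo + hi) / 2
    w[i, nb] <- exp(-pmax(dn - rho, 0) / sigma)
  }
  list(w = w)
}

backend_transform <- function(backend, state, x, training = FALSE) {
  if (backend == "pca") {
    return(x %*% state$rotation)
  }
  if (training) {
    return(state$train_coords)
  }
  # Nystrom-style out-of-sample placement at the membership-weighted mean of
  # the nearest training points' coordinates.
  d <- euclid_cross(x, state$train_x)
  memb <- fuzzy_memberships(d, state$n_neighbors, self = FALSE)$w
  wsum <- pmax(rowSums(memb), .Machine$double.eps)
  (memb %*% state$train_coords) / wsum
}

euclid_cross <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}
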