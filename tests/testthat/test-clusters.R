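test_that("centroids are plain coordinate means per label", {
  one <- tibble::tibble(.row_id = "a", c1 = 3, c2 = 4)
  expect_equal(compute_centroids(one, "pos")[, c("c1", "c2")], tibble::tibble(c1 = 3, c2 = 4))

  two <- tibble::tibble(.row_id = c("a", "b"), c1 = c(0, 2), c2 = c(0, 0))
  cents <- compute_centroids(two, c("x", "x"))
  expect_equal(c(cents$c1, cents$c2), c(1, 0))

  set.seed(11)
  many <- tibble::tibble(.row_id = sprintf("m%03d", 1:100), c1 = rnorm(100), c2 = rnorm(100))
  lab <- sample(c("u", "v"), 100, replace = TRUE)
  cents <- compute_centroids(many, lab)
  for (l in c("u", "v")) {
    expect_equal(cents$c1[cents$label == l], mean(many$c1[lab == l]), tolerance = 1e-12)
    expect_equal(cents$c2[cents$label == l], mean(many$c2[lab == l]), tolerance = 1e-12)
  }
  expect_error(compute_centroids(many, lab[1:10]), "align")
})

test_that("the fitted radius is the largest grid radius meeting the density", {
  # single member at the centroid: 1/(pi r^2) >= 5 up to r = 0.2 on a 0.1 grid
  r <- fit_radius(c(0, 0), cbind(0, 0), 5, r_start = 0.1, r_step = 0.1, r_max = 1)
  expect_equal(r, 0.2)
  # threshold 0 never fails: radius = r_max
  expect_equal(fit_radius(c(0, 0), cbind(0, 0), 0, r_start = 0.1, r_step = 0.1, r_max = 1), 1)
  # nothing qualifies -> empty area
  expect_equal(fit_radius(c(0, 0), cbind(5, 5), 1e9, r_max = 1), 0)
  expect_error(fit_radius(c(0, 0), cbind(numeric(0), numeric(0)), 1), "Empty member")
  expect_error(fit_radius(c(0, 0), cbind(0, 0), 1, r_step = 0), "positive")
})

test_that("uniform disk members recover radius ~1 at the matched density", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    th <- runif(100, 0, 2 * pi)
    rr <- sqrt(runif(100))
    members <- cbind(rr * cos(th), rr * sin(th))
    fitted <- fit_radius(c(0, 0), members, 100 / pi)
    expect_equal(fitted, 1, tolerance = 0.051) # within one grid step
  }
})

test_that("radius fitting is monotone in the threshold and order-invariant", {
  set.seed(5)
  members <- cbind(rnorm(80), rnorm(80))
  radii <- vapply(
    c(0, 1, 3, 6, 8, 12, 20),
    function(th) fit_radius(c(0, 0), members, th),
    numeric(1)
  )
  expect_true(all(diff(radii) <= 0))
  shuffled <- members[sample(80), ]
  expect_identical(
    fit_radius(c(0, 0), members, 6),
    fit_radius(c(0, 0), shuffled, 6)
  )
})

test_that("label assignment handles containment, overlap, and outsiders", {
  clusters <- structure(
    tibble::tibble(
      label = c("A", "B"), c1 = c(0, 3), c2 = c(0, 0),
      radius = c(2, 2), density_threshold = 1, n_members = c(5L, 5L)
    ),
    class = c("psdg_clusters", class(tibble::tibble()))
  )
  q <- tibble::tibble(
    .row_id = c("at_A", "overlap_nearer_A", "midpoint_tie", "far"),
    c1 = c(0, 1.2, 1.5, 50), c2 = c(0, 0, 0, 50)
  )
  got <- assign_labels(q, clusters)
  expect_equal(got$label, c("A", "A", "A", NA)) # tie breaks to smaller label
  # brute-force check of the overlap rule
  dA <- abs(q$c1 - 0)
  dB <- abs(q$c1 - 3)
  expect_equal(got$label[2], c("A", "B")[which.min(c(dA[2], dB[2]))])
})

test_that("every assigned point is inside its stored cluster radius", {
  ref <- make_reference(fixture_spec(n_rows = 200, seed = 21))
  model <- fit_embedding(ref, seed = 9)
  clusters <- fit_clusters(model$training_coords, ref$class, density_threshold = 2)
  q <- project(model, make_reference(fixture_spec(n_rows = 100, seed = 22)))
  asg <- assign_labels(q, clusters)
  hit <- !is.na(asg$label)
  expect_gt(sum(hit), 0)
  for (i in which(hit)) {
    j <- match(asg$label[i], clusters$label)
    d <- sqrt((q$c1[i] - clusters$c1[j])^2 + (q$c2[i] - clusters$c2[j])^2)
    expect_lte(d, clusters$radius[j])
  }
})

test_that("validation curves shrink as the density threshold rises", {
  ref <- make_reference(fixture_spec(n_rows = 200, seed = 31))
  model <- fit_embedding(ref, seed = 4)
  q <- model$training_coords # queries = members: threshold 0 assigns all
  curve <- validation_curve(q, model$training_coords, ref$class,
    thresholds = c(0, 1, 2, 4, 8, 16)
  )
  total <- curve[curve$label == "(total)", ]
  expect_equal(total$pct[total$density_threshold == 0], 100)
  expect_true(all(diff(total$pct) <= 0))
  # per-label recount at one threshold
  cl <- fit_clusters(model$training_coords, ref$class, 2)
  asg <- assign_labels(q, cl)
  for (l in cl$label) {
    expect_equal(
      curve$n_assigned[curve$density_threshold == 2 & curve$label == l],
      sum(asg$label == l, na.rm = TRUE)
    )
  }
})

test_that("cluster tables round-trip through CSV", {
  ref <- make_reference(fixture_spec(n_rows = 150, seed = 41))
  model <- fit_embedding(ref, seed = 2)
  cl <- fit_clusters(model$training_coords, ref$class, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clusters(cl, path)
  back <- read_clusters(path)
  expect_equal(as.data.frame(back), as.data.frame(cl))
})
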