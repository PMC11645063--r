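test_that("neighborhood means match hand-computed micro-cases", {
  one <- tibble::tibble(.row_id = "a", c1 = 0, c2 = 0)
  q <- tibble::tibble(.row_id = "q", c1 = 3, c2 = -4)
  expect_equal(knn_mean(one, 10, q, 1)$neighbor_mean, 10)

  two <- tibble::tibble(.row_id = c("a", "b"), c1 = c(0, 1), c2 = c(0, 0))
  q2 <- tibble::tibble(.row_id = "q", c1 = 0.4, c2 = 0)
  expect_equal(knn_mean(two, c(10, 20), q2, 2)$neighbor_mean, 15)

  expect_error(knn_mean(two, c(10, 20), q2, 3), "exceeds")
  expect_error(knn_mean(two[0, ], numeric(0), q2, 1), "Empty reference")
})

test_that("neighborhood means equal the exhaustive oracle, ties included", {
  set.seed(7)
  ref <- tibble::tibble(
    .row_id = sprintf("r%03d", 1:50),
    c1 = round(rnorm(50), 1), # rounding forces ties
    c2 = round(rnorm(50), 1)
  )
  vals <- rpois(50, 60)
  q <- tibble::tibble(.row_id = sprintf("q%02d", 1:10), c1 = round(rnorm(10), 1), c2 = round(rnorm(10), 1))
  got <- knn_mean(ref, vals, q, 5)$neighbor_mean
  expect_equal(got, brute_knn_mean(ref, vals, q, 5))

  # explicit tie at the k-th distance: four equidistant references, k = 2
  sq <- tibble::tibble(.row_id = c("d", "c", "b", "a"), c1 = c(1, -1, 0, 0), c2 = c(0, 0, 1, -1))
  qq <- tibble::tibble(.row_id = "q", c1 = 0, c2 = 0)
  # ascending id wins: neighbors {a, b}
  expect_equal(knn_mean(sq, c(40, 30, 20, 10), qq, 2)$neighbor_mean, 15)
})

test_that("disparity banding reproduces the six-band table and its 0 extension", {
  cfg <- reliability_config(epsilon = 1)
  cases <- data.frame(
    f = c(0, 0.4, 1, 1.0001, 2, 2.5, 3, 3.5, 4, 4.5, 5, 5.5, 6, 6.0001, 7),
    r = c(1, 1, 1, 0.9, 0.9, 0.8, 0.8, 0.7, 0.7, 0.6, 0.6, 0.5, 0.5, 0, 0)
  )
  expect_equal(score_disparity(cases$f, cfg), cases$r)
  expect_error(score_disparity(-0.1, cfg), "nonnegative")
  expect_error(reliability_config(epsilon = 0), "positive")
})

test_that("banding is scale-invariant and non-increasing in disparity", {
  set.seed(3)
  f <- sort(runif(200, 0, 8))
  cfg1 <- reliability_config(epsilon = 1)
  s1 <- score_disparity(f, cfg1)
  expect_true(all(diff(s1) <= 0))
  for (c_ in c(0.01, 0.5, 7)) {
    expect_equal(score_disparity(f * c_, reliability_config(epsilon = c_)), s1)
  }
})

test_that("candidate scoring composes knn_mean and banding; worked example agrees", {
  we <- make_worked_example()
  nm <- knn_mean(we$reference_coords, we$reference_values, we$candidates, we$config$k)
  expect_equal(nm$neighbor_mean, we$expected$neighbor_mean)
  scores <- score_disparity(abs(we$candidates$x_hat - nm$neighbor_mean), we$config)
  expect_equal(scores, we$expected$r_c)
  expect_equal(abs(we$candidates$x_hat - nm$neighbor_mean), we$expected$f_disp)

  # full pipeline equality on a real fixture: scored == compose(stages)
  ref <- tiny_reference(n = 30, seed = 2)
  inc <- blank_feature(tiny_reference(n = 6, seed = 3), "age")
  grid <- enumerate_values(ref, "age")
  gen <- expand_candidates(inc, grid)
  model <- fit_embedding(ref, seed = 5, n_neighbors = 10)
  coords_g <- project(model, materialize(gen))
  cfg <- reliability_config(k = 7, epsilon = 1)
  scored <- score_candidates(gen, coords_g, model$training_coords, ref$age, cfg)
  nm2 <- knn_mean(model$training_coords, ref$age, coords_g, 7)
  expect_equal(scored$neighbor_mean, nm2$neighbor_mean)
  expect_equal(scored$r_c, score_disparity(abs(gen$x_hat - nm2$neighbor_mean), cfg))
  expect_equal(scored$f_disp, abs(scored$x_hat - scored$neighbor_mean))
  # misaligned ids are rejected
  expect_error(
    score_candidates(gen, coords_g[rev(seq_len(nrow(coords_g))), ], model$training_coords, ref$age, cfg),
    "not aligned"
  )
})

test_that("validated sets are nested in the threshold and never deduplicated", {
  ref <- tiny_reference(n = 40, seed = 8)
  inc <- blank_feature(tiny_reference(n = 10, seed = 9), "age")
  grid <- enumerate_values(ref, "age")
  gen <- expand_candidates(inc, grid)
  model <- fit_embedding(ref, seed = 5)
  coords_g <- project(model, materialize(gen))
  scored <- score_candidates(gen, coords_g, model$training_coords, ref$age, reliability_config())

  ladder <- c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1)
  sizes <- vapply(ladder, function(rm) nrow(filter_validated(scored, rm)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  for (rm in ladder) {
    expect_equal(nrow(filter_validated(scored, rm)), sum(scored$r_c >= rm & scored$r_c > 0))
  }
  # multiple candidates of one source row can validate together
  v <- filter_validated(scored, 0.5)
  expect_gt(max(table(v$.row_id)), 1)
})

test_that("two-party scoring options agree with each other and with local scoring", {
  ref <- tiny_reference(n = 30, seed = 12)
  inc <- blank_feature(tiny_reference(n = 8, seed = 13), "age")
  grid <- enumerate_values(ref, "age")
  gen <- expand_candidates(inc, grid)
  model <- fit_embedding(ref, seed = 2)
  coords_g <- project(model, materialize(gen))
  cfg <- reliability_config(k = 5, epsilon = 1)
  local <- score_candidates(gen, coords_g, model$training_coords, ref$age, cfg)

  coords_path <- withr::local_tempfile(fileext = ".csv")
  values_path <- withr::local_tempfile(fileext = ".csv")
  means_path <- withr::local_tempfile(fileext = ".csv")
  o1_path <- withr::local_tempfile(fileext = ".csv")
  o2_path <- withr::local_tempfile(fileext = ".csv")
  export_coords(coords_g, coords_path)
  write_pair_file(tibble::tibble(.row_id = coords_g$.row_id, x_hat = gen$x_hat), "x_hat", values_path)

  opt1 <- exchange_score_option1(coords_path, values_path, model$training_coords, ref$age, cfg, o1_path)
  exchange_neighbor_means(coords_path, model$training_coords, ref$age, cfg$k, means_path)
  opt2 <- exchange_score_option2(means_path, values_path, cfg, o2_path)

  expect_identical(opt1, opt2)
  expect_identical(readLines(o1_path), readLines(o2_path))
  expect_equal(opt1$r_c, local$r_c)
})
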