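test_that("mean imputation assigns the grid-snapped reference mean everywhere", {
  sch <- psdg_schema(feature_spec("age", "integer"), feature_spec("psa", "continuous"))
  ref <- psdg_dataset(data.frame(age = c(40, 50, 60), psa = c(1, 2, 3)), sch)
  inc <- psdg_dataset(data.frame(age = rep(NA_real_, 4), psa = c(5, 6, 7, 8)), sch)
  expect_equal(mean_impute(ref, inc, "age")$age, rep(50, 4))

  refc <- psdg_dataset(data.frame(age = c(44, 44, 44), psa = c(1, 2, 3)), sch)
  expect_equal(mean_impute(refc, inc, "age")$age, rep(44, 4))

  # non-integer means snap to the nearest admissible value
  ref2 <- psdg_dataset(data.frame(age = c(40, 41, 43), psa = c(1, 2, 3)), sch)
  expect_equal(mean_impute(ref2, inc, "age")$age, rep(round(mean(c(40, 41, 43))), 4))
})

test_that("k-NN imputation matches micro-cases, limits, and the oracle", {
  fx <- make_split(fixture_spec(n_rows = 160, seed = 33), reference_fraction = 0.5)
  ref <- fx$reference
  inc <- fx$incomplete

  # k = N_r degenerates to (snapped) mean imputation
  all_k <- knn_impute(ref, inc, "age", k = nrow(ref))
  expect_equal(all_k$age, mean_impute(ref, inc, "age")$age)

  # k = 1 copies the nearest reference row's value (normalized feature space)
  known <- c("psa", "volume")
  nz <- fit_normalizer(ref)
  rx <- as.matrix(apply_normalizer(ref, nz)[known])
  qx <- as.matrix(apply_normalizer(as.data.frame(inc), nz, features = known)[known])
  o1 <- brute_knn_value(rx, ref$.row_id, ref$age, qx, 1)
  expect_equal(knn_impute(ref, inc, "age", k = 1)$age, o1) # integers: snap is identity

  # general k against the exhaustive oracle (snapped)
  ok <- brute_knn_value(rx, ref$.row_id, ref$age, qx, 7)
  grid <- enumerate_values(ref, "age")
  expect_equal(
    knn_impute(ref, inc, "age", k = 7)$age,
    vapply(ok, function(v) grid$values[which.min(abs(grid$values - v))], numeric(1))
  )
  expect_error(knn_impute(ref, inc, "age", k = nrow(ref) + 1), "exceeds")
})

test_that("the rotation harness follows the hold-out protocol", {
  ref <- make_reference(fixture_spec(n_rows = 253, seed = 35))
  cfg <- psdg_config(seed = 13, n_neighbors = 10L, k = 5L)
  expect_warning(
    rep <- rotation_validate(ref, "age", cfg, n_groups = 5),
    "remainder"
  )
  expect_equal(rep$group_size, 50) # 253 -> 5 x 50, 3 dropped
  expect_equal(sort(unique(rep$summary$rotation)), 1:5)
  # every rotation holds out (n_groups - 1) * group_size rows
  expect_true(all(rep$summary$n_rows == 200))
  # accounting identity and nesting on every (rotation, r_min) cell
  s <- rep$summary
  expect_true(all(s$correctly_imputed + s$synthetic == s$n_validated))
  for (g in 1:5) {
    sg <- s[s$rotation == g, ]
    sg <- sg[order(sg$r_min), ]
    expect_true(all(diff(sg$n_validated) <= 0))
    expect_true(all(diff(sg$correctly_imputed) <= 0))
  }
  # identical protocol under the same seed
  expect_warning(rep2 <- rotation_validate(ref, "age", cfg, n_groups = 5))
  expect_identical(rep$summary, rep2$summary)
})

test_that("range tables report per-range percentages with empty ranges blank", {
  ref <- make_reference(fixture_spec(n_rows = 250, seed = 37))
  cfg <- psdg_config(seed = 17, n_neighbors = 10L, k = 5L)
  rep <- rotation_validate(ref, "age", cfg, n_groups = 5)
  tab <- range_table(rep, c(35, 45, 55, 65, 75, 85, 93))
  rng_cols <- setdiff(names(tab), c("method", "r_min", "mean_pct"))
  vals <- as.matrix(tab[rng_cols])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 100)))
  expect_equal(nrow(tab), length(rep$r_min_ladder) + 2) # psdg ladder + 2 baselines

  # recount one cell by hand
  det <- rep$detail
  cell <- det[det$method == "psdg" & det$r_min == 1 &
    det$truth >= 45 & det$truth < 55, ]
  expect_equal(
    tab[tab$method == "psdg" & !is.na(tab$r_min) & tab$r_min == 1, ][["[45,55)"]],
    100 * sum(cell$correct) / nrow(cell)
  )

  # a range with no true rows is NA, not zero
  tab2 <- range_table(rep, c(0, 1, 35, 93))
  expect_true(all(is.na(tab2[["[0,1)"]])))

  # mean imputation is only ever right near the reference mean
  mean_rows <- tidy(rep)
  expect_lt(
    mean_rows$mean_pct[mean_rows$method == "mean"],
    mean_rows$mean_pct[mean_rows$method == "psdg" & mean_rows$r_min == 0.5]
  )
})
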