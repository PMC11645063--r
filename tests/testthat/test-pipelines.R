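make_case_fixture <- function(n = 400, seed = 10, fraction = 0.25, ...) {
  make_split(fixture_spec(n_rows = n, seed = seed, ...), reference_fraction = fraction)
}

test_that("partial synthesis keeps real known values and validated trial values", {
  fx <- make_case_fixture()
  cfg <- psdg_config(seed = 7, r_min = 1)
  out <- run_case1(fx$reference, fx$incomplete, cfg)
  counts <- attr(out, "counts")

  expect_gt(nrow(out), 0)
  expect_lte(nrow(out), counts$n_incomplete * counts$m)
  expect_equal(counts$n_generated, counts$n_incomplete * counts$m)
  # at r_min = 1 every surviving trial value sits within epsilon of its
  # neighborhood mean
  grid <- attr(out, "grid")
  expect_true(all(abs(out$age - out$neighbor_mean) <= grid$epsilon_default))
  # known features are bit-equal to their source rows
  src <- match(out$.source_id, fx$incomplete$.row_id)
  expect_identical(out$psa, fx$incomplete$psa[src])
  expect_identical(out$volume, fx$incomplete$volume[src])
  expect_identical(out$class, fx$incomplete$class[src])
})

test_that("pipelines are deterministic under a fixed config and seed", {
  fx <- make_case_fixture(n = 250, seed = 3)
  cfg <- psdg_config(seed = 5, r_min = 0.9)
  o1 <- run_case1(fx$reference, fx$incomplete, cfg)
  o2 <- run_case1(fx$reference, fx$incomplete, cfg)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(tibble::as_tibble(as.data.frame(o1)), p1)
  write_dataset(tibble::as_tibble(as.data.frame(o2)), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("label assignment accepts central rows and rejects outliers", {
  spec <- fixture_spec(n_rows = 300, seed = 14)
  split <- make_split(spec, reference_fraction = 0.5, drop_features = character(0), drop_label = TRUE)
  cfg <- psdg_config(seed = 5, density_threshold = 1)

  out <- run_case0(split$reference, split$incomplete, cfg)
  expect_gt(nrow(out), 0)
  expect_true(all(!is.na(out$.label_assigned)))
  # assignments overwhelmingly match the held-back truth on separated classes
  truth <- split$truth$class[match(out$.source_id, split$truth$.row_id)]
  expect_gt(mean(out$.label_assigned == truth), 0.9)

  # class-conditional mean rows project at the centroids and get that class
  ref_tbl <- as.data.frame(split$reference)
  centers <- lapply(split(ref_tbl[c("age", "psa", "volume")], ref_tbl$class), colMeans)
  center_rows <- do.call(rbind, lapply(centers, function(v) as.data.frame(as.list(v))))
  center_rows$age <- round(center_rows$age)
  inc2 <- psdg_dataset(center_rows, dataset_schema(split$reference))
  out2 <- run_case0(split$reference, inc2, cfg)
  expect_equal(out2$.label_assigned, names(centers))

  # rows far from every cluster are excluded
  far <- center_rows
  for (nm in names(far)) far[[nm]] <- far[[nm]] + 1000
  out3 <- run_case0(split$reference, psdg_dataset(far, dataset_schema(split$reference)), cfg)
  expect_equal(nrow(out3), 0)
})

test_that("joint generation is the label-assigned subset of partial synthesis", {
  spec <- fixture_spec(n_rows = 300, seed = 16)
  split <- make_split(spec, reference_fraction = 0.3, drop_label = TRUE)
  cfg <- psdg_config(seed = 9, r_min = 1, density_threshold = 1)

  out2 <- run_case2(split$reference, split$incomplete, cfg)
  out1 <- run_case1(split$reference, split$incomplete, cfg)
  expect_true(all(out2$.row_id %in% out1$.row_id))
  expect_true(all(!is.na(out2$.label_assigned)))
  # labels agree with a direct assignment of the surviving coordinates
  clusters <- attr(out2, "clusters")
  direct <- assign_labels(
    tibble::tibble(.row_id = out2$.row_id, c1 = out2$c1, c2 = out2$c2), clusters
  )
  expect_equal(out2$.label_assigned, direct$label)
  # stage-by-stage recount: case-2 rows are exactly the assignable case-1 rows
  asg1 <- assign_labels(
    tibble::tibble(.row_id = out1$.row_id, c1 = out1$c1, c2 = out1$c2), clusters
  )
  expect_equal(sort(out2$.row_id), sort(out1$.row_id[!is.na(asg1$label)]))
})

test_that("iterative synthesis adds one feature per pass and fills them all", {
  spec <- fixture_spec(n_rows = 300, n_features = 4, seed = 18)
  full <- make_reference(spec)
  split <- make_split(spec, reference_fraction = 0.4, drop_features = c("age", "marker1"))
  cfg <- psdg_config(seed = 4, r_min = 0.8)

  out <- run_full_synthesis(split$reference, split$incomplete, cfg)
  iters <- attr(out, "iterations")
  expect_equal(length(iters), 2)
  expect_true(all(!is.na(out$age)) && all(!is.na(out$marker1)))
  expect_true(all(c("psa", "volume", "age", "marker1") %in% names(out)))

  # default generation order is descending |correlation| with the label
  y <- as.numeric(full$class)
  cors <- abs(c(age = cor(full$age, y), marker1 = cor(full$marker1, y)))
  expect_equal(names(iters), names(sort(cors, decreasing = TRUE)))

  # an empty feature order is the identity
  ident <- run_full_synthesis(split$reference, split$incomplete,
    psdg_config(seed = 4, feature_order = character(0))
  )
  expect_identical(as.data.frame(ident), as.data.frame(split$incomplete))
  expect_error(
    run_full_synthesis(split$reference, split$incomplete,
      psdg_config(seed = 4, feature_order = "nope")
    ),
    "absent from reference"
  )
})

test_that("iterative synthesis can assign the label when it is missing too", {
  spec <- fixture_spec(n_rows = 300, seed = 19)
  split <- make_split(spec,
    reference_fraction = 0.4,
    drop_features = "age", drop_label = TRUE
  )
  cfg <- psdg_config(seed = 6, r_min = 1, density_threshold = 1)
  out <- run_full_synthesis(split$reference, split$incomplete, cfg)
  expect_gt(nrow(out), 0)
  expect_true(all(!is.na(out$.label_assigned)))
})

test_that("imputation partitions by missingness pattern and picks the best candidate", {
  spec <- fixture_spec(n_rows = 500, seed = 23)
  full <- make_reference(spec)
  tbl <- tibble::as_tibble(as.data.frame(full))
  ref <- psdg_dataset(tbl[1:200, ], dataset_schema(full), label_name = "class", id_col = ".row_id")
  inc_tbl <- tbl[201:400, ]
  truth <- inc_tbl
  inc_tbl$age[1:100] <- NA # pattern 1: age missing
  inc_tbl$psa[101:160] <- NA # pattern 2: psa missing
  inc <- psdg_dataset(inc_tbl, dataset_schema(full),
    label_name = "class",
    id_col = ".row_id", strict = FALSE
  )
  cfg <- psdg_config(seed = 8, r_min = 0.9, n_levels = 12L)

  imp <- run_imputation(inc, ref, cfg)
  unimp <- attr(imp, "unimputed")
  filled_age <- !imp$.row_id[1:100] %in% unimp$.row_id[unimp$feature == "age"]
  expect_gt(mean(filled_age), 0.5)
  expect_identical(imp$age[161:200], inc_tbl$age[161:200]) # untouched complete rows
  expect_true(all(is.na(imp$age[1:100]) == !filled_age))

  # selection rule oracle: rerun the single-pattern stage as case 1 and take
  # argmax r_c, ties by disparity then value
  sub <- psdg_dataset(inc_tbl[1:100, ], dataset_schema(full), label_name = "class", id_col = ".row_id")
  val <- run_case1(ref, sub, cfg)
  best <- tibble::as_tibble(as.data.frame(val)) |>
    dplyr::arrange(.source_id, dplyr::desc(r_c), f_disp, age) |>
    dplyr::distinct(.source_id, .keep_all = TRUE)
  got <- imp$age[match(best$.source_id, imp$.row_id)]
  expect_equal(got, best$age)
  # every imputed value came from the validated candidate set
  expect_true(all(got %in% val$age))

  # multiple-imputation raw material: top-n candidates per cell
  imp3 <- run_imputation(inc, ref, cfg, top_n = 3)
  mi <- attr(imp3, "mi_candidates")
  expect_true(all(table(mi$feature, mi$.row_id) <= 3))
})

test_that("a table can be imputed against its own complete rows", {
  spec <- fixture_spec(n_rows = 400, seed = 29)
  full <- make_reference(spec)
  tbl <- tibble::as_tibble(as.data.frame(full))
  tbl$age[1:80] <- NA
  mixed <- psdg_dataset(tbl, dataset_schema(full),
    label_name = "class",
    id_col = ".row_id", strict = FALSE
  )
  complete_rows <- psdg_dataset(tbl[!is.na(tbl$age), ], dataset_schema(full),
    label_name = "class", id_col = ".row_id"
  )
  imp <- run_imputation(mixed, complete_rows, psdg_config(seed = 2, r_min = 0.8))
  expect_gt(sum(!is.na(imp$age[1:80])), 0)
})
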