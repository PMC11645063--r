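# Shared builders and independent brute-force oracles.

tiny_schema <- function() {
  psdg_schema(
    feature_spec("age", "integer", unit = "years"),
    feature_spec("psa", "continuous", unit = "ng/mL"),
    feature_spec("volume", "continuous", unit = "mL")
  )
}

tiny_reference <- function(n = 40, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    age = sample(35:92, n, replace = TRUE),
    psa = round(stats::rlnorm(n, log(8), 0.4), 3),
    volume = round(stats::rnorm(n, 45, 8), 3),
    class = as.character(rbinom(n, 1, 0.5))
  )
  psdg_dataset(df, tiny_schema(), label_name = "class")
}

blank_feature <- function(dataset, feature) {
  tbl <- tibble::as_tibble(as.data.frame(dataset))
  tbl[[feature]] <- NA_real_
  psdg_dataset(tbl, dataset_schema(dataset),
    label_name = dataset_label(dataset), id_col = ".row_id"
  )
}

# Exhaustive k-NN mean oracle: full sort per query, ties by ascending id.
brute_knn_mean <- function(ref_coords, ref_values, query_coords, k) {
  vapply(seq_len(nrow(query_coords)), function(i) {
    d <- sqrt((ref_coords$c1 - query_coords$c1[i])^2 +
      (ref_coords$c2 - query_coords$c2[i])^2)
    ord <- order(d, ref_coords$.row_id, method = "radix")
    mean(ref_values[ord[seq_len(k)]])
  }, numeric(1))
}

# Exhaustive k-NN imputation oracle in (already normalized) feature space.
brute_knn_value <- function(ref_mat, ref_ids, ref_values, query_mat, k) {
  vapply(seq_len(nrow(query_mat)), function(i) {
    d <- sqrt(rowSums((ref_mat - matrix(query_mat[i, ],
      nrow(ref_mat), ncol(ref_mat),
      byrow = TRUE
    ))^2))
    ord <- order(d, ref_ids, method = "radix")
    mean(ref_values[ord[seq_len(k)]])
  }, numeric(1))
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
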