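# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider pivot_longer crossing
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap
NULL

# Full-precision decimal rendering so text round-trips reproduce doubles
# bit-for-bit (17 significant digits are sufficient for IEEE 754 doubles).
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

# Stable, locale-independent ordering for character/numeric keys.
stable_order <- function(...) order(..., method = "radix")

# Deterministic short hash of a configuration object (hex string).
config_hash <- function(x) {
  rlang::hash(x)
}

`%||%` <- rlang::`%||%`

assert_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1 || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s.", name, min))
  }
  as.integer(x)
}
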