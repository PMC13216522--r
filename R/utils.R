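#' @useDynLib stscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", ".I", "neighborhood_id", "period", "n", "o", "raw_rate",
  "sebs_rate", "participated", "woman_id", "invitation_year", "age_group",
  "x", "y", "z", "pseudo_p", "category", "deprivation", "population",
  "building_id", "norm_street", "norm_number", "registry_key",
  "street_number", "postal_code", "id", "value", "mean_abs_shap",
  "trajectory", "access", "outcome", "similarity", "from", "to", "node_id",
  "..features", "address"
))

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each random
#' stage draws from its own stream, obtained by hashing the master seed with
#' a small stream index; this keeps stages independent of each other's draw
#' counts while remaining fully reproducible.
#'
#' @param seed master integer seed
#' @param stream non-negative integer stream index
#' @return an integer seed in the range 1 to 2^31 - 2
#' @export
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% m)
  # one multiplicative-congruential step per stream index keeps streams apart
  s <- (s * 48271 + 1 + 104729 * as.numeric(stream)) %% m
  as.integer(s %/% 1 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stopf(...)
  invisible(TRUE)
}
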