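# Cross-sectional Getis-Ord Gi* hot/cold spot detection: binary
# k-nearest-neighbor weights on unit centroids (self-included "star" form),
# z-scores against the global mean, conditional Monte-Carlo permutation
# pseudo-p-values, and graduated significance classes.

#' Build k-nearest-neighbor binary weights
#'
#' Each unit's neighbors are its `k` nearest by centroid Euclidean
#' distance (directed: symmetry is not imposed). Exact distance ties are
#' broken by unit order.
#'
#' @param centroids matrix or data.frame with x, y
#' @param k number of neighbors
#' @return object of class `knn_weights`: list with `nb` (n x k matrix of
#'   neighbor indices, self excluded) and `k`
#' @export
build_knn <- function(centroids, k) {
  cc <- as.matrix(as.data.frame(centroids)[, c("x", "y")])
  n <- nrow(cc)
  assert_that(k >= 1L && k < n,
              "parameter error: k = %d must be in [1, n - 1] with n = %d", k, n)
  nb <- FNN::get.knn(cc, k = k)$nn.index
  structure(list(nb = nb, k = as.integer(k), n = n), class = "knn_weights")
}

#' Getis-Ord Gi* z-scores
#'
#' Self-included form with binary weights: for unit i with weighted sum
#' `sum_j w_ij x_j` over itself and its k neighbors (`W_i = k + 1`),
#' `z_i = (sum_j w_ij x_j - xbar W_i) /
#'        (S sqrt((n sum_j w_ij^2 - W_i^2) / (n - 1)))`
#' where `xbar` and `S` are the global mean and standard deviation
#' including unit i.
#'
#' @param x finite values, one per unit
#' @param weights a [build_knn()] object
#' @return numeric z per unit; if the global variance is zero, a vector of
#'   `NA` with `attr(, "degenerate") = TRUE` (no spatial pattern)
#' @export
gi_star <- function(x, weights) {
  n <- length(x)
  assert_that(n == weights$n, "gi_star(): %d values for %d units", n, weights$n)
  assert_that(all(is.finite(x)), "gi_star(): values must be finite")
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  if (S == 0) {
    z <- rep(NA_real_, n)
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  W <- weights$k + 1
  lag <- x + rowSums(matrix(x[weights$nb], nrow = n))
  denom <- S * sqrt((n * W - W^2) / (n - 1))
  (lag - xbar * W) / denom
}

#' Conditional-permutation pseudo-p-values for Gi*
#'
#' The focal value is held fixed while the k neighbor values are drawn
#' without replacement from the remaining n - 1 values;
#' `pseudo_p = (m + 1) / (n_perm + 1)` where m counts permuted statistics
#' whose magnitude is as or more extreme than the observed one
#' (`|z_perm| >= |z_obs|`). The sign of the observed z decides hot versus
#' cold in [classify_significance()]; keeping the p two-sided on the
#' magnitude holds the test at its nominal level under exchangeable
#' surfaces. Deterministic given the seed.
#'
#' @param x values per unit
#' @param weights a [build_knn()] object
#' @param n_perm number of permutations (default 9999, >= 99)
#' @param rng_seed integer seed
#' @return pseudo-p per unit in (0, 1]; `NA` where z is degenerate
#' @export
permutation_p <- function(x, weights, n_perm = 9999L, rng_seed = 1L) {
  assert_that(n_perm >= 99L, "parameter error: n_perm must be >= 99")
  z <- gi_star(x, weights)
  if (isTRUE(attr(z, "degenerate"))) return(rep(NA_real_, length(x)))
  valid <- as.integer(!is.na(z))
  center <- mean(x) * (weights$k + 1)
  set.seed(derive_seed(rng_seed, 40L))
  rcpp_gi_perm_p(as.numeric(x), weights$nb, valid, center,
                 as.integer(n_perm))
}

#' Graduated hot/cold significance classes
#'
#' Hot when z > 0, cold when z < 0, at the smallest crossed threshold
#' among 0.001, 0.01, 0.05, 0.1; otherwise "not significant".
#'
#' @param z Gi* z-scores
#' @param pseudo_p permutation pseudo-p-values
#' @return factor with levels `hot_p0.001` ... `cold_p0.1`,
#'   `not_significant`
#' @export
classify_significance <- function(z, pseudo_p) {
  lv <- c(paste0("hot_p", c(0.001, 0.01, 0.05, 0.1)),
          paste0("cold_p", c(0.001, 0.01, 0.05, 0.1)), "not_significant")
  out <- rep("not_significant", length(z))
  for (thr in c(0.1, 0.05, 0.01, 0.001)) { # smallest crossed wins
    sel <- !is.na(z) & !is.na(pseudo_p) & pseudo_p < thr
    out[sel & z > 0] <- paste0("hot_p", thr)
    out[sel & z < 0] <- paste0("cold_p", thr)
  }
  factor(out, levels = lv)
}

#' Per-period Gi* hot spot analysis of a panel
#'
#' Runs [gi_star()], [permutation_p()] and [classify_significance()] on the
#' chosen value column for every period. Units missing in a period are
#' dropped and the KNN weights rebuilt from the remaining centroids.
#'
#' @param panel a smoothed panel (see [sebs_smooth()])
#' @param centroids data.frame with neighborhood_id, x, y
#' @param value name of the value column (default "sebs_rate")
#' @param k neighbors (default 16, the retained definition; 8 available)
#' @param n_perm permutations
#' @param rng_seed seed
#' @return data.table: neighborhood_id, period, z, pseudo_p, class
#' @export
hotspot_panel <- function(panel, centroids, value = "sebs_rate", k = 16L,
                          n_perm = 9999L, rng_seed = 1L) {
  panel <- data.table::as.data.table(panel)
  cen <- data.table::as.data.table(centroids)
  res <- list()
  for (per in sort(unique(panel$period))) {
    sub <- panel[period == per & !is.na(get(value))]
    cc <- cen[match(sub$neighborhood_id, cen$neighborhood_id)]
    w <- build_knn(cc, k = min(k, nrow(sub) - 1L))
    z <- gi_star(sub[[value]], w)
    p <- permutation_p(sub[[value]], w, n_perm = n_perm,
                       rng_seed = derive_seed(rng_seed, per))
    res[[as.character(per)]] <- data.table::data.table(
      neighborhood_id = sub$neighborhood_id, period = per,
      z = as.numeric(z), pseudo_p = p, class = classify_significance(z, p))
  }
  data.table::rbindlist(res)[]
}
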