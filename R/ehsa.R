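# Emerging hot spot analysis: a location x period space-time cube of
# smoothed rates, a Gi* score for every bin over a spatial-KNN x temporal-lag
# neighborhood, Benjamini-Hochberg FDR correction of the bin p-values, a
# Mann-Kendall trend test on each location's bin z-score series, and a
# 17-category rule table (1 no-pattern + 8 hot + 8 cold) classifying each
# location's trajectory. The Historical category uses a 50% threshold; all
# run-based categories use the standard 90% threshold.

#' The 17 emerging hot spot categories
#' @export
ehsa_categories <- function() {
  fam <- c("new", "consecutive", "intensifying", "persistent", "diminishing",
           "sporadic", "oscillating", "historical")
  c("no_pattern", paste0(fam, "_hot"), paste0(fam, "_cold"))
}

#' Build a space-time cube from a panel
#'
#' @param panel data.frame with neighborhood_id, period and a value column
#' @param value value column name (default "sebs_rate")
#' @return list of class `st_cube`: `values` (locations x periods matrix,
#'   NA where unobserved), `mask` (TRUE = observed), `locations`, `periods`,
#'   `capacity` = locations x periods
#' @export
build_cube <- function(panel, value = "sebs_rate") {
  panel <- data.table::as.data.table(panel)
  periods <- sort(unique(panel$period))
  assert_that(length(periods) >= 2L,
              "parameter error: a space-time cube needs >= 2 periods")
  locs <- sort(unique(panel$neighborhood_id))
  vals <- matrix(NA_real_, length(locs), length(periods),
                 dimnames = list(locs, periods))
  vals[cbind(match(panel$neighborhood_id, locs),
             match(panel$period, periods))] <- panel[[value]]
  structure(list(values = vals, mask = !is.na(vals), locations = locs,
                 periods = periods,
                 capacity = length(locs) * length(periods)),
            class = "st_cube")
}

#' Gi* statistics for every space-time bin
#'
#' The neighborhood of bin (i, t) is the bin itself plus the bins of i and
#' its `spatial_k` nearest locations at temporal lags up to
#' `temporal_window`. Masked bins are excluded from the sums, with the
#' weight count renormalized accordingly. The global mean, SD and n are
#' taken over all observed bins of the cube. Two-sided analytic normal
#' p-values accompany the z-scores.
#'
#' @param cube an [build_cube()] object
#' @param centroids data.frame with neighborhood_id, x, y
#' @param spatial_k spatial nearest neighbors (default 16)
#' @param temporal_window temporal lag (default 1)
#' @return list: `z` and `p` matrices shaped like the cube, plus the
#'   `degenerate` flag when the cube has zero variance
#' @export
bin_gi_star <- function(cube, centroids, spatial_k = 16L, temporal_window = 1L) {
  cen <- data.table::as.data.table(centroids)
  cc <- cen[match(cube$locations, cen$neighborhood_id)]
  nl <- length(cube$locations); np <- length(cube$periods)
  w <- build_knn(cc, k = min(spatial_k, nl - 1L))
  sp_nb <- cbind(seq_len(nl), w$nb) # self + spatial neighbors
  obs <- cube$values[cube$mask]
  n <- length(obs)
  xbar <- mean(obs)
  S <- sqrt(sum(obs^2) / n - xbar^2)
  z <- p <- matrix(NA_real_, nl, np, dimnames = dimnames(cube$values))
  if (S == 0) {
    return(list(z = z, p = p, degenerate = TRUE))
  }
  lags <- -temporal_window:temporal_window
  vals0 <- cube$values
  vals0[!cube$mask] <- 0
  for (t in seq_len(np)) {
    ts <- t + lags
    ts <- ts[ts >= 1L & ts <= np]
    # per-location sums over the spatiotemporal neighborhood
    lag_sum <- rowSums(matrix(vals0[sp_nb, ts], nrow = nl))
    Wi <- rowSums(matrix(cube$mask[sp_nb, ts], nrow = nl))
    ok <- cube$mask[, t] & Wi > 0
    denom <- S * sqrt(pmax(0, (n * Wi - Wi^2)) / (n - 1))
    zt <- ifelse(denom > 0, (lag_sum - xbar * Wi) / denom, NA_real_)
    z[ok, t] <- zt[ok]
    p[ok, t] <- 2 * stats::pnorm(-abs(zt[ok]))
  }
  list(z = z, p = p, degenerate = FALSE)
}

#' FDR-corrected hot/cold indicators for cube bins
#'
#' Benjamini-Hochberg step-up over all observed bins jointly; a bin is
#' "hot" when rejected with z > 0, "cold" when rejected with z < 0,
#' otherwise "neither".
#'
#' @param z,p bin matrices from [bin_gi_star()]
#' @param alpha FDR level (default 0.05)
#' @return character matrix of "hot"/"cold"/"neither" (NA where unobserved)
#' @export
fdr_adjust <- function(z, p, alpha = 0.05) {
  ind <- matrix(NA_character_, nrow(p), ncol(p), dimnames = dimnames(p))
  obs <- !is.na(p)
  padj <- stats::p.adjust(p[obs], method = "BH")
  rej <- padj <= alpha
  lab <- rep("neither", sum(obs))
  lab[rej & z[obs] > 0] <- "hot"
  lab[rej & z[obs] < 0] <- "cold"
  ind[obs] <- lab
  ind
}

#' Mann-Kendall trend test
#'
#' `S = sum_{i<j} sign(x_j - x_i)`, tie-corrected variance
#' `Var(S) = (n(n-1)(2n+5) - sum_t t(t-1)(2t+5)) / 18`, continuity-corrected
#' `z = (S - 1)/sqrt(Var)` for S > 0, 0 for S = 0, `(S + 1)/sqrt(Var)` for
#' S < 0, two-sided p. Series with fewer than 4 observed values (or
#' constant series) get direction "none".
#'
#' @param series numeric series (NAs dropped)
#' @param alpha_trend two-sided significance level for the direction call
#' @return list: S, var_S, z, p, direction in \{increasing, decreasing,
#'   none\}, n
#' @export
mann_kendall <- function(series, alpha_trend = 0.05) {
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 4L) {
    return(list(S = NA_real_, var_S = NA_real_, z = NA_real_, p = NA_real_,
                direction = "none", n = n))
  }
  S <- 0
  for (i in seq_len(n - 1L)) {
    S <- S + sum(sign(x[(i + 1L):n] - x[i]))
  }
  tie_counts <- table(x)
  tie_counts <- tie_counts[tie_counts > 1L]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(tie_counts * (tie_counts - 1) * (2 * tie_counts + 5))) / 18
  if (var_S <= 0) {
    return(list(S = S, var_S = var_S, z = 0, p = 1, direction = "none", n = n))
  }
  z <- if (S > 0) (S - 1) / sqrt(var_S) else if (S < 0) (S + 1) / sqrt(var_S) else 0
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (p < alpha_trend && z > 0) "increasing"
               else if (p < alpha_trend && z < 0) "decreasing" else "none"
  list(S = S, var_S = var_S, z = z, p = p, direction = direction, n = n)
}

#' Classify one location's space-time trajectory
#'
#' Applies the 17-category rule table to the location's post-FDR hot/cold
#' indicator series (observed periods only) and its intensity trend. Hot
#' rules are evaluated in a fixed order; the mirrored cold rules are
#' evaluated only when no hot rule fires. For the cold family the trend
#' direction is mirrored: cold intensity grows as z-scores decrease.
#'
#' @param indicators character vector over observed periods: "hot",
#'   "cold" or "neither"
#' @param trend_direction "increasing", "decreasing" or "none" (from
#'   [mann_kendall()] on the location's bin z-scores)
#' @param run_threshold fraction of periods for the persistent-family
#'   rules (default 0.90)
#' @param historical_threshold fraction for the Historical rule
#'   (default 0.50)
#' @return a single category label from [ehsa_categories()]
#' @export
classify_location <- function(indicators, trend_direction,
                              run_threshold = 0.90,
                              historical_threshold = 0.50) {
  ind <- indicators[!is.na(indicators)]
  P <- length(ind)
  if (P < 2L) return("no_pattern")
  one_family <- function(hot, cold, trend_inc, trend_dec, suffix) {
    nh <- sum(hot)
    frac <- nh / P
    final <- hot[P]
    prev_hot <- if (P > 1L) any(hot[seq_len(P - 1L)]) else FALSE
    # final uninterrupted run length
    run <- 0L
    for (t in P:1L) { if (hot[t]) run <- run + 1L else break }
    lab <- NULL
    if (final && !prev_hot) lab <- "new"
    else if (run >= 2L && nh == run && frac < run_threshold) lab <- "consecutive"
    else if (frac >= run_threshold && trend_inc) lab <- "intensifying"
    else if (frac >= run_threshold && !trend_inc && !trend_dec) lab <- "persistent"
    else if (frac >= run_threshold && trend_dec) lab <- "diminishing"
    else if (final && frac < run_threshold && sum(cold) == 0L) lab <- "sporadic"
    else if (final && frac < run_threshold && sum(cold) >= 1L) lab <- "oscillating"
    else if (!final && frac >= historical_threshold) lab <- "historical"
    if (is.null(lab)) NULL else paste0(lab, "_", suffix)
  }
  inc <- identical(trend_direction, "increasing")
  dec <- identical(trend_direction, "decreasing")
  hot <- ind == "hot"; cold <- ind == "cold"
  lab <- one_family(hot, cold, inc, dec, "hot")
  if (is.null(lab)) lab <- one_family(cold, hot, dec, inc, "cold")
  if (is.null(lab)) lab <- "no_pattern"
  lab
}

#' Emerging hot spot analysis of a panel
#'
#' Composition of [build_cube()], [bin_gi_star()], [fdr_adjust()],
#' [mann_kendall()] and [classify_location()]. Locations observed in fewer
#' than 2 periods are labeled no_pattern and flagged.
#'
#' @param panel smoothed panel with neighborhood_id, period and `value`
#' @param centroids data.frame with neighborhood_id, x, y
#' @param value value column (default "sebs_rate")
#' @param spatial_k spatial neighbors (default 16)
#' @param temporal_window temporal lag (default 1)
#' @param alpha FDR level for bin indicators
#' @param alpha_trend significance level of the trend direction
#' @param run_threshold,historical_threshold rule-table thresholds
#' @return list of class `ehsa_result`: `locations` (data.table with
#'   category, n_hot, n_cold, mk_S, mk_z, mk_p, n_periods_observed,
#'   flagged), `by_category_period` (mean value per category x period),
#'   `cube`, `bins` (z, p, indicator matrices)
#' @export
ehsa <- function(panel, centroids, value = "sebs_rate", spatial_k = 16L,
                 temporal_window = 1L, alpha = 0.05, alpha_trend = 0.05,
                 run_threshold = 0.90, historical_threshold = 0.50) {
  cube <- build_cube(panel, value = value)
  bins <- bin_gi_star(cube, centroids, spatial_k = spatial_k,
                      temporal_window = temporal_window)
  nl <- length(cube$locations)
  if (isTRUE(bins$degenerate)) {
    indic <- matrix(ifelse(cube$mask, "neither", NA_character_),
                    nl, length(cube$periods), dimnames = dimnames(cube$values))
  } else {
    indic <- fdr_adjust(bins$z, bins$p, alpha = alpha)
  }
  cat_out <- character(nl)
  mk_S <- mk_z <- mk_p <- rep(NA_real_, nl)
  n_hot <- n_cold <- n_obs <- integer(nl)
  for (i in seq_len(nl)) {
    obs_t <- which(cube$mask[i, ])
    n_obs[i] <- length(obs_t)
    ind_i <- indic[i, obs_t]
    n_hot[i] <- sum(ind_i == "hot"); n_cold[i] <- sum(ind_i == "cold")
    mk <- mann_kendall(bins$z[i, obs_t], alpha_trend = alpha_trend)
    mk_S[i] <- mk$S; mk_z[i] <- mk$z; mk_p[i] <- mk$p
    cat_out[i] <- if (length(obs_t) < 2L) "no_pattern" else
      classify_location(ind_i, mk$direction,
                        run_threshold = run_threshold,
                        historical_threshold = historical_threshold)
  }
  locations <- data.table::data.table(
    neighborhood_id = cube$locations, category = cat_out,
    n_hot = n_hot, n_cold = n_cold, mk_S = mk_S, mk_z = mk_z, mk_p = mk_p,
    n_periods_observed = n_obs, flagged = n_obs < 2L)
  # per-category mean value by period (the temporal-evolution surface)
  long <- data.table::data.table(
    neighborhood_id = rep(cube$locations, length(cube$periods)),
    period = rep(cube$periods, each = nl),
    value = as.vector(cube$values))
  long <- long[!is.na(value)]
  long[, category := locations$category[match(neighborhood_id,
                                              locations$neighborhood_id)]]
  by_cat <- long[, .(mean_value = mean(value), n = .N),
                 by = .(category, period)]
  data.table::setorder(by_cat, category, period)
  structure(list(locations = locations, by_category_period = by_cat,
                 cube = cube, bins = c(bins, list(indicator = indic))),
            class = "ehsa_result")
}
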