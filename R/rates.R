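# Neighborhood x biennial-period participation panel: aggregation of
# geocoded invitations and spatial empirical Bayes smoothing (SEBS) of the
# small-area rates. Rates are on the percent scale (participants /
# invitations * 100).

#' Assign an invitation year to its biennial period
#'
#' Each biennial period is labeled by its even year: an odd year maps to
#' the following even year (2003 -> "2004"), an even year to itself.
#'
#' @param year integer invitation year(s)
#' @param period_labels ordered even-year labels defining the study window
#' @return integer period label; years outside the window are `NA` with the
#'   excluded count in `attr(, "excluded")`
#' @export
assign_period <- function(year, period_labels) {
  lab <- ifelse(year %% 2 == 0, year, year + 1)
  out <- ifelse(lab %in% period_labels, lab, NA_integer_)
  n_out <- sum(is.na(out))
  if (n_out > 0) {
    message(n_out, " invitation(s) outside the study window excluded")
  }
  structure(as.integer(out), excluded = n_out)
}

#' Assign points to neighborhoods
#'
#' Points inside a polygon get that polygon's id; points outside all
#' polygons get the nearest polygon by boundary distance; points on a
#' shared boundary of several polygons are assigned uniformly at random
#' among them (seeded, to prevent duplication).
#'
#' @param points data.frame with x, y
#' @param polygons list of closed polygon rings, names/positions = ids
#' @param rng_seed seed for boundary ties
#' @param centroids optional matrix of polygon centroids (computed if NULL)
#' @return integer vector of polygon indices
#' @export
assign_neighborhood <- function(points, polygons, rng_seed = 1L,
                                centroids = NULL) {
  assert_that(length(polygons) > 0L, "assign_neighborhood(): no polygons")
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (!is.matrix(p) || nrow(p) < 4L || any(!is.finite(p)))
      stopf("geometry error: invalid polygon %d", i)
  }
  if (is.null(centroids))
    centroids <- t(vapply(polygons, polygon_centroid, numeric(2)))
  px <- points$x; py <- points$y
  n <- length(px)
  out <- rep(NA_integer_, n)
  kq <- min(8L, length(polygons))
  kn <- FNN::get.knnx(centroids, cbind(px, py), k = kq)
  set.seed(derive_seed(rng_seed, 90L))
  unresolved <- integer(0)
  for (i in seq_len(n)) {
    hits <- integer(0); on_edge <- integer(0)
    for (j in kn$nn.index[i, ]) {
      s <- point_in_poly(px[i], py[i], polygons[[j]])
      if (s == 1L) hits <- c(hits, j)
      else if (s >= 2L) on_edge <- c(on_edge, j)
    }
    if (length(hits) >= 1L) {
      out[i] <- hits[1]
    } else if (length(on_edge) == 1L) {
      out[i] <- on_edge[1]
    } else if (length(on_edge) > 1L) {
      out[i] <- on_edge[sample.int(length(on_edge), 1L)] # seeded tie rule
    } else {
      unresolved <- c(unresolved, i)
    }
  }
  # outside every candidate polygon: full containment scan (the containing
  # polygon's centroid may not be among the k nearest), then nearest boundary
  for (i in unresolved) {
    status <- vapply(polygons, function(p)
      point_in_poly(px[i], py[i], p), integer(1))
    if (any(status == 1L)) {
      out[i] <- which(status == 1L)[1]
    } else if (any(status >= 2L)) {
      edge <- which(status >= 2L)
      out[i] <- if (length(edge) == 1L) edge else
        edge[sample.int(length(edge), 1L)]
    } else {
      d <- vapply(polygons, function(p)
        point_boundary_distance(px[i], py[i], p), numeric(1))
      out[i] <- which.min(d)
    }
  }
  out
}

#' Aggregate invitations to a neighborhood x period panel
#'
#' @param invitations data.frame with `neighborhood_id`, `period`,
#'   `participated` in \{0, 1\}
#' @return data.table: neighborhood_id, period, n (invitations), o
#'   (participants), raw_rate = 100 o / n. Cells with no invitations are
#'   absent (missing, not zero).
#' @export
aggregate_invitations <- function(invitations) {
  inv <- data.table::as.data.table(invitations)
  assert_that(all(inv$participated %in% c(0L, 1L)),
              "schema error: participated must be 0/1")
  panel <- inv[, .(n = .N, o = sum(participated)),
               by = .(neighborhood_id, period)]
  panel[, raw_rate := 100 * o / n]
  data.table::setorder(panel, period, neighborhood_id)
  panel[]
}

#' Spatial empirical Bayes smoothing of panel rates
#'
#' For each cell the reference rate is the pooled rate of the unit's
#' window (itself plus its `k` nearest neighbors among units observed in
#' the same period, by centroid distance). With window pooled rate
#' `m_i = sum(o_j) / sum(n_j)`, local variance
#' `v_i = sum(n_j (r_j - m_i)^2) / sum(n_j) - m_i / (sum(n_j) / |J_i|)`
#' floored at 0, and shrinkage weight `w_i = v_i / (v_i + m_i / n_i)`,
#' the smoothed proportion is `m_i + w_i (r_i - m_i)`, reported x 100.
#' The smoothed rate always lies between the raw rate and the window rate.
#'
#' @param panel an [aggregate_invitations()] panel
#' @param centroids data.frame with neighborhood_id, x, y
#' @param k number of nearest neighbors in the smoothing window (default 8)
#' @return the panel with an added `sebs_rate` column
#' @export
sebs_smooth <- function(panel, centroids, k = 8L) {
  panel <- data.table::as.data.table(panel)
  cen <- data.table::as.data.table(centroids)
  out <- vector("list", length(unique(panel$period)))
  oi <- 0L
  for (per in sort(unique(panel$period))) {
    sub <- panel[period == per & n > 0]
    cc <- cen[match(sub$neighborhood_id, cen$neighborhood_id)]
    kk <- min(k, nrow(sub) - 1L)
    windows <- if (kk >= 1L) {
      nn <- FNN::get.knn(as.matrix(cc[, .(x, y)]), k = kk)$nn.index
      cbind(seq_len(nrow(sub)), nn)
    } else matrix(seq_len(nrow(sub)), ncol = 1L)
    r <- sub$o / sub$n
    theta <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      J <- windows[i, ]
      nj <- sub$n[J]; oj <- sub$o[J]; rj <- r[J]
      m <- sum(oj) / sum(nj)
      v <- sum(nj * (rj - m)^2) / sum(nj) - m / (sum(nj) / length(J))
      v <- max(v, 0)
      w <- if (v + m / sub$n[i] == 0) 0 else v / (v + m / sub$n[i])
      theta[i] <- m + w * (r[i] - m)
    }
    sub[, sebs_rate := 100 * theta]
    oi <- oi + 1L
    out[[oi]] <- sub
  }
  res <- data.table::rbindlist(out[seq_len(oi)])
  data.table::setorder(res, period, neighborhood_id)
  res[]
}
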