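# Planar geometry helpers for polygon neighborhoods (coordinates in meters).
# Voronoi tessellation is delegated to deldir; containment to sp. The only
# hand-written primitives are point-to-segment distance (needed for
# nearest-polygon assignment) and the polygon area/centroid formulas.

#' Voronoi tessellation of seed points clipped to a rectangle
#'
#' @param pts two-column matrix of seed coordinates
#' @param bbox numeric c(xmin, xmax, ymin, ymax)
#' @return list of polygons, each a closed two-column matrix (last row = first)
#' @keywords internal
voronoi_polygons <- function(pts, bbox) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], rw = bbox, suppressMsge = TRUE)
  tl <- deldir::tile.list(dd)
  lapply(tl, function(t) {
    p <- cbind(t$x, t$y)
    rbind(p, p[1, , drop = FALSE])
  })
}

#' Signed area of a closed polygon ring
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Area-weighted centroid of a closed polygon ring
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(poly[-n, , drop = FALSE]))
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

#' Minimum distance from points to a polygon boundary
#'
#' @param px,py point coordinates (vectors)
#' @param poly closed polygon ring
#' @return vector of distances (0 is not special-cased: interior points get
#'   their distance to the boundary, callers test containment separately)
#' @keywords internal
point_boundary_distance <- function(px, py, poly) {
  n <- nrow(poly) - 1L
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    bx <- poly[i + 1L, 1]; by <- poly[i + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Point-in-polygon test (wrapper over sp)
#'
#' @return integer vector: 0 outside, 1 inside, 2 on edge, 3 on vertex
#' @keywords internal
point_in_poly <- function(px, py, poly) {
  sp::point.in.polygon(px, py, poly[, 1], poly[, 2])
}

#' Sample points uniformly inside a polygon by bbox rejection
#' @keywords internal
sample_in_polygon <- function(n, poly) {
  out <- matrix(NA_real_, 0L, 2L)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  guard <- 0L
  while (nrow(out) < n && guard < 1000L) {
    m <- max(2L * (n - nrow(out)), 8L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_poly(px, py, poly) > 0L
    out <- rbind(out, cbind(px[keep], py[keep]))
    guard <- guard + 1L
  }
  if (nrow(out) < n) { # degenerate sliver: fall back to centroid
    cen <- polygon_centroid(poly)
    out <- rbind(out, matrix(rep(cen, n - nrow(out)), ncol = 2, byrow = TRUE))
  }
  out[seq_len(n), , drop = FALSE]
}
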