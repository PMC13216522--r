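labels9 <- seq(2004L, 2020L, by = 2L)

test_that("invitation years map to even-labeled biennial periods", {
  expect_equal(as.integer(assign_period(2003L, labels9)), 2004L)
  expect_equal(as.integer(assign_period(2004L, labels9)), 2004L)
  expect_equal(as.integer(assign_period(2019L, labels9)), 2020L)
  suppressMessages({
    out <- assign_period(c(2001L, 2010L), labels9)
  })
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "excluded"), 1L)
})

test_that("points are assigned to containing or nearest neighborhoods", {
  # two unit squares side by side, plus an isolated one far away
  sq <- function(x0, y0) {
    m <- rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1), c(x0, y0 + 1))
    rbind(m, m[1, ])
  }
  polys <- list(sq(0, 0), sq(1, 0), sq(5, 5))

  pts <- data.frame(x = c(0.5, 1.5, 5.5), y = c(0.5, 0.5, 5.5))
  expect_equal(assign_neighborhood(pts, polys), c(1L, 2L, 3L))

  # outside everything: nearest boundary wins (10 units right of square 2)
  far <- data.frame(x = 2.6, y = 0.5)
  expect_equal(assign_neighborhood(far, polys), 2L)

  # point on the shared edge of squares 1 and 2: seeded, reproducible
  edge <- data.frame(x = 1, y = 0.5)
  a <- assign_neighborhood(edge, polys, rng_seed = 3L)
  b <- assign_neighborhood(edge, polys, rng_seed = 3L)
  expect_identical(a, b)
  expect_true(a %in% c(1L, 2L))

  bad <- list(rbind(c(0, 0), c(1, NA)))
  expect_error(assign_neighborhood(pts, bad), "polygon 1")
})

test_that("aggregation conserves invitations and flags empty cells", {
  inv <- data.table::data.table(
    neighborhood_id = c(1L, 1L, 1L, 2L),
    period = c(2004L, 2004L, 2004L, 2006L),
    participated = c(1L, 1L, 0L, 1L))
  panel <- aggregate_invitations(inv)
  expect_equal(sum(panel$n), nrow(inv))
  cell <- panel[neighborhood_id == 1L & period == 2004L]
  expect_equal(cell$o, 2L)
  expect_equal(cell$raw_rate, 100 * 2 / 3)
  # absent cell is missing, not zero
  expect_equal(nrow(panel[neighborhood_id == 2L & period == 2004L]), 0L)
  # order invariance
  panel2 <- aggregate_invitations(inv[c(4, 2, 1, 3)])
  expect_identical(panel, panel2)
  expect_error(aggregate_invitations(data.table::data.table(
    neighborhood_id = 1L, period = 2004L, participated = 2L)), "0/1")
})

test_that("smoothing shrinks toward the window rate and stays between", {
  # 9-unit toy window on a 3x3 grid: hand-set counts, formula oracle
  cen <- data.table::data.table(
    neighborhood_id = 1:9,
    x = rep(1:3, 3), y = rep(1:3, each = 3))
  set.seed(8)
  panel <- data.table::data.table(
    neighborhood_id = 1:9, period = 2004L,
    n = c(12L, 40L, 7L, 55L, 20L, 33L, 9L, 61L, 25L),
    o = c(5L, 15L, 2L, 30L, 9L, 10L, 4L, 28L, 11L))
  panel[, raw_rate := 100 * o / n]
  sm <- sebs_smooth(panel, cen, k = 8L)
  for (i in 1:9) {
    # window = all 9 units (k = 8 on 9 units); self first in the oracle
    ord <- c(i, setdiff(1:9, i))
    expect_equal(sm$sebs_rate[sm$neighborhood_id == i],
                 oracle_sebs_cell(i, panel$n[ord], panel$o[ord], panel$n[i]),
                 tolerance = 1e-12)
  }

  # all rates equal: full shrinkage to the common value
  flat <- data.table::data.table(neighborhood_id = 1:9, period = 2004L,
                                 n = rep(50L, 9), o = rep(20L, 9))
  flat[, raw_rate := 100 * o / n]
  smf <- sebs_smooth(flat, cen, k = 8L)
  expect_equal(smf$sebs_rate, rep(40, 9))

  # huge denominator: smoothed rate converges to the raw rate
  big <- data.table::copy(panel)
  big[neighborhood_id == 5L, `:=`(n = 1000000L, o = 450000L)]
  big[, raw_rate := 100 * o / n]
  smb <- sebs_smooth(big, cen, k = 8L)
  expect_equal(smb[neighborhood_id == 5L]$sebs_rate, 45, tolerance = 1e-3)
})

test_that("smoothed rates satisfy betweenness on random panels", {
  set.seed(21)
  for (rep in 1:25) {
    nu <- 30L
    cen <- data.table::data.table(neighborhood_id = 1:nu,
                                  x = runif(nu), y = runif(nu))
    n <- sample(5:200, nu, replace = TRUE)
    o <- rbinom(nu, n, runif(1, 0.1, 0.9))
    panel <- data.table::data.table(neighborhood_id = 1:nu, period = 2004L,
                                    n = n, o = o, raw_rate = 100 * o / n)
    sm <- sebs_smooth(panel, cen, k = 8L)
    # recompute each cell's window rate to bound theta
    nn <- FNN::get.knn(as.matrix(cen[, .(x, y)]), k = 8L)$nn.index
    for (i in 1:nu) {
      J <- c(i, nn[i, ])
      m <- 100 * sum(o[J]) / sum(n[J])
      r <- 100 * o[i] / n[i]
      expect_gte(sm$sebs_rate[sm$neighborhood_id == i], min(r, m) - 1e-9)
      expect_lte(sm$sebs_rate[sm$neighborhood_id == i], max(r, m) + 1e-9)
    }
  }
})

test_that("shrinkage weight is nondecreasing in the cell denominator", {
  # fixed window moments, varying n_i
  v <- 0.004; m <- 0.4
  w <- function(n_i) v / (v + m / n_i)
  ns <- c(5, 10, 50, 200, 1000)
  expect_true(all(diff(w(ns)) > 0))
})
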