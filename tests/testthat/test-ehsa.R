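make_panel <- function(values, locations, periods) {
  # values: locations x periods matrix possibly with NA (cell absent)
  dt <- data.table::CJ(neighborhood_id = locations, period = periods)
  dt[, sebs_rate := as.vector(t(values))[
    (match(neighborhood_id, locations) - 1L) * length(periods) +
      match(period, periods)]]
  dt[!is.na(sebs_rate)]
}

test_that("the space-time cube has full capacity and an honest mask", {
  # the real study's dimensions: 2121 locations x 9 periods
  set.seed(2)
  big <- data.table::CJ(neighborhood_id = 1:2121,
                        period = seq(2004L, 2020L, by = 2L))
  big[, sebs_rate := runif(.N, 20, 60)]
  cube <- build_cube(big)
  expect_equal(cube$capacity, 19089L)
  expect_equal(dim(cube$values), c(2121L, 9L))

  # missing cells are masked, not imputed
  small <- big[1:500][!(neighborhood_id == 3L & period %in% c(2006L, 2010L))]
  cube2 <- build_cube(small)
  expect_equal(sum(!cube2$mask[cube2$locations == 3L, ]), 2L)
  expect_true(all(is.na(cube2$values[!cube2$mask])))

  # permuting input rows changes nothing
  cube3 <- build_cube(small[sample(.N)])
  expect_identical(cube2, cube3)

  expect_error(build_cube(big[period == 2004L]), ">= 2 periods")
})

test_that("bin Gi* agrees with a brute-force spatiotemporal oracle", {
  set.seed(6)
  nl <- 20L; np <- 5L
  cen <- data.table::data.table(neighborhood_id = 1:nl,
                                x = runif(nl), y = runif(nl))
  vals <- matrix(rnorm(nl * np, 50, 8), nl, np)
  vals[3, 2] <- NA; vals[11, 5] <- NA # masked bins
  panel <- make_panel(vals, 1:nl, seq(2004L, 2012L, 2L))
  cube <- build_cube(panel)
  res <- bin_gi_star(cube, cen, spatial_k = 4L, temporal_window = 1L)

  # oracle: explicit double loop over every bin and its neighborhood
  nb <- FNN::get.knn(as.matrix(cen[, .(x, y)]), k = 4L)$nn.index
  obs <- cube$values[cube$mask]
  n <- length(obs); xbar <- mean(obs)
  S <- sqrt(sum(obs^2) / n - xbar^2)
  for (i in 1:nl) {
    for (t in 1:np) {
      if (!cube$mask[i, t]) {
        expect_true(is.na(res$z[i, t]))
        next
      }
      wsum <- 0; Wi <- 0
      for (j in c(i, nb[i, ])) {
        for (tt in (t - 1):(t + 1)) {
          if (tt >= 1 && tt <= np && cube$mask[j, tt]) {
            wsum <- wsum + cube$values[j, tt]
            Wi <- Wi + 1
          }
        }
      }
      zo <- (wsum - xbar * Wi) / (S * sqrt((n * Wi - Wi^2) / (n - 1)))
      expect_equal(res$z[i, t], zo, tolerance = 1e-10)
    }
  }

  # constant cube: degenerate, no bins claimed
  flatpanel <- make_panel(matrix(42, nl, np), 1:nl, seq(2004L, 2012L, 2L))
  flat <- bin_gi_star(build_cube(flatpanel), cen, spatial_k = 4L)
  expect_true(flat$degenerate)

  # an elevated block spanning three periods forces positive z inside it
  vals2 <- matrix(40, nl, np)
  block_units <- c(1L, nb[1, ])
  vals2[block_units, 2:4] <- 70
  res2 <- bin_gi_star(build_cube(make_panel(vals2, 1:nl,
                                            seq(2004L, 2012L, 2L))),
                      cen, spatial_k = 4L)
  expect_true(all(res2$z[block_units, 2:4] > 0))
})

test_that("FDR correction follows Benjamini-Hochberg step-up", {
  z <- matrix(c(3, 2.3, -0.1), 1, 3)
  p <- matrix(c(0.001, 0.02, 0.9), 1, 3)
  ind <- fdr_adjust(z, p, alpha = 0.05)
  expect_equal(as.vector(ind), c("hot", "hot", "neither"))

  # all p = 1: nothing rejected
  expect_true(all(fdr_adjust(z, matrix(1, 1, 3)) == "neither"))

  # duplicating every p-value preserves decisions (BH scale property)
  set.seed(10)
  p1 <- matrix(runif(40)^2, 4, 10)
  z1 <- matrix(rnorm(40), 4, 10)
  dup_ind <- fdr_adjust(cbind(z1, z1), cbind(p1, p1))
  one_ind <- fdr_adjust(z1, p1)
  expect_equal(dup_ind[, 1:10], one_ind)
  # and matches the hand-applied step-up oracle
  rej <- oracle_bh_reject(as.vector(p1), 0.05)
  expect_equal(as.vector(one_ind) != "neither", rej)

  # monotonicity: rejections at 0.01 are a subset of rejections at 0.05
  strict <- fdr_adjust(z1, p1, alpha = 0.01) != "neither"
  loose <- fdr_adjust(z1, p1, alpha = 0.05) != "neither"
  expect_true(all(loose[strict]))
})

test_that("Mann-Kendall statistics match the stated formulas", {
  mk <- mann_kendall(1:9)
  expect_equal(mk$S, 36)              # n(n-1)/2 concordant pairs
  expect_equal(mk$var_S, 92)          # 9 * 8 * 23 / 18
  expect_equal(mk$z, 35 / sqrt(92), tolerance = 1e-12)
  expect_equal(mk$direction, "increasing")

  rev <- mann_kendall(9:1)
  expect_equal(rev$S, -36)
  expect_equal(rev$z, -mk$z, tolerance = 1e-12)

  expect_equal(mann_kendall(rep(2, 7))$direction, "none")
  expect_equal(mann_kendall(c(1, 2, 3))$direction, "none") # too short

  # tie correction against the pair-enumeration oracle
  set.seed(12)
  for (rep in 1:30) {
    x <- sample(1:4, 8, replace = TRUE)
    mk <- mann_kendall(x)
    or <- oracle_mk(x)
    expect_equal(mk$S, or$S)
    expect_equal(mk$var_S, or$var_S)
    expect_equal(mk$z, or$z, tolerance = 1e-12)
  }
})

test_that("Mann-Kendall is exact on all permutations of short series", {
  for (n in 4:6) {
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == n), ,
                   drop = FALSE]
    for (r in seq_len(nrow(perms))) {
      mk <- mann_kendall(perms[r, ])
      or <- oracle_mk(perms[r, ])
      expect_identical(mk$S, or$S + 0) # numeric equality, no tolerance
      expect_identical(mk$var_S, or$var_S)
      expect_equal(mk$z, or$z, tolerance = 0)
    }
  }
})

test_that("trajectory classification reproduces the rule table", {
  P9 <- rep("hot", 9)
  expect_equal(classify_location(P9, "increasing"), "intensifying_hot")
  expect_equal(classify_location(P9, "none"), "persistent_hot")
  expect_equal(classify_location(P9, "decreasing"), "diminishing_hot")

  new9 <- c(rep("neither", 8), "hot")
  expect_equal(classify_location(new9, "none"), "new_hot")

  hist9 <- c(rep("hot", 5), rep("neither", 4))
  expect_equal(classify_location(hist9, "none"), "historical_hot")

  cons9 <- c(rep("neither", 6), rep("hot", 3))
  expect_equal(classify_location(cons9, "none"), "consecutive_hot")

  spor9 <- c("hot", "neither", "hot", "neither", "neither", "hot",
             "neither", "neither", "hot")
  expect_equal(classify_location(spor9, "none"), "sporadic_hot")

  osc9 <- c("cold", "neither", "hot", "neither", "neither", "hot",
            "neither", "neither", "hot")
  expect_equal(classify_location(osc9, "none"), "oscillating_hot")

  expect_equal(classify_location(rep("neither", 9), "none"), "no_pattern")
  expect_equal(classify_location(rep("cold", 9), "decreasing"),
               "intensifying_cold")

  # the label space is exactly the 17 documented categories
  expect_length(ehsa_categories(), 17L)
  expect_equal(sum(grepl("_hot$", ehsa_categories())), 8L)
  expect_equal(sum(grepl("_cold$", ehsa_categories())), 8L)
})

test_that("classifier is total, exclusive and oracle-equivalent (length 5)", {
  states <- c("hot", "cold", "neither")
  grids <- expand.grid(rep(list(states), 5), stringsAsFactors = FALSE)
  trends <- c("increasing", "decreasing", "none")
  for (tr in trends) {
    for (r in seq_len(nrow(grids))) {
      ind <- unlist(grids[r, ], use.names = FALSE)
      got <- classify_location(ind, tr)
      expect_true(got %in% ehsa_categories())
      expect_identical(got, oracle_classify(ind, tr),
                       info = paste(paste(ind, collapse = ","), tr))
    }
  }
})

test_that("the full analysis recovers planted space-time structure", {
  canton <- tiny_canton()
  panel <- sebs_smooth(aggregate_invitations(canton$invitations),
                       canton$neighborhoods, k = 8L)
  res <- ehsa(panel, canton$neighborhoods)
  expect_s3_class(res, "ehsa_result")
  expect_true(all(res$locations$category %in% ehsa_categories()))

  # determinism: identical category map on a second run
  res2 <- ehsa(panel, canton$neighborhoods)
  expect_identical(res$locations, res2$locations)

  # category-by-period surface covers every emitted category
  expect_setequal(unique(res$by_category_period$category),
                  unique(res$locations$category))
})
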