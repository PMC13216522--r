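test_that("canton generation is deterministic and validates its spec", {
  spec <- canton_spec(n_neighborhoods = 40L, n_women = 1500L,
                      period_labels = seq(2004L, 2010L, 2L), rng_seed = 7L)
  a <- simulate_canton(spec)
  b <- simulate_canton(spec)
  expect_identical(a$neighborhoods, b$neighborhoods)
  expect_identical(a$registry, b$registry)
  expect_identical(a$invitations, b$invitations)

  expect_error(canton_spec(period_labels = c(2004L, 2005L)), "even years")
  expect_error(canton_spec(period_labels = c(2004L, 2008L)), "step 2")
  expect_error(canton_spec(n_neighborhoods = 10L), "n_neighborhoods")
  expect_error(canton_spec(effect_deprivation = Inf), "finite")
})

test_that("the generated canton has the promised spatial structure", {
  canton <- tiny_canton()
  nb <- canton$neighborhoods
  L <- canton$spec$canton_size

  expect_true(all(nb$deprivation >= 0 & nb$deprivation <= 1))
  expect_true(all(canton$network$edges$length > 0))

  # deprivation is positively spatially autocorrelated (Moran-type)
  w <- build_knn(nb, k = 5L)
  d <- nb$deprivation - mean(nb$deprivation)
  lag <- rowMeans(matrix(d[w$nb], nrow = nrow(nb)))
  moran <- sum(d * lag) / sum(d^2)
  expect_gt(moran, 0.2)

  # centers cluster in the urban core
  core_d <- sqrt((canton$centers$x - L / 2)^2 + (canton$centers$y - L / 2)^2)
  expect_lt(mean(core_d), L / 3)

  # the registry covers every woman's address (building and coordinates)
  expect_true(all(canton$women$building_id %in% canton$registry$building_id))
  expect_identical(canton$women$x,
                   canton$registry$x[canton$women$building_id])

  # every woman's address geocodes into her own neighborhood's polygon
  samp <- canton$women[sample(.N, 200L)]
  inside <- vapply(seq_len(nrow(samp)), function(i) {
    poly <- canton$polygons[[samp$neighborhood_id[i]]]
    sp::point.in.polygon(samp$x[i], samp$y[i], poly[, 1], poly[, 2]) > 0
  }, logical(1))
  expect_true(all(inside))
})

test_that("invitations follow the biennial 50-74 eligibility rule", {
  canton <- tiny_canton()
  inv <- canton$invitations
  spec <- canton$spec
  y1 <- spec$period_labels[1]

  # conservation: one row per woman per eligible period
  ages <- canton$women$age_at_start
  eligible_periods <- vapply(ages, function(a) {
    sum(a + (spec$period_labels - y1) >= 50 &
        a + (spec$period_labels - y1) <= 74)
  }, numeric(1))
  expect_equal(nrow(inv), sum(eligible_periods))
  expect_equal(attr(inv, "excluded_women"), sum(eligible_periods == 0))

  # a woman aged 49 at study start is invited only from the period she
  # turns 50
  w49 <- canton$women[age_at_start == 49L]$woman_id
  if (length(w49)) {
    first_inv <- inv[woman_id %in% w49, min(period), by = woman_id]$V1
    expect_true(all(first_inv == y1 + 2L))
  }
  # age groups are the five 5-year categories
  expect_true(all(inv$age_group %in%
                    c("50-54", "55-59", "60-64", "65-69", "70-74")))
  # invitation years fall inside their biennium
  expect_true(all(inv$invitation_year %in% c(inv$period, inv$period - 1L)))
})

test_that("degenerate and planted-shift limits behave as documented", {
  # impossible participation: all rates zero
  spec0 <- canton_spec(n_neighborhoods = 30L, n_women = 500L,
                       period_labels = c(2004L, 2006L),
                       intercept = -1e6,
                       planted_patterns = list(pattern_plan("none", 2L)),
                       rng_seed = 3L)
  c0 <- simulate_canton(spec0)
  expect_equal(sum(c0$invitations$participated), 0L)

  # a persistent hot region beats the background in every period
  spec1 <- canton_spec(
    n_neighborhoods = 60L, n_women = 6000L,
    period_labels = seq(2004L, 2012L, 2L),
    planted_patterns = list(
      pattern_plan("persistent_hot", 5L, base_shift = 1.5,
                   region_size = 10L, halo_size = 0L, anchor = "sw")),
    rng_seed = 9L)
  c1 <- simulate_canton(spec1)
  panel <- aggregate_invitations(c1$invitations)
  hot_ids <- c1$truth[trajectory == "persistent_hot", neighborhood_id]
  for (per in spec1$period_labels) {
    sub <- panel[period == per]
    hot_rate <- sub[neighborhood_id %in% hot_ids,
                    100 * sum(o) / sum(n)]
    bg_rate <- sub[!neighborhood_id %in% hot_ids,
                   100 * sum(o) / sum(n)]
    expect_gt(hot_rate, bg_rate)
  }
})

test_that("a no-pattern zero-effect canton is exchangeable across units", {
  spec <- canton_spec(n_neighborhoods = 50L, n_women = 8000L,
                      period_labels = seq(2004L, 2010L, 2L),
                      effect_deprivation = 0, effect_access = 0,
                      sd_neighborhood_period = 0,
                      planted_patterns = list(pattern_plan("none", 4L)),
                      rng_seed = 13L)
  canton <- simulate_canton(spec)
  panel <- aggregate_invitations(canton$invitations)
  p0 <- stats::plogis(spec$intercept)
  # per-cell participation counts live inside central binomial bands
  lo <- qbinom(0.0025, panel$n, p0)
  hi <- qbinom(0.9975, panel$n, p0)
  coverage <- mean(panel$o >= lo & panel$o <= hi)
  expect_gte(coverage, 0.985)
})
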