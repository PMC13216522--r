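# Synthetic canton generator: a square study region tessellated into
# irregular Voronoi neighborhoods, a spatially autocorrelated deprivation
# field, screening centers concentrated in an urban core, a perturbed-grid
# street network, a building registry, and a biennial invitation stream with
# planted spatiotemporal participation patterns. Every downstream stage of
# the pipeline can be validated against the planted truth.

#' Specification of a synthetic canton
#'
#' Bundles every parameter of the generator. Defaults define the reference
#' study conditions used throughout the package's validation runs: 400
#' neighborhoods, nine biennial periods (2004--2020), a 10 km square canton,
#' and four planted pattern regions (persistent hot, intensifying hot,
#' persistent cold, intensifying cold; each a 20-unit core with a 16-unit tapered
#' halo) against a background shaped by modest deprivation and
#' accessibility effects, with transient neighborhood-period
#' overdispersion.
#'
#' @param n_neighborhoods number of Voronoi neighborhoods (>= 25)
#' @param n_women number of women in the eligible cohort
#' @param period_labels strictly increasing even-year labels, step 2
#' @param deprivation_range range of the min-max scaled deprivation index
#' @param spatial_autocorr_scale Gaussian kernel scale (meters) of the
#'   deprivation field
#' @param effect_deprivation log-odds change in participation per unit
#'   deprivation index. Kept modest by default so the planted patterns, not
#'   the covariate field, dominate the spatial signal
#' @param effect_access log-odds change per unit accessibility score
#'   (negative: the urban core participates less, as organized programs
#'   typically observe)
#' @param intercept baseline participation log-odds (default `qlogis(0.4)`,
#'   a 40% background rate)
#' @param planted_patterns list of [pattern_plan()] objects
#' @param canton_size side length of the square canton in meters
#' @param age_range inclusive age range (at study start) from which women's
#'   ages are drawn uniformly; starting below 50 creates cohort turnover
#' @param sd_neighborhood_period standard deviation (log-odds) of the iid
#'   neighborhood-by-period random effect: transient, spatially unstructured
#'   participation fluctuations (campaign timing, local events). This gives
#'   the empirical-Bayes smoother genuine extra-binomial variance to detect,
#'   so smoothing stays minimal in well-sampled areas
#' @param sd_neighborhood standard deviation (log-odds) of a time-constant
#'   iid neighborhood random effect (persistent unmeasured heterogeneity).
#'   Default 0: persistent spatially-unstructured deviations make every
#'   location's bins temporally dependent, so with this knob on, emerging
#'   hot spot analysis legitimately categorizes many background locations
#'   (as real analyses do); keep it 0 when planted-truth recovery is the
#'   point, turn it on for sensitivity runs
#' @param n_centers number of screening centers
#' @param rng_seed master seed; all generator streams derive from it
#' @return an object of class `canton_spec`
#' @export
canton_spec <- function(n_neighborhoods = 400L,
                        n_women = 60000L,
                        period_labels = seq(2004L, 2020L, by = 2L),
                        deprivation_range = c(0, 1),
                        spatial_autocorr_scale = 1500,
                        effect_deprivation = 0.15,
                        effect_access = -0.02,
                        intercept = stats::qlogis(0.4),
                        planted_patterns = default_patterns(length(period_labels)),
                        canton_size = 10000,
                        age_range = c(48L, 74L),
                        sd_neighborhood_period = 0.5,
                        sd_neighborhood = 0,
                        n_centers = 12L,
                        rng_seed = 1L) {
  assert_that(length(n_neighborhoods) == 1L && n_neighborhoods >= 25,
              "invalid field 'n_neighborhoods': must be a single value >= 25")
  assert_that(length(period_labels) >= 2L,
              "invalid field 'period_labels': need at least two periods")
  assert_that(all(period_labels %% 2 == 0),
              "invalid field 'period_labels': labels must be even years")
  assert_that(all(diff(period_labels) == 2),
              "invalid field 'period_labels': must be strictly increasing with step 2")
  assert_that(all(is.finite(c(effect_deprivation, effect_access, intercept))),
              "invalid field 'effect sizes': must be finite")
  assert_that(deprivation_range[1] >= 0 && deprivation_range[2] <= 1 &&
                deprivation_range[1] < deprivation_range[2],
              "invalid field 'deprivation_range': must be within [0, 1]")
  P <- length(period_labels)
  for (pp in planted_patterns) {
    assert_that(inherits(pp, "pattern_plan"),
                "invalid field 'planted_patterns': entries must be pattern_plan objects")
    assert_that(length(pp$per_period_shifts) == P,
                "invalid field 'planted_patterns': per_period_shifts length %d != %d periods",
                length(pp$per_period_shifts), P)
  }
  structure(list(
    n_neighborhoods = as.integer(n_neighborhoods),
    n_women = as.integer(n_women),
    period_labels = as.integer(period_labels),
    deprivation_range = deprivation_range,
    spatial_autocorr_scale = spatial_autocorr_scale,
    effect_deprivation = effect_deprivation,
    effect_access = effect_access,
    intercept = intercept,
    planted_patterns = planted_patterns,
    canton_size = canton_size,
    age_range = as.integer(age_range),
    sd_neighborhood_period = sd_neighborhood_period,
    sd_neighborhood = sd_neighborhood,
    n_centers = as.integer(n_centers),
    rng_seed = as.integer(rng_seed)
  ), class = "canton_spec")
}

#' A planted spatiotemporal participation pattern
#'
#' Describes one contiguous region whose participation log-odds are shifted
#' by a prescribed amount in each period. The shift trajectories mirror the
#' emerging-hot-spot category definitions so that the classifier's output
#' can be compared with planted truth.
#'
#' @param trajectory one of `persistent_hot`, `intensifying_hot`,
#'   `diminishing_hot`, `new_hot`, `sporadic_hot`, `historical_hot`,
#'   `persistent_cold`, `intensifying_cold`, `none`
#' @param n_periods number of biennial periods
#' @param base_shift peak log-odds shift (sign is taken from the trajectory)
#' @param region optional explicit neighborhood ids; when `NULL` a compact
#'   region of `region_size` units is grown around `anchor` at generation time
#' @param region_size number of core neighborhoods when `region` is `NULL`
#' @param anchor one of `"sw"`, `"se"`, `"nw"`, `"ne"`, `"core"`: corner (or
#'   center) of the canton near which the region is planted
#' @param halo_size number of additional neighborhoods ringing the core
#'   that receive the shift scaled by `halo_factor`. Real participation
#'   clusters fade over space rather than ending at a cliff; the default 16
#'   matches the one-shell margin a k = 16 local statistic integrates over,
#'   so the unit-level ground truth stays well defined at the cluster edge
#' @param halo_factor shift multiplier in the halo (default 0.5)
#' @param per_period_shifts optional explicit log-odds shift per period,
#'   overriding the trajectory-derived default
#' @return an object of class `pattern_plan`
#' @export
pattern_plan <- function(trajectory, n_periods,
                         base_shift = 1.5,
                         region = NULL, region_size = 20L, anchor = "core",
                         halo_size = 16L, halo_factor = 0.5,
                         per_period_shifts = NULL) {
  trajectories <- c("persistent_hot", "intensifying_hot", "diminishing_hot",
                    "new_hot", "sporadic_hot", "historical_hot",
                    "persistent_cold", "intensifying_cold", "none")
  trajectory <- match.arg(trajectory, trajectories)
  P <- as.integer(n_periods)
  if (is.null(per_period_shifts)) {
    b <- abs(base_shift)
    shifts <- switch(trajectory,
      persistent_hot   = rep(b, P),
      intensifying_hot = seq(0.55 * b, 1.35 * b, length.out = P),
      diminishing_hot  = seq(1.35 * b, 0.55 * b, length.out = P),
      new_hot          = c(rep(0, P - 1L), b),
      sporadic_hot     = ifelse(seq_len(P) %% 2L == P %% 2L, b, 0),
      historical_hot   = c(rep(b, ceiling(P * 0.6)), rep(0, P - ceiling(P * 0.6))),
      persistent_cold  = rep(-b, P),
      intensifying_cold = seq(-0.55 * b, -1.35 * b, length.out = P),
      none             = rep(0, P)
    )
  } else {
    assert_that(length(per_period_shifts) == P,
                "invalid field 'per_period_shifts': length %d != %d periods",
                length(per_period_shifts), P)
    shifts <- as.numeric(per_period_shifts)
  }
  if (trajectory == "none") assert_that(all(shifts == 0),
    "invalid field 'per_period_shifts': trajectory 'none' requires all-zero shifts")
  structure(list(trajectory = trajectory, region = region,
                 region_size = as.integer(region_size), anchor = anchor,
                 halo_size = as.integer(halo_size), halo_factor = halo_factor,
                 base_shift = base_shift, per_period_shifts = shifts),
            class = "pattern_plan")
}

#' Default planted patterns for the reference canton
#'
#' Four balanced regions: persistent hot (south-west), intensifying hot
#' (north-east), persistent cold (south-east) and intensifying cold
#' (north-west). Hot and cold mass balance so planted patterns do not
#' shift the canton-wide mean. Peak core shift 0.8 log-odds (roughly 40%
#' to 59% participation), halved in each region's tapered halo.
#'
#' @param n_periods number of biennial periods
#' @export
default_patterns <- function(n_periods) {
  list(
    pattern_plan("persistent_hot",    n_periods, base_shift = 0.8, region_size = 20L, anchor = "sw"),
    pattern_plan("intensifying_hot",  n_periods, base_shift = 0.8, region_size = 20L, anchor = "ne"),
    pattern_plan("persistent_cold",   n_periods, base_shift = 0.8, region_size = 20L, anchor = "se"),
    pattern_plan("intensifying_cold", n_periods, base_shift = 0.8, region_size = 20L, anchor = "nw")
  )
}

anchor_point <- function(anchor, L) {
  switch(anchor,
    sw = c(0.08, 0.08) * L, se = c(0.92, 0.08) * L,
    nw = c(0.08, 0.92) * L, ne = c(0.92, 0.92) * L,
    core = c(0.5, 0.5) * L,
    stopf("invalid field 'anchor': unknown anchor '%s'", anchor))
}

#' Generate a synthetic canton
#'
#' Deterministic given `spec$rng_seed`. Produces neighborhoods (Voronoi
#' polygons with population and deprivation), screening centers clustered in
#' the urban core, a perturbed-grid street network, a building registry
#' covering every generated address, the cohort of women, and the planted
#' truth labels. Invitations are drawn separately by
#' [generate_invitations()] (and by [simulate_canton()] which does both).
#'
#' @param spec a [canton_spec()]
#' @return a list of class `synthetic_canton` with elements `neighborhoods`
#'   (data.table: id, x, y centroid, population, deprivation), `polygons`
#'   (list of closed rings), `centers`, `network` (list nodes/edges),
#'   `registry`, `women`, `truth`, and the `spec`
#' @export
generate_canton <- function(spec) {
  assert_that(inherits(spec, "canton_spec"), "generate_canton() needs a canton_spec")
  L <- spec$canton_size
  N <- spec$n_neighborhoods
  P <- length(spec$period_labels)

  # -- geometry: Voronoi tessellation of uniform seed points ----------------
  set.seed(derive_seed(spec$rng_seed, 1L))
  seeds <- cbind(stats::runif(N, 0, L), stats::runif(N, 0, L))
  polys <- voronoi_polygons(seeds, c(0, L, 0, L))
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))

  # -- deprivation: Gaussian-kernel-smoothed white noise, min-max scaled ----
  set.seed(derive_seed(spec$rng_seed, 2L))
  eps <- stats::rnorm(N)
  D2 <- as.matrix(stats::dist(cents))^2
  K <- exp(-D2 / (2 * spec$spatial_autocorr_scale^2))
  depr_raw <- as.vector(K %*% eps)
  dr <- spec$deprivation_range
  depr <- dr[1] + (dr[2] - dr[1]) *
    (depr_raw - min(depr_raw)) / (max(depr_raw) - min(depr_raw))

  # -- population: denser toward the urban core -----------------------------
  set.seed(derive_seed(spec$rng_seed, 3L))
  core <- c(0.5, 0.5) * L
  d_core <- sqrt((cents[, 1] - core[1])^2 + (cents[, 2] - core[2])^2)
  w_pop <- exp(-d_core / (L / 3)) * exp(stats::rnorm(N, 0, 0.3))
  nb_of_woman <- sample.int(N, spec$n_women, replace = TRUE, prob = w_pop)
  pop <- tabulate(nb_of_woman, nbins = N)

  # -- screening centers: urban-core placement, staggered activity ----------
  set.seed(derive_seed(spec$rng_seed, 4L))
  nc <- spec$n_centers
  cx <- pmin(0.95 * L, pmax(0.05 * L, stats::rnorm(nc, core[1], L / 8)))
  cy <- pmin(0.95 * L, pmax(0.05 * L, stats::rnorm(nc, core[2], L / 8)))
  first_act <- rep(spec$period_labels[1], nc)
  last_act <- rep(spec$period_labels[P], nc)
  if (nc >= 3L) first_act[nc] <- spec$period_labels[min(P, 4L)]       # late opener
  if (nc >= 4L) last_act[nc - 1L] <- spec$period_labels[max(1L, P - 3L)] # early closer
  centers <- data.table::data.table(
    center_id = seq_len(nc), x = cx, y = cy,
    first_active_period = first_act, last_active_period = last_act)

  # -- street network: perturbed grid ---------------------------------------
  set.seed(derive_seed(spec$rng_seed, 5L))
  ng <- 31L
  g <- L / (ng - 1L)
  gx <- rep(seq(0, L, length.out = ng), times = ng)
  gy <- rep(seq(0, L, length.out = ng), each = ng)
  jit <- function(v) pmin(L, pmax(0, v + stats::runif(length(v), -0.25 * g, 0.25 * g)))
  nodes <- data.table::data.table(node_id = seq_len(ng * ng), x = jit(gx), y = jit(gy))
  idx <- function(i, j) (j - 1L) * ng + i
  eh <- cbind(idx(rep(1:(ng - 1L), ng), rep(1:ng, each = ng - 1L)),
              idx(rep(2:ng, ng), rep(1:ng, each = ng - 1L)))
  ev <- cbind(idx(rep(1:ng, ng - 1L), rep(1:(ng - 1L), each = ng)),
              idx(rep(1:ng, ng - 1L), rep(2:ng, each = ng)))
  ee <- rbind(eh, ev)
  elen <- sqrt((nodes$x[ee[, 1]] - nodes$x[ee[, 2]])^2 +
               (nodes$y[ee[, 1]] - nodes$y[ee[, 2]])^2)
  network <- list(nodes = nodes,
                  edges = data.table::data.table(from = ee[, 1], to = ee[, 2],
                                                 length = elen))

  # -- building registry: streets and numbered buildings per neighborhood ---
  set.seed(derive_seed(spec$rng_seed, 6L))
  types <- c("chemin", "avenue", "rue", "route", "boulevard")
  nouns <- c("roses", "lilas", "acacias", "vergers", "platanes", "tilleuls",
             "cerisiers", "noyers", "saules", "peupliers", "vignes", "champs",
             "sources", "moulins", "pins", "ormes", "glycines", "iris",
             "muriers", "sapins", "charmes", "erables", "figuiers", "jardins",
             "pres")
  quals <- c("", "blancs", "hauts", "vieux", "grands", "petits", "longs",
             "clairs", "verts", "fleuris", "dores", "neufs", "anciens",
             "jolis", "beaux", "calmes")
  combos <- expand.grid(noun = nouns, qual = quals, stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), ]
  street_of_nb <- paste(
    types[(seq_len(N) - 1L) %% length(types) + 1L], "des",
    trimws(paste(combos$noun[seq_len(N)], combos$qual[seq_len(N)])))
  km <- stats::kmeans(cents, centers = max(4L, round(N / 25)), iter.max = 50L,
                      nstart = 1L)
  postal_of_nb <- sprintf("12%02d", km$cluster)
  reg_list <- vector("list", N)
  for (i in seq_len(N)) {
    nb_build <- min(40L, max(3L, ceiling(pop[i] / 4)))
    bxy <- sample_in_polygon(nb_build, polys[[i]])
    reg_list[[i]] <- data.table::data.table(
      neighborhood_id = i, street_name = street_of_nb[i],
      street_number = as.character(seq_len(nb_build)),
      postal_code = postal_of_nb[i], x = bxy[, 1], y = bxy[, 2])
  }
  registry <- data.table::rbindlist(reg_list)
  registry[, building_id := .I]

  # -- women: building assignment, address strings, ages --------------------
  set.seed(derive_seed(spec$rng_seed, 7L))
  nbb <- registry[, .N, by = neighborhood_id]$N
  first_b <- cumsum(c(0L, nbb[-N]))
  b_of_w <- first_b[nb_of_woman] +
    (floor(stats::runif(spec$n_women) * nbb[nb_of_woman]) + 1L)
  age0 <- spec$age_range[1] +
    floor(stats::runif(spec$n_women) * (diff(spec$age_range) + 1L))
  abbr <- c("chemin" = "ch.", "avenue" = "av.", "rue" = "r.",
            "route" = "rte", "boulevard" = "bd.")
  wstreet <- registry$street_name[b_of_w]
  use_abbr <- stats::runif(spec$n_women) < 0.3
  head_word <- sub(" .*$", "", wstreet)
  addr <- ifelse(use_abbr,
                 paste(abbr[head_word], sub("^\\S+ ", "", wstreet)),
                 wstreet)
  cap <- function(s) paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
  women <- data.table::data.table(
    woman_id = seq_len(spec$n_women),
    neighborhood_id = nb_of_woman,
    building_id = b_of_w,
    address = paste(cap(addr), registry$street_number[b_of_w]),
    postal_code = registry$postal_code[b_of_w],
    x = registry$x[b_of_w], y = registry$y[b_of_w],
    age_at_start = as.integer(age0))

  # -- planted truth regions (deterministic, geometry-based) ----------------
  truth_label <- rep("none", N)
  truth_role <- rep("background", N)
  shift_mat <- matrix(0, N, P)
  taken <- logical(N)
  patterns <- spec$planted_patterns
  for (pp in patterns) {
    if (pp$trajectory == "none") next
    if (!is.null(pp$region)) {
      ids <- pp$region
      halo <- integer(0)
    } else {
      ap <- anchor_point(pp$anchor, L)
      ord <- order((cents[, 1] - ap[1])^2 + (cents[, 2] - ap[2])^2)
      ord <- ord[!taken[ord]]
      anchor_id <- ord[1]
      free <- which(!taken)
      d_anchor <- (cents[free, 1] - cents[anchor_id, 1])^2 +
                  (cents[free, 2] - cents[anchor_id, 2])^2
      picked <- free[order(d_anchor)]
      ids <- picked[seq_len(min(pp$region_size, length(picked)))]
      nh <- min(pp$halo_size %||% 0L, max(0L, length(picked) - length(ids)))
      halo <- if (nh > 0L)
        picked[(length(ids) + 1L):(length(ids) + nh)] else integer(0)
    }
    if (!length(ids)) next # small canton exhausted by earlier patterns
    taken[c(ids, halo)] <- TRUE
    truth_label[ids] <- pp$trajectory
    truth_role[ids] <- "core"
    shift_mat[ids, ] <- matrix(pp$per_period_shifts, length(ids), P, byrow = TRUE)
    if (length(halo)) {
      truth_label[halo] <- pp$trajectory
      truth_role[halo] <- "halo"
      shift_mat[halo, ] <- matrix(pp$per_period_shifts * (pp$halo_factor %||% 0.5),
                                  length(halo), P, byrow = TRUE)
    }
  }
  truth <- data.table::data.table(neighborhood_id = seq_len(N),
                                  trajectory = truth_label, role = truth_role)

  neighborhoods <- data.table::data.table(
    neighborhood_id = seq_len(N), x = cents[, 1], y = cents[, 2],
    population = pop, deprivation = depr)

  structure(list(spec = spec, neighborhoods = neighborhoods, polygons = polys,
                 centers = centers, network = network, registry = registry,
                 women = women, truth = truth, shift_mat = shift_mat),
            class = "synthetic_canton")
}

#' Generate the biennial invitation stream for a canton
#'
#' Every woman receives one invitation per biennial period while her age is
#' in 50--74; the invitation year is drawn from the two years of the
#' biennium. Participation is Bernoulli with
#' `logit = intercept + effect_deprivation * index + effect_access * access +
#' planted shift` for her neighborhood and period. Women never eligible in
#' any period are excluded; the count is recorded in
#' `attr(, "excluded_women")`.
#'
#' @param canton a `synthetic_canton`
#' @param spec the [canton_spec()] (defaults to the one inside `canton`)
#' @return data.table: woman_id, invitation_year, period, participated,
#'   age_group, neighborhood_id, address, postal_code, x, y
#' @export
generate_invitations <- function(canton, spec = canton$spec) {
  assert_that(inherits(canton, "synthetic_canton"),
              "generate_invitations() needs a synthetic_canton")
  P <- length(spec$period_labels)
  y1 <- spec$period_labels[1]

  # per-neighborhood accessibility by period, at neighborhood centroids
  acc <- access_panel(canton$neighborhoods[, .(id = neighborhood_id, x, y)],
                      canton$centers, canton$network,
                      periods = spec$period_labels)

  set.seed(derive_seed(spec$rng_seed, 8L))
  NN <- nrow(canton$neighborhoods)
  nb_effect <- stats::rnorm(NN, 0, spec$sd_neighborhood %||% 0)
  nbp_effect <- matrix(stats::rnorm(NN * P, 0, spec$sd_neighborhood_period %||% 0),
                       NN, P)
  w <- canton$women
  rows <- vector("list", P)
  for (t in seq_len(P)) {
    lab <- spec$period_labels[t]
    age <- w$age_at_start + (lab - y1)
    elig <- age >= 50L & age <= 74L
    if (!any(elig)) { rows[[t]] <- NULL; next }
    wi <- w[elig]
    agei <- age[elig]
    inv_year <- lab - stats::rbinom(nrow(wi), 1L, 0.5)
    eta <- spec$intercept +
      spec$effect_deprivation * canton$neighborhoods$deprivation[wi$neighborhood_id] +
      spec$effect_access * acc[cbind(wi$neighborhood_id, t)] +
      nb_effect[wi$neighborhood_id] +
      nbp_effect[cbind(wi$neighborhood_id, rep(t, nrow(wi)))] +
      canton$shift_mat[cbind(wi$neighborhood_id, rep(t, nrow(wi)))]
    part <- stats::rbinom(nrow(wi), 1L, stats::plogis(eta))
    rows[[t]] <- data.table::data.table(
      woman_id = wi$woman_id, invitation_year = as.integer(inv_year),
      period = lab, participated = part,
      age_group = cut(agei, breaks = c(49, 54, 59, 64, 69, 74),
                      labels = c("50-54", "55-59", "60-64", "65-69", "70-74")),
      neighborhood_id = wi$neighborhood_id,
      address = wi$address, postal_code = wi$postal_code,
      x = wi$x, y = wi$y)
  }
  inv <- data.table::rbindlist(rows)
  data.table::setorder(inv, woman_id, period)
  n_never <- sum(!canton$women$woman_id %in% inv$woman_id)
  data.table::setattr(inv, "excluded_women", n_never)
  data.table::setattr(inv, "access_panel", acc)
  inv[]
}

#' Generate a canton and its invitation stream in one call
#'
#' @inheritParams generate_canton
#' @return the `synthetic_canton` with an extra `invitations` element
#' @export
simulate_canton <- function(spec = canton_spec()) {
  canton <- generate_canton(spec)
  canton$invitations <- generate_invitations(canton, spec)
  canton
}
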