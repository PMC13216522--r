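# Independent oracle implementations used to cross-check the package.
# Each oracle is written from the definition, in a different style from the
# implementation it checks (plain loops, no shared code paths).

# --- Ratcliff-Obershelp: brute-force longest-matching-block enumeration ----

oracle_longest_block <- function(a, b) {
  # try every (start_a, start_b, length) triple; keep the longest, earliest
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- c(0L, 0L, 0L) # i, j, len
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      len <- 0L
      while (i + len <= length(ca) && j + len <= length(cb) &&
             ca[i + len] == cb[j + len]) {
        len <- len + 1L
      }
      if (len > best[3]) best <- c(i, j, len)
    }
  }
  best
}

oracle_matching_chars <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  blk <- oracle_longest_block(a, b)
  if (blk[3] == 0L) return(0L)
  left <- oracle_matching_chars(substr(a, 1L, blk[1] - 1L),
                                substr(b, 1L, blk[2] - 1L))
  right <- oracle_matching_chars(substr(a, blk[1] + blk[3], nchar(a)),
                                 substr(b, blk[2] + blk[3], nchar(b)))
  blk[3] + left + right
}

oracle_similarity <- function(a, b) {
  2 * oracle_matching_chars(a, b) / (nchar(a) + nchar(b))
}

# --- Getis-Ord Gi*: textbook formula, plain double loop --------------------

oracle_gi_star <- function(x, nb_idx) {
  # nb_idx: n x k matrix of neighbor indices (self excluded)
  n <- length(x)
  xbar <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    js <- c(i, nb_idx[i, ])
    wsum <- 0
    for (j in js) wsum <- wsum + x[j]
    W <- length(js)
    denom <- s * sqrt((n * W - W * W) / (n - 1))
    z[i] <- (wsum - xbar * W) / denom
  }
  z
}

# --- conditional permutation pseudo-p: plain-R replica of the pinned draw --
# Consumes the same uniforms as the compiled implementation (partial
# Fisher-Yates, unit-major) but computes the full Gi* z statistic for every
# permutation instead of comparing weighted sums.

oracle_permutation_p <- function(x, nb_idx, n_perm, rng_seed) {
  n <- length(x)
  k <- ncol(nb_idx)
  m <- n - 1L
  xbar <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xbar^2)
  W <- k + 1
  denom <- s * sqrt((n * W - W^2) / (n - 1))
  z_obs <- vapply(seq_len(n), function(i)
    (x[i] + sum(x[nb_idx[i, ]]) - xbar * W) / denom, numeric(1))
  set.seed(stscreen::derive_seed(rng_seed, 40L))
  p <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(z_obs[i]) || z_obs[i] == 0) {
      invisible(stats::runif(n_perm * k)) # keep streams aligned
      p[i] <- NA_real_
      next
    }
    pool <- x[-i]
    count <- 0L
    for (b in seq_len(n_perm)) {
      idx <- seq_len(m)
      u <- stats::runif(k)
      for (t in seq_len(k)) {
        r <- t + floor(u[t] * (m - t + 1))
        if (r > m) r <- m
        tmp <- idx[t]; idx[t] <- idx[r]; idx[r] <- tmp
      }
      z_perm <- (x[i] + sum(pool[idx[seq_len(k)]]) - xbar * W) / denom
      if (abs(z_perm) >= abs(z_obs[i])) count <- count + 1L
    }
    p[i] <- (count + 1) / (n_perm + 1)
  }
  p
}

# --- Mann-Kendall: pair enumeration and tie-corrected variance -------------

oracle_mk <- function(x) {
  x <- unname(x)
  n <- length(x)
  S <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      S <- S + sign(x[j] - x[i])
    }
  }
  ties <- as.integer(table(x))
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(vapply(ties, function(t) t * (t - 1) * (2 * t + 5),
                        numeric(1)))) / 18
  z <- if (varS <= 0) 0 else if (S > 0) (S - 1) / sqrt(varS)
       else if (S < 0) (S + 1) / sqrt(varS) else 0
  list(S = S, var_S = varS, z = z)
}

# --- emerging-hot-spot rule table: rle-based independent coding ------------
# Written directly from the category descriptions (final-period state, run
# structure, fraction of steps, trend), evaluated hot family then cold.

oracle_classify <- function(ind, trend, run_thr = 0.9, hist_thr = 0.5) {
  ind <- ind[!is.na(ind)]
  P <- length(ind)
  if (P < 2L) return("no_pattern")
  for (fam in c("hot", "cold")) {
    opp <- if (fam == "hot") "cold" else "hot"
    is_f <- ind == fam
    n_f <- sum(is_f)
    n_opp <- sum(ind == opp)
    frac <- n_f / P
    final <- is_f[P]
    runs <- rle(is_f)
    final_run <- if (final) runs$lengths[length(runs$lengths)] else 0L
    # trend direction in this family's "intensity" convention: a hot spot
    # intensifies when z-scores rise, a cold spot when they fall
    t_int <- if (fam == "hot") trend == "increasing" else trend == "decreasing"
    t_dim <- if (fam == "hot") trend == "decreasing" else trend == "increasing"
    lab <- NULL
    if (final && n_f == final_run && final_run == 1L) {
      lab <- "new"                              # first-ever flag, final step
    } else if (final && n_f == final_run && final_run >= 2L &&
               frac < run_thr) {
      lab <- "consecutive"                      # single trailing run
    } else if (frac >= run_thr && t_int) {
      lab <- "intensifying"
    } else if (frac >= run_thr && t_dim) {
      lab <- "diminishing"
    } else if (frac >= run_thr) {
      lab <- "persistent"
    } else if (final && frac < run_thr && n_opp == 0L) {
      lab <- "sporadic"
    } else if (final && frac < run_thr && n_opp >= 1L) {
      lab <- "oscillating"
    } else if (!final && frac >= hist_thr) {
      lab <- "historical"
    }
    if (!is.null(lab)) return(paste0(lab, "_", fam))
  }
  "no_pattern"
}

# --- Benjamini-Hochberg step-up, hand-applied ------------------------------

oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  thresholds <- alpha * seq_len(m) / m
  passed <- which(p[ord] <= thresholds)
  rej <- logical(m)
  if (length(passed)) rej[ord[seq_len(max(passed))]] <- TRUE
  rej
}

# --- spatial empirical Bayes: direct formula evaluation --------------------

oracle_sebs_cell <- function(i, n_window, o_window, n_i) {
  # n_window/o_window: counts over the window J_i (self first)
  r <- o_window / n_window
  m <- sum(o_window) / sum(n_window)
  v <- sum(n_window * (r - m)^2) / sum(n_window) -
    m / (sum(n_window) / length(n_window))
  v <- max(v, 0)
  w <- v / (v + m / n_i)
  100 * (m + w * (o_window[1] / n_window[1] - m))
}

# --- Dijkstra shortest paths, plain R --------------------------------------

oracle_dijkstra <- function(nodes, edges, source) {
  n <- nrow(nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]; w <- edges$length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist <- rep(Inf, n)
  dist[source] <- 0
  visited <- logical(n)
  repeat {
    un <- which(!visited & is.finite(dist))
    if (!length(un)) break
    u <- un[which.min(dist[un])]
    visited[u] <- TRUE
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]; w <- adj[[u]][r, 2]
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist
}

# --- small fixtures --------------------------------------------------------

# line street network: nodes every `step` meters along the x axis
line_network <- function(n_nodes = 6L, step = 1000) {
  nodes <- data.frame(node_id = seq_len(n_nodes),
                      x = (seq_len(n_nodes) - 1) * step, y = 0)
  edges <- data.frame(from = seq_len(n_nodes - 1L), to = 2:n_nodes,
                      length = rep(step, n_nodes - 1L))
  list(nodes = nodes, edges = edges)
}

# small random canton shared across tests (built once per test run)
tiny_canton <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_canton(canton_spec(
        n_neighborhoods = 60L, n_women = 4000L,
        period_labels = seq(2004L, 2014L, by = 2L), rng_seed = 11L))
    }
    cache
  }
})

# registry of unique synthetic street names for geocoder benchmarks
make_synthetic_registry <- function(n_streets = 250L, numbers_per_street = 20L,
                                    n_postal = 25L, seed = 5L) {
  set.seed(seed)
  types <- c("chemin", "avenue", "rue", "route", "boulevard")
  nouns <- c("roses", "lilas", "acacias", "vergers", "platanes", "tilleuls",
             "cerisiers", "noyers", "saules", "peupliers", "vignes",
             "champs", "sources", "moulins", "pins", "ormes", "glycines",
             "iris", "muriers", "sapins", "charmes", "erables", "figuiers",
             "jardins", "pres")
  quals <- c("blancs", "hauts", "vieux", "grands", "petits", "longs",
             "clairs", "verts", "fleuris", "dores", "neufs", "anciens",
             "jolis", "beaux", "calmes")
  combos <- expand.grid(noun = nouns, qual = quals, stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos), n_streets), ]
  streets <- paste(types[(seq_len(n_streets) - 1L) %% length(types) + 1L],
                   "des", combos$noun, combos$qual)
  postal <- sprintf("12%02d", sample.int(n_postal, n_streets, replace = TRUE))
  data.frame(
    street_name = rep(streets, each = numbers_per_street),
    street_number = as.character(rep(seq_len(numbers_per_street), n_streets)),
    postal_code = rep(postal, each = numbers_per_street),
    x = round(stats::runif(n_streets * numbers_per_street, 0, 10000), 1),
    y = round(stats::runif(n_streets * numbers_per_street, 0, 10000), 1),
    stringsAsFactors = FALSE)
}

# abbreviate the street type and delete one character from the name part
perturb_address <- function(street_name, number) {
  abbr <- c(chemin = "ch.", avenue = "av.", rue = "r.", route = "rte",
            boulevard = "bd.")
  head_word <- sub(" .*$", "", street_name)
  rest <- sub("^\\S+ ", "", street_name)
  s <- paste(abbr[[head_word]], rest)
  # drop one alphabetic character (never the first of a token)
  letters_at <- which(strsplit(s, "")[[1]] %in% letters)
  ok <- letters_at[letters_at > 1]
  drop <- sample(ok, 1L)
  s <- paste0(substr(s, 1, drop - 1L), substr(s, drop + 1L, nchar(s)))
  paste(s, number)
}
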