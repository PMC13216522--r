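# Area-level determinants of participation: gradient-boosted tree
# regression of final-period smoothed rates on deprivation, screening-center
# accessibility, age composition and spatial coordinates, tuned by Bayesian
# optimization (Gaussian-process surrogate, expected improvement) with
# 5-fold cross-validation, and interpreted with exact TreeSHAP attributions.

#' Assemble the modeling feature table
#'
#' One row per neighborhood with final-period invitations: deprivation
#' index, accessibility score, age-share vector of invited women (five
#' 5-year groups summing to 1), centroid coordinates, and the final-period
#' rate as outcome.
#'
#' @param panel smoothed panel (needs the final period)
#' @param access_panel matrix from [access_panel()] (rows = neighborhoods
#'   in id order, columns = periods)
#' @param neighborhoods data.table with neighborhood_id, x, y, deprivation
#' @param invitations invitation table with age_group, neighborhood_id,
#'   period
#' @param outcome outcome column in the panel (default "sebs_rate")
#' @return data.table: neighborhood_id, deprivation, access,
#'   share_50_54 ... share_70_74, x, y, outcome
#' @export
build_features <- function(panel, access_panel, neighborhoods, invitations,
                           outcome = "sebs_rate") {
  panel <- data.table::as.data.table(panel)
  nb <- data.table::as.data.table(neighborhoods)
  inv <- data.table::as.data.table(invitations)
  final <- max(panel$period)
  sub <- panel[period == final & n > 0]
  orphans <- setdiff(sub$neighborhood_id, nb$neighborhood_id)
  assert_that(length(orphans) == 0L,
              "join error: panel ids missing from neighborhoods: %s",
              paste(utils::head(orphans, 5L), collapse = ", "))
  groups <- c("50-54", "55-59", "60-64", "65-69", "70-74")
  invf <- inv[period == final]
  shares <- invf[, {
    tb <- table(factor(age_group, levels = groups))
    as.list(as.numeric(tb) / sum(tb))
  }, by = neighborhood_id]
  data.table::setnames(shares, c("neighborhood_id",
                                 paste0("share_", gsub("-", "_", groups))))
  ft <- merge(sub[, .(neighborhood_id, outcome = get(outcome))],
              nb[, .(neighborhood_id, x, y, deprivation)],
              by = "neighborhood_id")
  ft[, access := access_panel[neighborhood_id, as.character(final)]]
  ft <- merge(ft, shares, by = "neighborhood_id")
  assert_that(!anyNA(ft$outcome), "join error: missing outcomes")
  data.table::setcolorder(ft, c("neighborhood_id", "deprivation", "access",
                                paste0("share_", gsub("-", "_", groups)),
                                "x", "y", "outcome"))
  data.table::setorder(ft, neighborhood_id)
  ft[]
}

#' Default hyperparameter search space
#'
#' Bounds for the Bayesian search: tree depth, learning rate (log scale),
#' row/column subsampling, minimum child weight (log scale) and gamma.
#' @export
default_search_space <- function() {
  list(
    max_depth = c(2L, 8L),            # integer
    eta = log(c(0.01, 0.3)),          # sampled on log scale
    subsample = c(0.5, 1),
    colsample_bytree = c(0.5, 1),
    min_child_weight = log(c(1, 10)), # log scale
    gamma = c(0, 5)
  )
}

space_to_params <- function(u, space) {
  # u: unit-cube vector, one entry per dimension
  p <- list()
  for (j in seq_along(space)) {
    b <- space[[j]]
    v <- b[1] + u[j] * (b[2] - b[1])
    nm <- names(space)[j]
    if (nm == "max_depth") v <- as.integer(round(v))
    if (nm %in% c("eta", "min_child_weight")) v <- exp(v)
    p[[nm]] <- v
  }
  p
}

cv_rmse <- function(params, dtrain, folds, nrounds = 500L,
                    early_stopping_rounds = 25L) {
  cv <- xgboost::xgb.cv(
    params = c(params, list(objective = "reg:squarederror", nthread = 1L)),
    data = dtrain, nrounds = nrounds, folds = folds,
    early_stopping_rounds = early_stopping_rounds, verbose = 0L)
  ev <- cv$evaluation_log
  best <- which.min(ev$test_rmse_mean)
  list(rmse = ev$test_rmse_mean[best], nrounds = best)
}

expected_improvement <- function(mu, sigma, best) {
  d <- best - mu
  s <- pmax(sigma, 1e-9)
  d * stats::pnorm(d / s) + s * stats::dnorm(d / s)
}

#' Tune and fit the gradient-boosting determinants model
#'
#' Seeded 80/20 train/test split; hyperparameters minimize 5-fold
#' cross-validated RMSE via Bayesian optimization (Latin-hypercube initial
#' design, Gaussian-process surrogate, expected-improvement acquisition);
#' the final model is trained with early stopping on a 10% validation
#' carve-out of the training set; test metrics are computed once on the
#' untouched 20%.
#'
#' @param table a [build_features()] table
#' @param split training fraction (default 0.8)
#' @param folds CV folds (default 5)
#' @param n_evals total hyperparameter evaluations (default 20)
#' @param early_stopping_rounds early-stopping patience (default 25)
#' @param rng_seed seed governing split, folds, design and fit
#' @param features feature columns (default: all but id and outcome)
#' @return list of class `determinants_fit`: `model` (xgb.Booster),
#'   `report` (split sizes, tuned hyperparameters, test R2 and RMSE,
#'   trace), `features`, `split` (row assignment)
#' @export
tune_fit <- function(table, split = 0.8, folds = 5L, n_evals = 20L,
                     early_stopping_rounds = 25L, rng_seed = 1L,
                     features = NULL) {
  tb <- data.table::as.data.table(table)
  assert_that(nrow(tb) >= 100L, "tune_fit() needs >= 100 rows, got %d", nrow(tb))
  assert_that(stats::sd(tb$outcome) > 0,
              "degenerate outcome: zero variance, nothing to model")
  if (is.null(features)) {
    features <- setdiff(names(tb), c("neighborhood_id", "outcome"))
  }
  X <- as.matrix(tb[, ..features])
  yv <- tb$outcome
  nr <- nrow(tb)

  set.seed(derive_seed(rng_seed, 70L))
  train_idx <- sort(sample.int(nr, floor(split * nr)))
  test_idx <- setdiff(seq_len(nr), train_idx)
  fold_id <- sample(rep(seq_len(folds), length.out = length(train_idx)))
  fold_list <- split(seq_along(train_idx), fold_id)
  dtrain <- xgboost::xgb.DMatrix(X[train_idx, , drop = FALSE],
                                 label = yv[train_idx])

  space <- default_search_space()
  d <- length(space)
  n0 <- min(max(8L, d + 2L), n_evals)
  set.seed(derive_seed(rng_seed, 71L))
  U <- lhs::maximinLHS(n0, d)
  evals <- list()
  for (i in seq_len(n0)) {
    par <- space_to_params(U[i, ], space)
    set.seed(derive_seed(rng_seed, 72L))
    r <- cv_rmse(par, dtrain, fold_list, early_stopping_rounds = early_stopping_rounds)
    evals[[i]] <- c(list(u = U[i, ], rmse = r$rmse, nrounds = r$nrounds), par)
  }
  # sequential GP-EI proposals
  set.seed(derive_seed(rng_seed, 73L))
  while (length(evals) < n_evals) {
    Ue <- do.call(rbind, lapply(evals, `[[`, "u"))
    ye <- vapply(evals, `[[`, numeric(1), "rmse")
    gp <- try(suppressMessages(utils::capture.output(
      fit_gp <- kernlab::gausspr(x = Ue, y = ye, variance.model = TRUE,
                                 kpar = "automatic", var = 0.01),
      type = "output")), silent = TRUE)
    if (!inherits(gp, "try-error")) gp <- fit_gp
    cand <- matrix(stats::runif(500 * d), ncol = d)
    if (inherits(gp, "try-error")) {
      pick <- cand[1, ] # GP failure: fall back to a random proposal
    } else {
      mu <- as.numeric(kernlab::predict(gp, cand))
      sdev <- as.numeric(kernlab::predict(gp, cand, type = "sdeviation"))
      ei <- expected_improvement(mu, sdev, min(ye))
      pick <- cand[which.max(ei), ]
    }
    par <- space_to_params(pick, space)
    set.seed(derive_seed(rng_seed, 72L))
    r <- cv_rmse(par, dtrain, fold_list, early_stopping_rounds = early_stopping_rounds)
    evals[[length(evals) + 1L]] <- c(list(u = pick, rmse = r$rmse,
                                          nrounds = r$nrounds), par)
  }
  best_i <- which.min(vapply(evals, `[[`, numeric(1), "rmse"))
  best <- evals[[best_i]]
  tuned <- best[setdiff(names(best), c("u", "rmse", "nrounds"))]

  # final fit: early stopping on a 10% carve-out of the training rows
  set.seed(derive_seed(rng_seed, 74L))
  val_loc <- sample.int(length(train_idx), max(1L, floor(0.1 * length(train_idx))))
  tr_loc <- setdiff(seq_along(train_idx), val_loc)
  dtr <- xgboost::xgb.DMatrix(X[train_idx[tr_loc], , drop = FALSE],
                              label = yv[train_idx[tr_loc]])
  dval <- xgboost::xgb.DMatrix(X[train_idx[val_loc], , drop = FALSE],
                               label = yv[train_idx[val_loc]])
  set.seed(derive_seed(rng_seed, 75L))
  model <- xgboost::xgb.train(
    params = c(tuned, list(objective = "reg:squarederror", nthread = 1L)),
    data = dtr, nrounds = 1000L, evals = list(val = dval),
    early_stopping_rounds = early_stopping_rounds, verbose = 0L)

  pred <- stats::predict(model, X[test_idx, , drop = FALSE])
  rmse <- sqrt(mean((yv[test_idx] - pred)^2))
  r2 <- 1 - sum((yv[test_idx] - pred)^2) / sum((yv[test_idx] - mean(yv[test_idx]))^2)
  report <- list(
    n_train = length(train_idx), n_test = length(test_idx), folds = folds,
    hyperparameters = tuned, best_cv_rmse = best$rmse,
    test_r2 = r2, test_rmse = rmse,
    trace = data.table::data.table(
      eval = seq_along(evals),
      cv_rmse = vapply(evals, `[[`, numeric(1), "rmse")))
  structure(list(model = model, report = report, features = features,
                 split = list(train = train_idx, test = test_idx),
                 X = X, y = yv),
            class = "determinants_fit")
}

#' Shapley attributions and interaction summaries
#'
#' Exact tree-path (TreeSHAP) attributions from the fitted booster: a
#' per-row, per-feature matrix satisfying local accuracy (attributions +
#' base value = prediction), a mean-|attribution| importance ranking, and
#' pairwise interaction strengths (mean |interaction value| over a row
#' subsample).
#'
#' @param fit a [tune_fit()] result (tree-ensemble models only)
#' @param newdata optional feature matrix (default: the full fitted table)
#' @param interaction_sample max rows used for interaction values
#'   (default 500; interaction arrays are cubic in features x rows)
#' @return list: `attributions` (matrix with attr "base_value"),
#'   `importance` (data.table, decreasing mean |attribution|),
#'   `interactions` (feature x feature matrix)
#' @export
shap_explain <- function(fit, newdata = NULL, interaction_sample = 500L) {
  assert_that(inherits(fit, "determinants_fit") &&
                inherits(fit$model, "xgb.Booster"),
              "unsupported model: shap_explain() needs a tree-ensemble fit")
  X <- if (is.null(newdata)) fit$X else as.matrix(newdata)
  contrib <- stats::predict(fit$model, X, predcontrib = TRUE)
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  base <- contrib[, bias_col]
  attributions <- contrib[, setdiff(colnames(contrib), bias_col),
                          drop = FALSE]
  attr(attributions, "base_value") <- base
  importance <- data.table::data.table(
    feature = colnames(attributions),
    mean_abs_shap = colMeans(abs(attributions)))
  data.table::setorder(importance, -mean_abs_shap)
  sub <- seq_len(min(nrow(X), interaction_sample))
  inter <- stats::predict(fit$model, X[sub, , drop = FALSE],
                          predinteraction = TRUE)
  keep <- setdiff(dimnames(inter)[[2]], c("BIAS", "(Intercept)"))
  imat <- apply(abs(inter[, keep, keep, drop = FALSE]), c(2, 3), mean)
  list(attributions = attributions, importance = importance,
       interactions = imat)
}

#' Synthetic feature table with planted determinant effects
#'
#' Test-bed generator for the modeling stage alone: spatially smooth
#' deprivation, an urban-core accessibility score, Dirichlet-style age
#' shares, and an outcome (percent) driven by a dominant positive
#' deprivation effect and a negative accessibility effect plus noise.
#'
#' @param n rows (neighborhoods)
#' @param rng_seed seed
#' @param b_deprivation,b_access planted linear effects on the percent
#'   scale (defaults +12 and -6)
#' @param noise_sd residual noise SD in percentage points
#' @return data.table shaped like [build_features()] output
#' @export
simulate_features <- function(n = 2000L, rng_seed = 1L,
                              b_deprivation = 12, b_access = -6,
                              noise_sd = 2) {
  set.seed(derive_seed(rng_seed, 80L))
  x <- stats::runif(n, 0, 10000); y <- stats::runif(n, 0, 10000)
  core <- c(5000, 5000)
  d_core <- sqrt((x - core[1])^2 + (y - core[2])^2)
  depr <- stats::plogis(scale(stats::rnorm(n, 0, 1) +
                                sin(x / 2500) + cos(y / 2500))[, 1])
  access <- pmax(0, 3 * exp(-d_core / 2500) + stats::rnorm(n, 0, 0.2))
  a <- matrix(stats::rgamma(n * 5L, shape = 2), n, 5L)
  a <- a / rowSums(a)
  out <- 40 + b_deprivation * (depr - 0.5) + b_access * (access - mean(access)) +
    stats::rnorm(n, 0, noise_sd)
  ft <- data.table::data.table(
    neighborhood_id = seq_len(n), deprivation = depr, access = access,
    share_50_54 = a[, 1], share_55_59 = a[, 2], share_60_64 = a[, 3],
    share_65_69 = a[, 4], share_70_74 = a[, 5],
    x = x, y = y, outcome = out)
  ft[]
}
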