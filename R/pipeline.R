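# End-to-end orchestration: simulate (or load) -> geocode -> rates ->
# hotspots -> emerging hot spot analysis -> accessibility -> determinants
# model, with a run manifest recording per-stage row counts and the
# configuration hash.

#' Default run configuration
#'
#' Every random stage carries an explicit seed derived from `seed`.
#'
#' @param seed master seed
#' @param out_dir output directory (NULL: keep results in memory only)
#' @return named list understood by [run_all()]
#' @export
default_config <- function(seed = 1L, out_dir = NULL) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_neighborhoods = 400L, n_women = 60000L,
                    period_labels = seq(2004L, 2020L, by = 2L)),
    geocode = list(enabled = FALSE, threshold = 0.8),
    rates = list(k = 8L),
    hotspots = list(enabled = FALSE, k = 16L, n_perm = 999L),
    ehsa = list(spatial_k = 16L, temporal_window = 1L, alpha = 0.05,
                alpha_trend = 0.05, run_threshold = 0.9,
                historical_threshold = 0.5),
    access = list(radius = 5000),
    model = list(enabled = TRUE, n_evals = 12L, split = 0.8, folds = 5L)
  )
}

#' Run the full analysis chain
#'
#' Stages in order: simulate, (optional) geocode, rates, (optional)
#' cross-sectional hotspots, emerging hot spot analysis, accessibility,
#' determinants model. When `out_dir` is set in the config, stage outputs
#' are written as CSV/GeoJSON; a manifest of row counts and the config
#' hash is always returned.
#'
#' @param config a [default_config()]-style list
#' @return list of class `stscreen_run`: `canton`, `panel`, `hotspots`,
#'   `ehsa`, `access`, `model`, `shap`, `manifest`
#' @export
run_all <- function(config = default_config()) {
  t0 <- Sys.time()
  manifest <- list(config_hash = config_hash(config),
                   version = as.character(utils::packageVersion("stscreen")),
                   stages = list(), warnings = character(0))
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # simulate --------------------------------------------------------------
  sim <- config$simulate
  spec <- canton_spec(
    n_neighborhoods = sim$n_neighborhoods %||% 400L,
    n_women = sim$n_women %||% 60000L,
    period_labels = sim$period_labels %||% seq(2004L, 2020L, by = 2L),
    rng_seed = config$seed)
  canton <- simulate_canton(spec)
  inv <- canton$invitations
  note("simulate", neighborhoods = nrow(canton$neighborhoods),
       women = nrow(canton$women), invitations = nrow(inv),
       excluded_women = attr(inv, "excluded_women"))

  # geocode (exercises the offline geocoder on the synthetic addresses) ----
  if (isTRUE(config$geocode$enabled)) {
    reg <- prepare_registry(canton$registry)
    gc <- geocode_addresses(
      unique(inv[, .(id = woman_id, raw = address, postal_code)]),
      reg, threshold = config$geocode$threshold %||% 0.8)
    note("geocode", addresses = nrow(gc),
         failed = sum(gc$method == "failed"),
         review_band = nrow(review_band(gc)))
  }

  # rates ------------------------------------------------------------------
  panel <- aggregate_invitations(inv)
  panel <- sebs_smooth(panel, canton$neighborhoods,
                       k = config$rates$k %||% 8L)
  note("rates", cells = nrow(panel), invitations = sum(panel$n))

  # cross-sectional hotspots (optional: EHSA carries the space-time view) --
  hot <- NULL
  if (isTRUE(config$hotspots$enabled)) {
    hot <- hotspot_panel(panel, canton$neighborhoods,
                         k = config$hotspots$k %||% 16L,
                         n_perm = config$hotspots$n_perm %||% 999L,
                         rng_seed = config$seed)
    note("hotspots", rows = nrow(hot),
         significant = sum(hot$class != "not_significant"))
  }

  # emerging hot spot analysis ---------------------------------------------
  eh <- config$ehsa
  ehsa_res <- ehsa(panel, canton$neighborhoods,
                   spatial_k = eh$spatial_k %||% 16L,
                   temporal_window = eh$temporal_window %||% 1L,
                   alpha = eh$alpha %||% 0.05,
                   alpha_trend = eh$alpha_trend %||% 0.05,
                   run_threshold = eh$run_threshold %||% 0.9,
                   historical_threshold = eh$historical_threshold %||% 0.5)
  note("ehsa", locations = nrow(ehsa_res$locations),
       capacity = ehsa_res$cube$capacity,
       categorized = sum(ehsa_res$locations$category != "no_pattern"))

  # accessibility panel ----------------------------------------------------
  acc <- attr(inv, "access_panel")
  if (is.null(acc)) {
    acc <- access_panel(canton$neighborhoods[, .(id = neighborhood_id, x, y)],
                        canton$centers, canton$network,
                        periods = spec$period_labels,
                        radius = config$access$radius %||% 5000)
  }
  note("access", points = nrow(acc), periods = ncol(acc))

  # determinants model ------------------------------------------------------
  fit <- NULL; shap <- NULL
  if (isTRUE(config$model$enabled)) {
    ft <- build_features(panel, acc, canton$neighborhoods, inv)
    fit <- tune_fit(ft, split = config$model$split %||% 0.8,
                    folds = config$model$folds %||% 5L,
                    n_evals = config$model$n_evals %||% 12L,
                    rng_seed = config$seed)
    shap <- shap_explain(fit)
    note("model", rows = nrow(ft), test_r2 = fit$report$test_r2,
         test_rmse = fit$report$test_rmse)
  }

  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # persist ----------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_neighborhoods_geojson(canton$neighborhoods, canton$polygons,
                                file.path(od, "neighborhoods.geojson"))
    write_table_csv(canton$centers, file.path(od, "centers.csv"))
    write_table_csv(canton$network$nodes, file.path(od, "network_nodes.csv"))
    write_table_csv(canton$network$edges, file.path(od, "network_edges.csv"))
    write_table_csv(canton$registry, file.path(od, "registry.csv"))
    write_table_csv(inv, file.path(od, "invitations.csv"))
    write_table_csv(canton$truth, file.path(od, "truth.csv"))
    write_table_csv(panel, file.path(od, "panel.csv"))
    if (!is.null(hot)) write_table_csv(hot, file.path(od, "gi.csv"))
    write_table_csv(ehsa_res$locations, file.path(od, "ehsa.csv"))
    write_table_csv(ehsa_res$by_category_period,
                    file.path(od, "ehsa_by_category_period.csv"))
    acc_dt <- data.table::as.data.table(acc)
    acc_dt[, neighborhood_id := canton$neighborhoods$neighborhood_id]
    write_table_csv(acc_dt, file.path(od, "access.csv"))
    if (!is.null(fit)) {
      jsonlite::write_json(fit$report[c("n_train", "n_test", "folds",
                                        "hyperparameters", "test_r2",
                                        "test_rmse")],
                           file.path(od, "metrics.json"), auto_unbox = TRUE,
                           digits = NA)
      write_table_csv(shap$importance, file.path(od, "importance.csv"))
      write_table_csv(data.table::as.data.table(shap$attributions),
                      file.path(od, "shap_values.csv"))
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(canton = canton, panel = panel, hotspots = hot,
                 ehsa = ehsa_res, access = acc, model = fit, shap = shap,
                 manifest = manifest),
            class = "stscreen_run")
}

#' Compare emerging hot spot labels with planted truth
#'
#' @param run a [run_all()] result (or any list with `canton$truth` and
#'   `ehsa$locations`)
#' @return list: `hot_recovery` (fraction of planted persistent/
#'   intensifying hot-core neighborhoods given a hot-family category),
#'   `background_flagged` (fraction of background neighborhoods -- units
#'   with no planted shift, halos excluded -- given any hot/cold
#'   category), and the truth-by-category table
#' @export
truth_recovery <- function(run) {
  truth <- run$canton$truth
  loc <- run$ehsa$locations
  m <- merge(truth, loc[, .(neighborhood_id, category)],
             by = "neighborhood_id")
  hot_family <- paste0(c("new", "consecutive", "intensifying", "persistent",
                         "diminishing", "sporadic", "oscillating",
                         "historical"), "_hot")
  planted_hot <- m$trajectory %in% c("persistent_hot", "intensifying_hot") &
    m$role == "core"
  background <- m$role == "background"
  list(
    hot_recovery = mean(m$category[planted_hot] %in% hot_family),
    background_flagged = mean(m$category[background] != "no_pattern"),
    table = m[, .N, by = .(trajectory, role, category)])
}
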