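#' Configuration for a full pipeline run
#'
#' Gathers every knob of the end-to-end workflow with defaults reproducing
#' its standard shape: the synthetic seascape design, the 36-combination
#' tuning grid (3 learning rates x 6 tree complexities x 2 bag fractions),
#' 100 bootstrap models, all four threshold optimizers, and one global seed
#' fanned out to per-stage seeds by a fixed splitting rule so stages are
#' independently re-runnable.
#'
#' @param seascape a [seascape_config()].
#' @param lr_values,tc_values,bf_values tuning grids (defaults as in
#'   [tune_grid()]).
#' @param rho_threshold Spearman filter threshold (default 0.9).
#' @param fold_count,step_size,max_trees cross-validation controls.
#' @param n_boot bootstrap ensemble size (default 100).
#' @param boot_trees `"cv"` or `"fixed"` tree-count rule for bootstrap
#'   refits (see [bootstrap_ensemble()]).
#' @param seed global integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(seascape = seascape_config(),
                       lr_values = c(0.01, 0.001, 0.005),
                       tc_values = c(2, 3, 4, 5, 10, 20),
                       bf_values = c(0.5, 0.75),
                       rho_threshold = 0.9,
                       fold_count = 10L, step_size = 50L, max_trees = 10000L,
                       n_boot = 100L, boot_trees = c("cv", "fixed"),
                       seed = 1L) {
  boot_trees <- match.arg(boot_trees)
  stopifnot(inherits(seascape, "seascape_config"))
  structure(list(seascape = seascape, lr_values = lr_values,
                 tc_values = tc_values, bf_values = bf_values,
                 rho_threshold = rho_threshold,
                 fold_count = as.integer(fold_count),
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 n_boot = as.integer(n_boot), boot_trees = boot_trees,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full uncertainty-aware SDM workflow
#'
#' Executes simulate -> derive/filter predictors -> tune -> bootstrap
#' ensemble -> mean/sd/CoV surfaces -> threshold optimization (on the
#' independent test set only) -> nine combination maps -> zonal report, with
#' seeded determinism throughout. Each stage logs its seed, artifacts are
#' written as they are produced (ASCII grids, CSV, GeoJSON, JSON), and a
#' failure aborts with the stage name while earlier artifacts persist. The
#' returned manifest lists every file with its MD5 content hash.
#'
#' Threshold triple for the combination maps: low = the smaller of the
#' SES/MSS selections, moderate = PPOP, high = max-kappa, sorted ascending.
#'
#' @param config a [run_config()].
#' @param outdir writable output directory (created if missing).
#' @param verbose print stage progress (default `TRUE`).
#' @return invisibly, a list with every stage result plus `manifest`.
#' @export
run_sdm_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir, call. = FALSE)
  files <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  keep <- function(path) { files[length(files) + 1L] <<- path; path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seeds <- vapply(1:6, function(i) split_seed(config$seed, 10L * i), integer(1L))

  # -- simulate ---------------------------------------------------------------
  say("[simulate] seed %d", seeds[1L])
  sea <- stage("simulate", {
    sc <- config$seascape
    sc$seed <- seeds[1L]
    generate_seascape(sc)
  })
  sites <- stage("simulate", sample_sites(sea))
  shared <- intersect(paste(sites$train$x, sites$train$y),
                      paste(sites$test$x, sites$test$y))
  if (length(shared)) stop("internal: train and test share ", length(shared), " cells")
  grid_dir <- file.path(outdir, "predictors")
  dir.create(grid_dir, showWarnings = FALSE)
  for (nm in names(sea$predictors)) {
    keep(write_ascii_grid(sea$predictors[[nm]], file.path(grid_dir, paste0(nm, ".asc"))))
  }
  keep(write_ascii_grid(sea$true_probability, file.path(outdir, "true_probability.asc")))
  keep(write_zones_geojson(sea$zones, file.path(outdir, "zones.geojson")))
  keep(write_sites_csv(sites$train, file.path(outdir, "sites_train.csv")))
  keep(write_sites_csv(sites$test, file.path(outdir, "sites_test.csv")))

  # -- correlation filter -----------------------------------------------------
  flt <- stage("filter", filter_correlated(sites$train, config$rho_threshold))
  say("[filter] retained %d of %d predictors", length(flt$retained),
      length(flt$retained) + nrow(flt$dropped))
  utils::write.csv(tidy(flt), keep(file.path(outdir, "correlation_filter.csv")),
                   row.names = FALSE)

  # -- tune -------------------------------------------------------------------
  say("[tune] seed %d, %d combinations", seeds[2L],
      length(config$lr_values) * length(config$tc_values) * length(config$bf_values))
  tuning <- stage("tune", tune_grid(
    sites$train, lr_values = config$lr_values, tc_values = config$tc_values,
    bf_values = config$bf_values, fold_count = config$fold_count,
    step_size = config$step_size, max_trees = config$max_trees,
    seed = seeds[2L], predictors = flt$retained))
  utils::write.csv(dplyr::select(tuning$rows, -"note"),
                   keep(file.path(outdir, "tuning.csv")), row.names = FALSE)

  # -- final fit --------------------------------------------------------------
  say("[fit] lr %g tc %d bf %g, seed %d", tuning$best$lr, tuning$best$tc,
      tuning$best$bf, seeds[3L])
  best_params <- brt_params(lr = tuning$best$lr, tc = tuning$best$tc,
                            bf = tuning$best$bf, step_size = config$step_size,
                            max_trees = config$max_trees,
                            fold_count = config$fold_count, seed = seeds[3L])
  model <- stage("fit", fit_brt_step(sites$train, best_params,
                                     predictors = flt$retained))
  keep(write_brt_json(model, file.path(outdir, "brt_model.json")))

  # -- bootstrap ensemble -----------------------------------------------------
  say("[ensemble] n_boot %d, seed %d", config$n_boot, seeds[4L])
  ens <- stage("ensemble", bootstrap_ensemble(
    sites$train, best_params, n_boot = config$n_boot, seed = seeds[4L],
    trees = config$boot_trees, n_trees = model$n_trees_selected,
    predictors = flt$retained))
  stack <- subset_stack(sea$predictors, flt$retained)
  preds <- stage("ensemble", predict_ensemble(ens, stack))
  surfaces <- stage("ensemble", ensemble_surfaces(preds))
  keep(write_ascii_grid(surfaces$mean, file.path(outdir, "prob_mean.asc")))
  keep(write_ascii_grid(surfaces$sd, file.path(outdir, "prob_sd.asc")))
  keep(write_ascii_grid(surfaces$cov, file.path(outdir, "prob_cov.asc")))
  jsonlite::write_json(
    list(seed = seeds[4L], n_boot = config$n_boot,
         n_redrawn = attr(ens, "n_redrawn"),
         resample_indices = attr(ens, "resample_indices")),
    keep(file.path(outdir, "ensemble_manifest.json")), auto_unbox = TRUE)

  # -- thresholds (independent test set only) ---------------------------------
  test_pred <- stats::predict(model, sites$test)
  test_obs <- sites$test$presence
  thr <- stage("thresholds", optimize_thresholds(test_obs, test_pred))
  roc <- roc_curve(test_obs, test_pred)
  test_auc <- auc(test_obs, test_pred)
  test_pde <- percent_deviance_explained(test_obs, test_pred)
  say("[thresholds] test AUC %.3f, test PDE %.3f", test_auc, test_pde)
  utils::write.csv(as.data.frame(roc), keep(file.path(outdir, "roc.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(thr), keep(file.path(outdir, "thresholds.csv")),
                   row.names = FALSE)

  # -- nine combination maps --------------------------------------------------
  triple <- sort(c(min(thr$threshold[thr$method %in% c("ses", "mss")]),
                   thr$threshold[thr$method == "ppop"],
                   thr$threshold[thr$method == "max_kappa"]))
  combos <- stage("maps", combo_maps(surfaces$mean, surfaces$cov, triple))
  map_dir <- file.path(outdir, "combo_maps")
  dir.create(map_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(combos))) {
    fn <- sprintf("combo_%sprob_%sprec.asc", combos$probability_level[i],
                  combos$precision_level[i])
    keep(write_ascii_grid(combos$mask[[i]], file.path(map_dir, fn)))
  }
  utils::write.csv(dplyr::select(combos, -"mask"),
                   keep(file.path(outdir, "combo_maps.csv")), row.names = FALSE)

  # -- zonal accounting -------------------------------------------------------
  zonal <- stage("zones", zonal_report_all(combos, sea$zones))
  sens <- stage("report", sensitivity_report(zonal))
  utils::write.csv(zonal, keep(file.path(outdir, "zonal_report.csv")),
                   row.names = FALSE)
  jsonlite::write_json(sens, keep(file.path(outdir, "sensitivity_report.json")),
                       auto_unbox = TRUE, digits = NA)

  manifest <- tibble::tibble(
    file = files,
    bytes = file.size(files),
    md5 = unname(tools::md5sum(files))
  )
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  say("[done] %d artifacts in %s", nrow(manifest), outdir)

  invisible(list(seascape = sea, sites = sites, filter = flt, tuning = tuning,
                 model = model, ensemble = ens, surfaces = surfaces,
                 roc = roc, thresholds = thr, test_auc = test_auc,
                 test_pde = test_pde, combos = combos, zonal = zonal,
                 sensitivity = sens, manifest = manifest,
                 stage_seeds = seeds))
}
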