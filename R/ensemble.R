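#' Bootstrap ensemble of BRT models
#'
#' Refits the tuned model on `n_boot` resamples (with replacement, size n) of
#' the training sites, drawn from a seeded stream so the index sets are
#' reproducible. A resample that happens to lack one of the classes is
#' redrawn and the redraw is reported (at 4.5 percent prevalence and n = 292
#' this is a ~1e-6 event). Each model selects its own tree count by the
#' cross-validated rule (`trees = "cv"`), or reuses a fixed count
#' (`trees = "fixed"`, e.g. the count the tuned model selected) when the
#' selection has already been made.
#'
#' @param train site tibble with `presence` and predictor columns.
#' @param params a [brt_params()] carrying the tuned `lr`, `tc`, `bf`.
#' @param n_boot number of bootstrap models (default 100; at least 2, or the
#'   coefficient of variation is undefined).
#' @param seed integer seed for the resampling stream.
#' @param trees `"cv"` (default) or `"fixed"`.
#' @param n_trees tree count used when `trees = "fixed"`.
#' @param predictors optional predictor subset.
#' @return list of `brt_model` objects with a `resample_indices` attribute
#'   (list of index vectors) and `n_redrawn` attribute.
#' @export
bootstrap_ensemble <- function(train, params, n_boot = 100L, seed = 1L,
                               trees = c("cv", "fixed"), n_trees = NULL,
                               predictors = NULL) {
  trees <- match.arg(trees)
  if (n_boot < 2L) {
    stop("n_boot must be >= 2: the coefficient of variation is undefined for ",
         "a single model", call. = FALSE)
  }
  y <- train$presence
  if (length(unique(y)) < 2L) stop("training data contain a single class", call. = FALSE)
  if (trees == "fixed" && is.null(n_trees)) {
    stop("trees = \"fixed\" needs `n_trees`", call. = FALSE)
  }
  n <- nrow(train)
  set.seed(seed)
  indices <- vector("list", n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    indices[[b]] <- idx
  }
  if (n_redrawn > 0L) {
    message(n_redrawn, " single-class bootstrap resample(s) were redrawn")
  }
  models <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    resample <- train[indices[[b]], , drop = FALSE]
    boot_params <- brt_params(lr = params$lr, tc = params$tc, bf = params$bf,
                              step_size = params$step_size,
                              max_trees = params$max_trees,
                              fold_count = params$fold_count,
                              seed = split_seed(seed, 100L + b))
    models[[b]] <- if (trees == "cv") {
      fit_brt_step(resample, boot_params, predictors = predictors)
    } else {
      fit_brt_fixed(resample, boot_params, n_trees, predictors = predictors)
    }
  }
  attr(models, "resample_indices") <- indices
  attr(models, "n_redrawn") <- n_redrawn
  class(models) <- "brt_ensemble"
  models
}

# Fit with a predetermined tree count (no CV tree search).
fit_brt_fixed <- function(train, params, n_trees, predictors = NULL,
                          response = "presence") {
  y <- train[[response]]
  if (length(unique(y)) < 2L) stop("training data contain a single class", call. = FALSE)
  if (is.null(predictors)) predictors <- predictor_cols(train)
  X <- site_design_matrix(train, predictors)
  dall <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(params = xgb_param_list(params, params$seed),
                                data = dall, nrounds = n_trees, verbose = 0)
  new_brt_model(
    trees = parse_booster_trees(booster),
    intercept = booster_intercept(booster),
    params = params, n_trees_selected = n_trees,
    feature_names = predictors,
    train_summary = list(n = nrow(train), prevalence = mean(y)),
    booster = booster
  )
}

#' Reduce bootstrap predictions to mean, sd and CoV surfaces
#'
#' Per-cell mean, sample standard deviation (n - 1 denominator) and
#' coefficient of variation `CoV = sd / mean` over a list of aligned
#' probability surfaces. CoV is the workflow's precision measure: a cell
#' whose probability is 0.5 with CoV 0.1 could vary by 0.5 x 0.1 = +/- 0.05.
#' Cells with mean 0 get nodata CoV rather than infinity.
#'
#' @param predictions list of >= 2 aligned probability [grid_surface()]s
#'   (e.g. one per bootstrap model).
#' @return an `ensemble_surfaces` list: `mean`, `sd`, `cov` grids and
#'   `n_boot`.
#' @examples
#' g <- function(v) grid_surface(matrix(v, 2, 2))
#' ensemble_surfaces(list(g(0.2), g(0.4)))$cov[1, 1]  # 0.4714
#' @export
ensemble_surfaces <- function(predictions) {
  if (length(predictions) < 2L) {
    stop("need at least two prediction surfaces", call. = FALSE)
  }
  check_aligned(predictions)
  ref <- predictions[[1L]]
  arr <- vapply(predictions, as.numeric, numeric(length(ref)))
  if (is.null(dim(arr))) arr <- matrix(arr, nrow = 1L)  # single-cell grids
  mu <- rowMeans(arr)
  sdv <- apply(arr, 1L, stats::sd)
  cov <- ifelse(!is.na(mu) & mu > 0, sdv / mu, NA_real_)
  structure(list(mean = grid_like(matrix(mu, nrow(ref), ncol(ref)), ref),
                 sd = grid_like(matrix(sdv, nrow(ref), ncol(ref)), ref),
                 cov = grid_like(matrix(cov, nrow(ref), ncol(ref)), ref),
                 n_boot = length(predictions)),
            class = "ensemble_surfaces")
}

#' @export
print.ensemble_surfaces <- function(x, ...) {
  cat(sprintf("<ensemble_surfaces> n_boot %d, mean prob %.4f, mean CoV %.3f\n",
              x$n_boot, mean(x$mean, na.rm = TRUE), mean(x$cov, na.rm = TRUE)))
  invisible(x)
}

#' Predict surfaces for every ensemble member
#'
#' @param ensemble a [bootstrap_ensemble()] result.
#' @param stack a [predictor_stack()].
#' @return list of probability [grid_surface()]s.
#' @export
predict_ensemble <- function(ensemble, stack) {
  lapply(ensemble, predict_surface, stack = stack)
}
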