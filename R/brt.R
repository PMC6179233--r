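#' Boosted regression tree hyperparameters
#'
#' The tuning constants of a stagewise boosted-tree occurrence model:
#' learning rate `lr` (shrinkage per tree), tree complexity `tc` (interaction
#' depth: a complexity-`tc` tree can represent `tc`-way interactions), and
#' bag fraction `bf` (share of training rows randomly subsampled for each
#' tree). `step_size` and `max_trees` control the cross-validated tree-count
#' search (50 and 10000, the customary staged-fitting convention);
#' `fold_count` is the number of class-stratified CV folds.
#'
#' @param lr learning rate, > 0.
#' @param tc tree complexity (integer >= 1).
#' @param bf bag fraction in (0, 1].
#' @param step_size trees added per evaluation step (default 50).
#' @param max_trees cap on ensemble size (default 10000).
#' @param fold_count cross-validation folds (default 10).
#' @param seed integer seed for subsampling and fold assignment.
#' @return a `brt_params` list.
#' @export
brt_params <- function(lr = 0.005, tc = 3L, bf = 0.75, step_size = 50L,
                       max_trees = 10000L, fold_count = 10L, seed = 1L) {
  if (!is.numeric(lr) || lr <= 0) stop("lr must be > 0", call. = FALSE)
  if (tc < 1 || tc != as.integer(tc)) stop("tc must be an integer >= 1", call. = FALSE)
  if (!(bf > 0 && bf <= 1)) stop("bf must be in (0, 1]", call. = FALSE)
  if (step_size < 1) stop("step_size must be >= 1", call. = FALSE)
  if (max_trees < step_size) stop("max_trees must be >= step_size", call. = FALSE)
  if (fold_count < 2) stop("fold_count must be >= 2", call. = FALSE)
  structure(list(lr = lr, tc = as.integer(tc), bf = bf,
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 fold_count = as.integer(fold_count), seed = as.integer(seed)),
            class = "brt_params")
}

# Class-stratified fold assignment so every fold holds presences even at low
# prevalence (held-out deviance stays defined).
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

xgb_param_list <- function(params, seed) {
  list(objective = "binary:logistic",
       eta = params$lr,
       max_depth = params$tc,
       subsample = params$bf,
       lambda = 0, alpha = 0,
       nthread = 1,
       seed = as.integer(seed))
}

site_design_matrix <- function(sites, feature_names) {
  missing <- setdiff(feature_names, names(sites))
  if (length(missing)) {
    stop("site table lacks predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(sites[feature_names])
}

#' Fit a BRT with cross-validated tree-count selection
#'
#' The staged-fitting procedure: for each of `fold_count` class-stratified
#' folds, a stagewise boosted-tree model (each stage fits a complexity-`tc`
#' regression tree to the Bernoulli-deviance gradient on a random
#' `bf`-fraction subsample and adds its shrunken Newton-step leaf values) is
#' grown on the other folds up to `max_trees`, and held-out deviance is
#' recorded every `step_size` trees. The tree count minimising the mean
#' held-out deviance across folds is selected; the cross-validated percent
#' deviance explained is `1 - min(mean held-out deviance) / (mean held-out
#' null deviance)`, the null being the training-fold prevalence. The final
#' model is refit on all rows with the selected tree count. Tree fitting is
#' delegated to xgboost; selection, evaluation and the final model contract
#' are this function's.
#'
#' @param train site tibble with a 0/1 `presence` column and predictor
#'   columns.
#' @param params a [brt_params()].
#' @param predictors character vector of predictor columns (default: every
#'   non-metadata column of `train`).
#' @param response name of the 0/1 response column (default `"presence"`).
#' @return a `brt_model`: selected tree rules, intercept (log-odds),
#'   `n_trees_selected`, `cv_pde`, per-fold PDEs, the deviance profile, and
#'   the fitted backend booster.
#' @export
fit_brt_step <- function(train, params, predictors = NULL, response = "presence") {
  stopifnot(inherits(params, "brt_params"))
  y <- train[[response]]
  if (is.null(y)) stop("train lacks a `", response, "` column", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class; cannot fit an occurrence model",
         call. = FALSE)
  }
  if (nrow(train) < 2L * params$fold_count) {
    stop("need at least ", 2L * params$fold_count, " rows for ",
         params$fold_count, "-fold cross-validation", call. = FALSE)
  }
  if (is.null(predictors)) predictors <- predictor_cols(train)
  X <- site_design_matrix(train, predictors)

  set.seed(params$seed)
  fold <- stratified_folds(y, params$fold_count)
  counts <- seq(params$step_size, params$max_trees, by = params$step_size)
  dev_mat <- matrix(NA_real_, params$fold_count, length(counts))
  null_dev <- numeric(params$fold_count)

  for (f in seq_len(params$fold_count)) {
    in_f <- fold == f
    dtrain <- xgboost::xgb.DMatrix(X[!in_f, , drop = FALSE], label = y[!in_f])
    dheld <- xgboost::xgb.DMatrix(X[in_f, , drop = FALSE])
    booster <- xgboost::xgb.train(params = xgb_param_list(params, params$seed + f),
                                  data = dtrain, nrounds = params$max_trees,
                                  verbose = 0)
    yh <- y[in_f]
    for (i in seq_along(counts)) {
      ph <- stats::predict(booster, dheld, iterationrange = c(1L, counts[i]))
      dev_mat[f, i] <- bernoulli_deviance(yh, ph) / length(yh)
    }
    null_dev[f] <- bernoulli_deviance(yh, rep(mean(y[!in_f]), length(yh))) / length(yh)
  }

  mean_dev <- colMeans(dev_mat)
  best_i <- which.min(mean_dev)
  if (best_i == length(counts)) {
    warning("held-out deviance still decreasing at max_trees = ", params$max_trees,
            "; returning max_trees", call. = FALSE)
  }
  n_trees <- counts[best_i]
  cv_pde <- 1 - mean_dev[best_i] / mean(null_dev)
  fold_pde <- 1 - dev_mat[, best_i] / null_dev

  dall <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(params = xgb_param_list(params, params$seed),
                                data = dall, nrounds = n_trees, verbose = 0)

  new_brt_model(
    trees = parse_booster_trees(booster),
    intercept = booster_intercept(booster),
    params = params,
    n_trees_selected = n_trees,
    feature_names = predictors,
    train_summary = list(n = nrow(train), prevalence = mean(y)),
    cv_pde = cv_pde,
    fold_pde = fold_pde,
    cv_profile = tibble::tibble(n_trees = counts, mean_heldout_deviance = mean_dev),
    booster = booster
  )
}

new_brt_model <- function(trees, intercept, params, n_trees_selected,
                          feature_names, train_summary = NULL, cv_pde = NA_real_,
                          fold_pde = numeric(0), cv_profile = NULL, booster = NULL) {
  structure(list(trees = trees, intercept = intercept, params = params,
                 n_trees_selected = as.integer(n_trees_selected),
                 feature_names = feature_names, train_summary = train_summary,
                 cv_pde = cv_pde, fold_pde = fold_pde, cv_profile = cv_profile,
                 booster = booster),
            class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf("<brt_model> lr %g, tc %d, bf %g; %d trees selected; cv PDE %s\n",
              x$params$lr, x$params$tc, x$params$bf, x$n_trees_selected,
              ifelse(is.na(x$cv_pde), "NA", sprintf("%.3f", x$cv_pde))))
  invisible(x)
}

# Parse the backend's fitted trees into the package's own rule table:
# one row per node, leaf log-odds increments in `value`.
parse_booster_trees <- function(booster) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- as.data.frame(dt)
  node_of <- function(id) ifelse(is.na(id), NA_integer_,
                                 as.integer(sub("^.*-", "", id)))
  is_leaf <- dt$Feature == "Leaf"
  tibble::tibble(
    tree = as.integer(dt$Tree),
    node = as.integer(dt$Node),
    feature = ifelse(is_leaf, NA_character_, dt$Feature),
    split = ifelse(is_leaf, NA_real_, dt$Split),
    yes = node_of(dt$Yes),
    no = node_of(dt$No),
    missing = node_of(dt$Missing),
    value = ifelse(is_leaf, dt$Gain, NA_real_)
  )
}

booster_intercept <- function(booster) {
  cfg <- xgboost::xgb.config(booster)
  stats::qlogis(as.numeric(cfg$learner$learner_model_param$base_score))
}

# Round doubles to the nearest float32, the precision at which tree split
# comparisons are made.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L), "numeric",
          n = length(v), size = 4L)
}

# Evaluate the rule table directly: per tree, route every row from the root
# until a leaf, then add the leaf log-odds increment. Inputs are rounded to
# float32 first so boundary cases route identically to the fitting backend.
# Independent of the backend; used for serialized models and as its
# cross-check.
predict_from_rules <- function(trees, intercept, feature_names, X, n_trees) {
  X <- matrix(as_float32(X), nrow(X), ncol(X), dimnames = dimnames(X))
  margin <- rep(intercept, nrow(X))
  if (n_trees == 0L || nrow(trees) == 0L) return(stats::plogis(margin))
  use <- trees[trees$tree < n_trees, , drop = FALSE]
  for (t_id in unique(use$tree)) {
    tr <- use[use$tree == t_id, , drop = FALSE]
    ord <- order(tr$node)
    tr <- tr[ord, , drop = FALSE]
    lookup <- match(seq(0L, max(tr$node)), tr$node)
    feat_col <- match(tr$feature, feature_names)
    cur <- rep(match(0L, tr$node), nrow(X))
    repeat {
      active <- which(!is.na(feat_col[cur]))
      if (!length(active)) break
      rows <- cur[active]
      xv <- X[cbind(active, feat_col[rows])]
      nxt <- ifelse(xv < tr$split[rows], tr$yes[rows], tr$no[rows])
      nxt[is.na(xv)] <- tr$missing[rows][is.na(xv)]
      cur[active] <- lookup[nxt + 1L]
    }
    margin <- margin + tr$value[cur]
  }
  stats::plogis(margin)
}

#' Predict occurrence probabilities from a fitted BRT
#'
#' Uses exactly the `n_trees_selected` trees chosen by cross-validation.
#' Models carrying their fitted backend booster predict through it; models
#' rebuilt from a serialized rule table are evaluated by the package's own
#' tree traversal (the two agree to single precision).
#'
#' @param object a `brt_model`.
#' @param newdata data frame (or matrix) containing the model's predictors.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.brt_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata[, object$feature_names, drop = FALSE]
       else site_design_matrix(newdata, object$feature_names)
  if (object$n_trees_selected == 0L || is.null(object$trees) ||
      nrow(object$trees) == 0L) {
    return(rep(stats::plogis(object$intercept), nrow(X)))
  }
  if (!is.null(object$booster)) {
    stats::predict(object$booster, xgboost::xgb.DMatrix(X),
                   iterationrange = c(1L, object$n_trees_selected))
  } else {
    predict_from_rules(object$trees, object$intercept, object$feature_names,
                       X, object$n_trees_selected)
  }
}

#' Tune the BRT hyperparameter grid by cross-validated PDE
#'
#' Evaluates every combination of the learning-rate, tree-complexity and
#' bag-fraction grids through [fit_brt_step()]'s cross-validation and keeps
#' only the metrics: the winning combination is the one with the highest mean
#' cross-validated percent deviance explained (ties broken by fewer selected
#' trees, then grid order). All models fitted during tuning are discarded.
#' The default grids are the workflow's standard tuning table: three learning
#' rates, six tree complexities and two bag fractions — 36 combinations.
#'
#' @param train site tibble with `presence` and predictor columns.
#' @param lr_values,tc_values,bf_values grids to cross (defaults
#'   `c(0.01, 0.001, 0.005)`, `c(2, 3, 4, 5, 10, 20)`, `c(0.5, 0.75)`).
#' @param fold_count CV folds (default 10).
#' @param step_size,max_trees tree-count search controls (see
#'   [brt_params()]).
#' @param seed integer seed.
#' @param predictors optional predictor subset.
#' @return a `tuning_result`: `rows` (one tibble row per combination with
#'   `mean_cv_pde`, `sd_cv_pde`, `n_trees`, `failed`) and `best`.
#' @export
tune_grid <- function(train, lr_values = c(0.01, 0.001, 0.005),
                      tc_values = c(2, 3, 4, 5, 10, 20),
                      bf_values = c(0.5, 0.75), fold_count = 10L,
                      step_size = 50L, max_trees = 10000L, seed = 1L,
                      predictors = NULL) {
  if (!length(lr_values) || !length(tc_values) || !length(bf_values)) {
    stop("value grids must be non-empty", call. = FALSE)
  }
  grid <- tidyr::expand_grid(lr = lr_values, tc = tc_values, bf = bf_values)
  rows <- purrr::pmap(grid, function(lr, tc, bf) {
    fit <- tryCatch(
      fit_brt_step(train,
                   brt_params(lr = lr, tc = tc, bf = bf, step_size = step_size,
                              max_trees = max_trees, fold_count = fold_count,
                              seed = seed),
                   predictors = predictors),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      tibble::tibble(lr = lr, tc = tc, bf = bf, mean_cv_pde = NA_real_,
                     sd_cv_pde = NA_real_, n_trees = NA_integer_, failed = TRUE,
                     note = conditionMessage(fit))
    } else {
      tibble::tibble(lr = lr, tc = tc, bf = bf, mean_cv_pde = fit$cv_pde,
                     sd_cv_pde = stats::sd(fit$fold_pde),
                     n_trees = fit$n_trees_selected, failed = FALSE,
                     note = NA_character_)
    }
  })
  rows <- dplyr::bind_rows(rows)
  ok <- which(!rows$failed)
  if (!length(ok)) stop("every tuning combination failed to fit", call. = FALSE)
  ord <- ok[order(-rows$mean_cv_pde[ok], rows$n_trees[ok], ok)]
  best <- rows[ord[1L], c("lr", "tc", "bf", "mean_cv_pde", "n_trees")]
  structure(list(rows = rows, best = best, fold_count = as.integer(fold_count),
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees), seed = as.integer(seed)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d combinations, %d-fold CV\n",
              nrow(x$rows), x$fold_count))
  cat(sprintf("  best: lr %g, tc %d, bf %g (mean cv PDE %.3f, %d trees)\n",
              x$best$lr, x$best$tc, x$best$bf, x$best$mean_cv_pde, x$best$n_trees))
  invisible(x)
}

#' Predict a probability-of-occurrence surface
#'
#' Applies a fitted BRT to every valid cell of a predictor stack:
#' `probability = plogis(intercept + sum of selected tree contributions)`.
#' Cells that are nodata in any required layer are nodata in the output.
#'
#' @param model a `brt_model`.
#' @param stack a [predictor_stack()] containing every predictor the model
#'   references.
#' @return a probability [grid_surface()].
#' @export
predict_surface <- function(model, stack) {
  missing <- setdiff(model$feature_names, names(stack))
  if (length(missing)) {
    stop("stack lacks predictor(s) the model references: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ref <- stack[[1L]]
  X <- vapply(model$feature_names, function(nm) as.numeric(stack[[nm]]),
              numeric(length(ref)))
  X <- matrix(X, ncol = length(model$feature_names),
              dimnames = list(NULL, model$feature_names))
  valid <- !apply(is.na(X), 1L, any)
  out <- rep(NA_real_, length(ref))
  if (any(valid)) {
    out[valid] <- predict(model, X[valid, , drop = FALSE])
  }
  grid_like(matrix(out, nrow(ref), ncol(ref)), ref)
}

#' Serialize a BRT model to JSON
#'
#' Writes the model as a plain JSON document: hyperparameters, intercept,
#' selected tree count, feature names, training summary and the full rule
#' table. `read_brt_json()` rebuilds a `brt_model` whose predictions come
#' from the package's own tree traversal.
#'
#' @param model a `brt_model`.
#' @param path file path.
#' @return `read_brt_json()` returns a `brt_model`; `write_brt_json()`
#'   returns `path` invisibly.
#' @export
write_brt_json <- function(model, path) {
  doc <- list(
    params = unclass(model$params),
    intercept = model$intercept,
    n_trees_selected = model$n_trees_selected,
    feature_names = model$feature_names,
    train_summary = model$train_summary,
    cv_pde = model$cv_pde,
    trees = model$trees
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_brt_json
#' @export
read_brt_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  trees <- tibble::as_tibble(doc$trees)
  trees$tree <- as.integer(trees$tree)
  trees$node <- as.integer(trees$node)
  new_brt_model(
    trees = trees,
    intercept = doc$intercept,
    params = do.call(brt_params, doc$params),
    n_trees_selected = doc$n_trees_selected,
    feature_names = doc$feature_names,
    train_summary = doc$train_summary,
    cv_pde = doc$cv_pde %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
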