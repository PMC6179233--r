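test_that("Bernoulli deviance matches hand-evaluated log-likelihoods", {
  expect_equal(bernoulli_deviance(1, 1 - 1e-9), 0, tolerance = 1e-6)
  expect_equal(bernoulli_deviance(c(1, 0, 0, 0), c(0.9, 0.1, 0.1, 0.1)),
               -2 * 4 * log(0.9), tolerance = 1e-12)
  expect_equal(round(bernoulli_deviance(c(1, 0, 0, 0), c(0.9, 0.1, 0.1, 0.1)), 4),
               0.8429)
  expect_equal(bernoulli_deviance(0, 0.5), 2 * log(2))
  expect_error(bernoulli_deviance(numeric(0), numeric(0)), "empty")
  expect_error(bernoulli_deviance(c(1, 0), 0.5), "lengths")
})

test_that("PDE is the null-relative deviance reduction", {
  obs <- c(1, 0, 0, 0)
  expect_equal(percent_deviance_explained(obs, rep(mean(obs), 4)), 0)
  expect_gt(percent_deviance_explained(obs, obs), 0.9999)
  # hand-computed two-deviance ratio
  null_dev <- -2 * (log(0.25) + 3 * log(0.75))
  expect_equal(percent_deviance_explained(obs, c(0.9, 0.1, 0.1, 0.1)),
               1 - (-2 * 4 * log(0.9)) / null_dev, tolerance = 1e-12)
  expect_equal(round(percent_deviance_explained(obs, c(0.9, 0.1, 0.1, 0.1)), 4),
               0.8126)
  expect_error(percent_deviance_explained(c(1, 1), c(0.5, 0.5)), "identical")
  # a worse-than-null model is allowed but reported
  expect_message(pde <- percent_deviance_explained(obs, c(0.1, 0.9, 0.9, 0.9)),
                 "less deviance")
  expect_lt(pde, 0)
})

test_that("hyperparameter validation rejects out-of-range values", {
  expect_error(brt_params(lr = 0), "lr")
  expect_error(brt_params(tc = 0), "tc")
  expect_error(brt_params(tc = 2.5), "tc")
  expect_error(brt_params(bf = 0), "bf")
  expect_error(brt_params(bf = 1.2), "bf")
  expect_error(brt_params(step_size = 0), "step_size")
  expect_error(brt_params(max_trees = 10, step_size = 50), "max_trees")
})

test_that("stratified folds partition every row exactly once, with presences spread", {
  set.seed(1)
  y <- rbinom(120, 1, 0.1)
  set.seed(2)
  fold <- reefsdm:::stratified_folds(y, 10)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 120)
  sizes <- as.numeric(table(fold))
  expect_equal(sum(sizes), 120)            # partition: every row in one fold
  expect_lte(max(sizes) - min(sizes), 2)   # balanced within one per class
  per_fold_pos <- tapply(y, fold, sum)
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 1)
})

test_that("a perfectly separating predictor is learned to AUC 1", {
  train <- separable_sites(n = 200, seed = 3)
  fit <- fit_brt_step(train, brt_params(lr = 0.05, tc = 2, bf = 1,
                                        max_trees = 200, step_size = 10,
                                        fold_count = 5, seed = 1),
                      predictors = "p1")
  # held-out draw keeps clear of the training gap, where the split sits
  held <- separable_sites(n = 100, seed = 99, lo = 0.35, hi = 0.65)
  expect_equal(auc(held$presence, predict(fit, held)), 1.0)
  expect_gt(fit$cv_pde, 0.5)
})

test_that("single-class training data are rejected", {
  train <- separable_sites(n = 60)
  train$presence <- 0L
  expect_error(fit_brt_step(train, brt_params(fold_count = 5)), "single class")
  expect_error(bootstrap_ensemble(train, brt_params(), n_boot = 5), "single class")
})

test_that("training deviance is non-increasing in ensemble size when bf = 1", {
  w <- small_world()
  train <- w$sites$train
  pars <- brt_params(lr = 0.05, tc = 2, bf = 1, max_trees = 100, step_size = 10,
                     fold_count = 5, seed = 4)
  fit <- suppressWarnings(fit_brt_step(train, pars, predictors = w$flt$retained))
  X <- reefsdm:::site_design_matrix(train, fit$feature_names)
  dm <- xgboost::xgb.DMatrix(X)
  devs <- vapply(seq(10, fit$n_trees_selected, by = 10), function(k) {
    p <- predict(fit$booster, dm, iterationrange = c(1L, k))
    bernoulli_deviance(train$presence, p)
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-8))
})

test_that("fitting is deterministic under a fixed seed", {
  w <- small_world()
  pars <- brt_params(lr = 0.01, tc = 3, bf = 0.75, max_trees = 100,
                     fold_count = 5, seed = 11)
  f1 <- suppressWarnings(fit_brt_step(w$sites$train, pars, predictors = w$flt$retained))
  f2 <- suppressWarnings(fit_brt_step(w$sites$train, pars, predictors = w$flt$retained))
  expect_identical(f1$n_trees_selected, f2$n_trees_selected)
  expect_identical(f1$cv_profile, f2$cv_profile)
  expect_equal(predict(f1, w$sites$test), predict(f2, w$sites$test))
  expect_equal(f1$trees, f2$trees)
})

test_that("a model that cannot beat the null has PDE at or below zero", {
  op <- random_obs_pred(n = 60, seed = 8)
  expect_equal(auc(op$obs, rep(0.3, 60)), 0.5)
  expect_lte(suppressMessages(percent_deviance_explained(op$obs, rep(0.3, 60))), 0)
})

test_that("a zero-tree model predicts its intercept everywhere", {
  m <- reefsdm:::new_brt_model(
    trees = tibble::tibble(tree = integer(), node = integer(),
                           feature = character(), split = numeric(),
                           yes = integer(), no = integer(), missing = integer(),
                           value = numeric()),
    intercept = qlogis(0.3), params = brt_params(), n_trees_selected = 0L,
    feature_names = c("a", "b"))
  stack <- predictor_stack(list(a = grid_surface(matrix(rnorm(16), 4, 4)),
                                b = grid_surface(matrix(rnorm(16), 4, 4))),
                           family = "spectral")
  surf <- predict_surface(m, stack)
  expect_equal(unique(round(as.numeric(surf), 12)), 0.3)
})

test_that("a hand-built single-split tree predicts its two leaf values", {
  # split: x < 5 -> leaf +1 ; else leaf -1 ; intercept 0
  trees <- tibble::tibble(
    tree = 0L, node = c(0L, 1L, 2L),
    feature = c("x", NA, NA), split = c(5, NA, NA),
    yes = c(1L, NA, NA), no = c(2L, NA, NA), missing = c(2L, NA, NA),
    value = c(NA, 1, -1))
  m <- reefsdm:::new_brt_model(trees = trees, intercept = 0,
                               params = brt_params(), n_trees_selected = 1L,
                               feature_names = "x")
  grid <- grid_surface(matrix(c(1, 4.999, 5, 9), 2, 2))
  stack <- predictor_stack(list(x = grid), family = "geographic")
  surf <- predict_surface(m, stack)
  expect_equal(as.numeric(surf), plogis(c(1, 1, -1, -1)))
  # missing predictor is reported by name
  expect_error(predict_surface(m, predictor_stack(list(z = grid), "spectral")),
               "x")
})

test_that("all surface predictions lie strictly inside (0, 1)", {
  m <- small_model()
  w <- small_world()
  surf <- predict_surface(m, subset_stack(w$sea$predictors, m$feature_names))
  v <- surf[!is.na(surf)]
  expect_true(all(v > 0 & v < 1))
})

test_that("the package's tree traversal reproduces the backend predictions", {
  m <- small_model()
  w <- small_world()
  X <- reefsdm:::site_design_matrix(w$sites$test, m$feature_names)
  own <- reefsdm:::predict_from_rules(m$trees, m$intercept, m$feature_names,
                                      X, m$n_trees_selected)
  backend <- predict(m, w$sites$test)
  expect_equal(own, backend, tolerance = 1e-5)
})

test_that("JSON serialization round-trips model predictions", {
  m <- small_model()
  w <- small_world()
  path <- withr::local_tempfile(fileext = ".json")
  write_brt_json(m, path)
  m2 <- read_brt_json(path)
  expect_null(m2$booster)
  expect_equal(m2$n_trees_selected, m$n_trees_selected)
  expect_equal(predict(m2, w$sites$test), predict(m, w$sites$test),
               tolerance = 1e-5)
})

test_that("grid tuning covers the Cartesian grid and breaks ties as documented", {
  w <- small_world()
  tn <- suppressWarnings(tune_grid(
    w$sites$train, lr_values = 0.01, tc_values = c(2, 3), bf_values = 0.75,
    fold_count = 5, max_trees = 100, seed = 2, predictors = w$flt$retained))
  expect_equal(nrow(tn$rows), 2)
  expect_setequal(tn$rows$tc, c(2, 3))
  expect_equal(tn$best$mean_cv_pde, max(tn$rows$mean_cv_pde))
  single <- suppressWarnings(tune_grid(
    w$sites$train, lr_values = 0.01, tc_values = 2, bf_values = 0.75,
    fold_count = 5, max_trees = 100, seed = 2, predictors = w$flt$retained))
  expect_equal(nrow(single$rows), 1)
  expect_equal(unlist(single$best[c("lr", "tc", "bf")]),
               c(lr = 0.01, tc = 2, bf = 0.75))
  expect_error(tune_grid(w$sites$train, lr_values = numeric(0)), "non-empty")
  expect_error(brt_params(lr = 0), "lr")
})

test_that("tidiers summarise models and tuning tables", {
  m <- small_model()
  td <- tidy(m)
  expect_true(all(c("term", "gain") %in% names(td)))
  expect_true(all(td$term %in% m$feature_names))
  g <- glance(m)
  expect_equal(g$n_trees, m$n_trees_selected)
  expect_equal(g$n, 292)
})
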