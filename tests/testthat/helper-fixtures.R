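# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small seascape + sites + filter, cached across test files.
small_world <- function(seed = 1L, rows = 32L, cols = 32L) {
  key <- sprintf("world_%d_%d_%d", seed, rows, cols)
  if (is.null(fixture_env[[key]])) {
    sea <- generate_seascape(seascape_config(grid_rows = rows, grid_cols = cols,
                                             seed = seed))
    sites <- sample_sites(sea)
    flt <- suppressWarnings(filter_correlated(sites$train))
    fixture_env[[key]] <- list(sea = sea, sites = sites, flt = flt)
  }
  fixture_env[[key]]
}

# A quickly fitted model on the small world, cached.
small_model <- function(seed = 1L) {
  key <- sprintf("model_%d", seed)
  if (is.null(fixture_env[[key]])) {
    w <- small_world(seed)
    fixture_env[[key]] <- suppressWarnings(fit_brt_step(
      w$sites$train,
      brt_params(lr = 0.01, tc = 3, bf = 0.75, max_trees = 300,
                 fold_count = 5, seed = seed + 50),
      predictors = w$flt$retained))
  }
  fixture_env[[key]]
}

# Separable two-class site table: one informative predictor.
separable_sites <- function(n = 200, seed = 3, lo = 0.4, hi = 0.6) {
  set.seed(seed)
  sep <- c(stats::runif(n / 2, 0, lo), stats::runif(n / 2, hi, 1))
  tibble::tibble(
    site_id = sprintf("s%03d", seq_len(n)),
    x = stats::runif(n) * 10, y = stats::runif(n) * 10,
    presence = rep(c(0L, 1L), each = n / 2),
    p1 = sep,
    p2 = stats::rnorm(n)
  )
}

# Random 0/1 obs + prediction vectors with both classes guaranteed.
random_obs_pred <- function(n = 40, seed = 1) {
  set.seed(seed)
  repeat {
    obs <- stats::rbinom(n, 1, 0.3)
    if (length(unique(obs)) == 2L) break
  }
  pred <- stats::runif(n)
  # introduce some ties
  pred[sample(n, n %/% 4)] <- sample(c(0.25, 0.5, 0.75), n %/% 4, replace = TRUE)
  list(obs = obs, pred = pred)
}
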