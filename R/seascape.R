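#' Configuration for a synthetic seascape
#'
#' Bundles the study-design constants the simulator emulates: a fine
#' (default 2 m) grid, 28 environmental predictors in three families, a rare
#' benthic assemblage (target prevalence 4.5 percent), 292 training sites,
#' 273 spatially independent stratified-random test sites, and six exclusion
#' plus six operation management zones.
#'
#' @param grid_rows,grid_cols grid dimensions in cells (each >= 16).
#' @param cell_size cell edge, metres (default 2).
#' @param n_spectral number of spectral-like predictor fields (default 15).
#' @param n_train,n_test training / test site counts (defaults 292 / 273).
#' @param target_prevalence spatial mean of the true occurrence probability
#'   (default 0.045); must lie strictly inside (0, 1).
#' @param n_exclusion_zones,n_operation_zones management zone counts
#'   (defaults 6 and 6).
#' @param amplitude scale of the environmental signal in the true model
#'   (default 2.2, a strongly habitat-specialist assemblage); 0 gives a flat
#'   landscape with constant true probability.
#' @param seed integer seed controlling every random draw.
#' @return a `seascape_config` list.
#' @export
seascape_config <- function(grid_rows = 64L, grid_cols = 64L, cell_size = 2,
                            n_spectral = 15L, n_train = 292L, n_test = 273L,
                            target_prevalence = 0.045,
                            n_exclusion_zones = 6L, n_operation_zones = 6L,
                            amplitude = 2.2, seed = 1L) {
  if (grid_rows < 16L || grid_cols < 16L) {
    stop("grid_rows and grid_cols must be >= 16", call. = FALSE)
  }
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    stop("target_prevalence must lie strictly between 0 and 1: ",
         "a constant-0 or constant-1 truth cannot be calibrated", call. = FALSE)
  }
  if (n_train < 20L || n_test < 20L) stop("n_train and n_test must be >= 20", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  structure(list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
                 cell_size = cell_size, n_spectral = as.integer(n_spectral),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 target_prevalence = target_prevalence,
                 n_exclusion_zones = as.integer(n_exclusion_zones),
                 n_operation_zones = as.integer(n_operation_zones),
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "seascape_config")
}

# Deterministic fan-out of one global seed into per-stage seeds (< 2^31).
split_seed <- function(seed, offset) {
  as.integer(((as.double(seed) %% 1048573) * 1024 + offset) %% 2147483647)
}

# Smooth mean-0 sd-1 Gaussian random field: white noise convolved with a
# separable Gaussian kernel (edge-renormalised), then standardised.
smooth_field <- function(nr, nc, range_cells = 6) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * range_cells))
  k <- stats::dnorm(-half:half, sd = range_cells)
  conv1 <- function(m, along_rows) {
    num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
    for (i in seq_along(k)) {
      off <- i - half - 1L
      s <- if (along_rows) shift_mat(m, 0L, off) else shift_mat(m, off, 0L)
      w <- !is.na(s)
      s[!w] <- 0
      num <- num + k[i] * s
      den <- den + k[i] * w
    }
    num / den
  }
  z <- conv1(conv1(z, TRUE), FALSE)
  (z - mean(z)) / stats::sd(z)
}

# Smooth depth-preference term of the true model: high on the shallow
# (~1.5-6.5 m) reef-flat band, low on exposed and deep cells.
depth_preference <- function(depth) {
  stats::plogis((depth - 1) / 0.5) * stats::plogis((7 - depth) / 1.0)
}

#' Generate a synthetic seascape with known truth
#'
#' Builds a gridded lagoon stand-in: a smooth bathymetry (positive metres
#' down, roughly 0-20 m), `n_spectral` spectral-like smooth fields partially
#' loaded on depth (four of which are near-duplicates of earlier bands so the
#' Spearman filter has redundancy to remove), nine topographic derivatives of
#' the depth grid, four geographic proxies, a true probability-of-occurrence
#' surface, and non-overlapping rectangular management zones.
#'
#' The truth is a logistic transform of a sparse nonlinear function of three
#' predictors (a smooth shallow-depth preference, the first spectral band and
#' proximity to the reef-crest feature), with its intercept calibrated by
#' root finding so the spatial mean probability equals `target_prevalence`.
#' Cells within one cell of the grid edge are nodata (the topographic window
#' is incomplete there) and the mask is shared by every layer.
#'
#' @param config a [seascape_config()].
#' @return a `seascape` list: `predictors` (28-layer [predictor_stack()]),
#'   `depth`, `true_probability`, `zones`, `features`, `config`.
#' @examples
#' sc <- generate_seascape(seascape_config(grid_rows = 32, grid_cols = 32, seed = 1))
#' mean(sc$true_probability, na.rm = TRUE)
#' @export
generate_seascape <- function(config) {
  stopifnot(inherits(config, "seascape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols; cs <- config$cell_size
  set.seed(split_seed(config$seed, 1L))

  width <- nc * cs; height <- nr * cs
  y_norm <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr)

  # bathymetry: smooth field plus a gentle deepening trend to the south
  depth <- 8 + 4 * smooth_field(nr, nc, range_cells = max(4, nr / 10)) +
    5 * (y_norm - 0.5) +
    0.08 * matrix(stats::rnorm(nr * nc), nr, nc)  # fine-scale seabed texture
  depth <- pmin(pmax(depth, 0.3), 20)
  depth_g <- grid_surface(depth, cs)

  # spectral bands: own smooth field plus a depth (attenuation) loading;
  # bands 2, 4, 6 and 12 are noisy monotone copies of bands 1, 3, 5, 11
  depthn <- as.numeric(scale(as.numeric(-depth)))
  depthn <- matrix(depthn, nr, nc)
  dup_of <- c(`2` = 1L, `4` = 3L, `6` = 5L, `12` = 11L)
  spectral <- vector("list", config$n_spectral)
  for (b in seq_len(config$n_spectral)) {
    key <- as.character(b)
    if (key %in% names(dup_of) && dup_of[[key]] <= length(spectral) &&
        !is.null(spectral[[dup_of[[key]]]])) {
      spectral[[b]] <- spectral[[dup_of[[key]]]] +
        0.06 * matrix(stats::rnorm(nr * nc), nr, nc)
    } else {
      w <- stats::runif(1, 0.25, 0.55)
      spectral[[b]] <- w * depthn +
        sqrt(1 - w^2) * smooth_field(nr, nc, range_cells = max(4, nr / 8))
    }
  }
  names(spectral) <- sprintf("spectral_%02d", seq_len(config$n_spectral))
  spectral_stack <- predictor_stack(lapply(spectral, grid_surface, cell_size = cs),
                                    family = "spectral")

  # geographic features: reef-crest proxy (L-strip along the north and west
  # edges) and a channel proxy blob in the south-east interior
  crest <- cbind(x = c(0, width, width, 2 * cs, 2 * cs, 0),
                 y = c(0, 0, 2 * cs, 2 * cs, height, height))
  channel <- rect_zone(0.45 * width, 0.65 * width, 0.40 * height, 0.60 * height)
  features <- zone_set(c("reef_crest", "channel"), c("corridor", "corridor"),
                       list(crest, channel))

  topo <- derive_topographic(depth_g, window_cells = 3L)
  geo <- derive_geographic(depth_g, features)
  predictors <- c_stacks(spectral_stack, topo, geo)

  # true model: sparse nonlinear function of depth, band 1 and crest distance
  shallow <- depth_preference(depth)
  band1 <- unclass(spectral_stack[["spectral_01"]])
  crest_prox <- exp(-unclass(geo[["dist_feature1"]]) / (0.3 * min(width, height)))
  signal <- config$amplitude *
    (3.5 * shallow + 1.2 * band1 + 2.5 * crest_prox)

  # shared nodata mask: one-cell margin where the 3x3 window is incomplete
  mask <- matrix(FALSE, nr, nc)
  mask[c(1L, nr), ] <- TRUE
  mask[, c(1L, nc)] <- TRUE
  signal[mask] <- NA_real_

  # calibrate the logistic intercept so mean probability = target prevalence
  target <- config$target_prevalence
  f <- function(b0) mean(stats::plogis(b0 + signal), na.rm = TRUE) - target
  b0 <- stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
  truth <- stats::plogis(b0 + signal)

  apply_mask <- function(g) { g[mask] <- NA_real_; g }
  predictors$grids <- lapply(predictors$grids, apply_mask)
  depth_masked <- apply_mask(depth_g)
  predictors$grids$depth <- depth_masked

  zones <- make_zones(nr, nc, cs,
                      config$n_exclusion_zones, config$n_operation_zones)

  structure(list(predictors = predictors,
                 depth = depth_masked,
                 true_probability = grid_surface(truth, cs),
                 zones = zones,
                 features = features,
                 intercept = b0,
                 config = config),
            class = "seascape")
}

# Non-overlapping rectangular management zones placed on a block lattice.
make_zones <- function(nr, nc, cs, n_exclusion, n_operation) {
  n_zones <- n_exclusion + n_operation
  nb <- ceiling(sqrt(n_zones))
  while (nb * nb < n_zones) nb <- nb + 1L
  blocks <- sample(nb * nb, n_zones)
  bw <- nc * cs / nb; bh <- nr * cs / nb
  vertices <- lapply(blocks, function(b) {
    bi <- (b - 1L) %% nb; bj <- (b - 1L) %/% nb
    x0 <- bi * bw; y0 <- bj * bh
    fx <- sort(stats::runif(2, 0.08, 0.92)); fy <- sort(stats::runif(2, 0.08, 0.92))
    # keep each rectangle at least one cell wide
    if ((fx[2] - fx[1]) * bw < cs) fx <- c(0.2, 0.2 + 1.2 * cs / bw)
    if ((fy[2] - fy[1]) * bh < cs) fy <- c(0.2, 0.2 + 1.2 * cs / bh)
    rect_zone(x0 + fx[1] * bw, x0 + fx[2] * bw, y0 + fy[1] * bh, y0 + fy[2] * bh)
  })
  zone_set(id = c(sprintf("excl_%d", seq_len(n_exclusion)),
                  sprintf("oper_%d", seq_len(n_operation))),
           zone_type = rep(c("exclusion", "operation"), c(n_exclusion, n_operation)),
           vertices = vertices)
}

#' @export
print.seascape <- function(x, ...) {
  cat(sprintf("<seascape> %d x %d cells (%g m), %d predictors, %d zones\n",
              nrow(x$depth), ncol(x$depth), cell_size(x$depth),
              length(x$predictors), nrow(x$zones)))
  cat(sprintf("  mean true probability %.4f (target %.4f)\n",
              mean(x$true_probability, na.rm = TRUE),
              x$config$target_prevalence))
  invisible(x)
}

#' Sample training and test sites from a seascape
#'
#' Training sites are a simple random sample of valid cells. Test sites are a
#' stratified random sample (strata = terciles of the true occurrence
#' probability, equal allocation) from the cells not used for training, so
#' train and test never share a grid cell and the test set retains presences
#' even at 4.5 percent prevalence. Presence at a site is a single Bernoulli
#' draw from the true probability of its cell; both tables carry the
#' extracted values of every predictor.
#'
#' @param seascape a [generate_seascape()] result.
#' @param config a [seascape_config()]; defaults to the one inside
#'   `seascape`.
#' @return a list with tibbles `train` and `test` (columns `site_id`, `x`,
#'   `y`, `presence`, predictors; test also carries `stratum`).
#' @export
sample_sites <- function(seascape, config = seascape$config) {
  stopifnot(inherits(seascape, "seascape"))
  truth <- seascape$true_probability
  valid <- which(!is.na(truth))
  if (config$n_train + config$n_test > length(valid)) {
    stop("requested ", config$n_train + config$n_test,
         " sites but only ", length(valid), " valid cells", call. = FALSE)
  }
  set.seed(split_seed(config$seed, 2L))

  train_cells <- sample(valid, config$n_train)
  remaining <- setdiff(valid, train_cells)

  p_rem <- truth[remaining]
  br <- stats::quantile(p_rem, c(1, 2) / 3, type = 7, names = FALSE)
  stratum <- if (br[1L] < br[2L]) {
    cut(p_rem, c(-Inf, br, Inf), labels = c("low", "mid", "high"))
  } else {
    # (near-)constant truth: fall back to rank-based thirds
    cut(rank(p_rem, ties.method = "first"), 3L, labels = c("low", "mid", "high"))
  }
  n_per <- rep(config$n_test %/% 3L, 3L)
  extra <- config$n_test - sum(n_per)
  if (extra > 0L) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L
  test_cells <- integer(0)
  for (s in seq_along(levels(stratum))) {
    pool <- remaining[as.integer(stratum) == s]
    if (length(pool) < n_per[s]) {
      stop("stratum ", levels(stratum)[s], " has only ", length(pool),
           " cells for ", n_per[s], " test sites", call. = FALSE)
    }
    test_cells <- c(test_cells, sample(pool, n_per[s]))
  }

  cell_table <- function(cells, prefix) {
    rc <- arrayInd(cells, dim(truth))
    cs <- cell_size(truth)
    p <- truth[cells]
    tibble::tibble(
      site_id = sprintf("%s_%03d", prefix, seq_along(cells)),
      x = (rc[, 2L] - 0.5) * cs,
      y = (rc[, 1L] - 0.5) * cs,
      presence = stats::rbinom(length(cells), 1L, p)
    )
  }
  train <- cell_table(train_cells, "tr")
  test <- cell_table(test_cells, "te")
  test$stratum <- as.character(stratum[match(test_cells, remaining)])

  list(train = extract_at_sites(train, seascape$predictors),
       test = extract_at_sites(test, seascape$predictors))
}

#' Read and write site tables as CSV
#'
#' The site-table dialect: a header `site_id,x,y,presence` followed by one
#' column per predictor (and, for stratified test sets, a `stratum` column).
#'
#' @param sites a site tibble.
#' @param path file path.
#' @return `read_sites_csv()` returns a tibble; `write_sites_csv()` returns
#'   `path` invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
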