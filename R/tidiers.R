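#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods
#'
#' broom-style summaries of the package's fitted objects: `tidy()` returns
#' one row per component (predictor importance for a model, one row per
#' tuning combination, per threshold method, per cell statistic), `glance()`
#' one row per object.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @return a tibble.
#' @name reefsdm-tidiers
NULL

#' @rdname reefsdm-tidiers
#' @export
tidy.brt_model <- function(x, ...) {
  if (!is.null(x$booster)) {
    imp <- xgboost::xgb.importance(model = x$booster)
    return(tibble::tibble(term = imp$Feature, gain = imp$Gain,
                          cover = imp$Cover, frequency = imp$Frequency))
  }
  splits <- x$trees[!is.na(x$trees$feature), , drop = FALSE]
  counts <- table(factor(splits$feature, levels = x$feature_names))
  tibble::tibble(term = names(counts),
                 frequency = as.numeric(counts) / max(1L, sum(counts)))
}

#' @rdname reefsdm-tidiers
#' @export
glance.brt_model <- function(x, ...) {
  tibble::tibble(lr = x$params$lr, tc = x$params$tc, bf = x$params$bf,
                 n_trees = x$n_trees_selected, cv_pde = x$cv_pde,
                 n = x$train_summary$n %||% NA_integer_,
                 prevalence = x$train_summary$prevalence %||% NA_real_)
}

#' @rdname reefsdm-tidiers
#' @export
tidy.tuning_result <- function(x, ...) x$rows

#' @rdname reefsdm-tidiers
#' @export
glance.tuning_result <- function(x, ...) {
  dplyr::bind_cols(x$best, tibble::tibble(fold_count = x$fold_count,
                                          n_combinations = nrow(x$rows)))
}

#' @rdname reefsdm-tidiers
#' @export
tidy.threshold_set <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "threshold_set")
  out
}

#' @rdname reefsdm-tidiers
#' @export
tidy.ensemble_surfaces <- function(x, ...) {
  dplyr::bind_cols(
    as_tibble(x$mean)[c("row", "col", "x", "y")],
    tibble::tibble(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                   cov = as.numeric(x$cov))
  )
}

#' @rdname reefsdm-tidiers
#' @export
glance.ensemble_surfaces <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot,
                 mean_probability = mean(x$mean, na.rm = TRUE),
                 mean_cov = mean(x$cov, na.rm = TRUE),
                 max_cov = max(x$cov, na.rm = TRUE))
}
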