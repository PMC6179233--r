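#' Bernoulli deviance and percent deviance explained
#'
#' `bernoulli_deviance()` is the loss underlying every model comparison in
#' this package: `-2 * sum(y * log(p) + (1 - y) * log(1 - p))`, with
#' predictions clipped to `[eps, 1 - eps]` before taking logs.
#' `percent_deviance_explained()` (PDE) is the share of the null (intercept
#' only) deviance removed by a model,
#' `1 - deviance(obs, pred) / deviance(obs, mean(obs))`, reported as a
#' fraction; it can be negative for a worse-than-null model.
#'
#' @param obs 0/1 observation vector.
#' @param pred probability vector, same length.
#' @param eps clipping bound for probabilities (default 1e-9).
#' @return a single number: the total deviance, or the PDE fraction.
#' @examples
#' bernoulli_deviance(c(1, 0, 0, 0), c(0.9, 0.1, 0.1, 0.1))
#' percent_deviance_explained(c(1, 0, 0, 0), c(0.9, 0.1, 0.1, 0.1))
#' @export
bernoulli_deviance <- function(obs, pred, eps = 1e-9) {
  if (length(obs) == 0L || length(pred) == 0L) stop("empty vectors", call. = FALSE)
  if (length(obs) != length(pred)) stop("obs and pred lengths differ", call. = FALSE)
  if (!all(obs %in% c(0, 1))) stop("obs must be 0/1", call. = FALSE)
  p <- pmin(pmax(pred, eps), 1 - eps)
  -2 * sum(obs * log(p) + (1 - obs) * log(1 - p))
}

#' @rdname bernoulli_deviance
#' @export
percent_deviance_explained <- function(obs, pred, eps = 1e-9) {
  if (length(obs) == 0L) stop("empty vectors", call. = FALSE)
  if (length(unique(obs)) < 2L) {
    stop("PDE undefined: all observations identical (null deviance 0)", call. = FALSE)
  }
  null_dev <- bernoulli_deviance(obs, rep(mean(obs), length(obs)), eps)
  pde <- 1 - bernoulli_deviance(obs, pred, eps) / null_dev
  if (pde < 0) message("model explains less deviance than the null (PDE ", signif(pde, 3), ")")
  pde
}
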