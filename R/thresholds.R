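#' ROC curve on the independent test set
#'
#' Builds the receiver operating characteristic of a probability prediction
#' against 0/1 observations. Candidate thresholds are the sorted unique
#' predicted values plus the sentinels 0 (everything classified present:
#' sensitivity 1, specificity 0) and 1 (everything absent: specificity 1).
#' A site is classified present when its prediction is at or above the
#' threshold.
#'
#' @param obs 0/1 observation vector (both classes required).
#' @param pred probability vector, same length.
#' @return a `roc_curve` tibble (`threshold`, `sens`, `spec`) with
#'   `obs_prevalence` and `n_test` attributes.
#' @export
roc_curve <- function(obs, pred) {
  check_two_classes(obs, pred)
  thresholds <- c(0, sort(unique(pred)), 1)
  n_pos <- sum(obs == 1); n_neg <- sum(obs == 0)
  sens <- vapply(thresholds, function(t) sum(pred >= t & obs == 1) / n_pos, numeric(1))
  spec <- vapply(thresholds, function(t) sum(pred < t & obs == 0) / n_neg, numeric(1))
  out <- tibble::tibble(threshold = thresholds, sens = sens, spec = spec)
  attr(out, "obs_prevalence") <- mean(obs)
  attr(out, "n_test") <- length(obs)
  class(out) <- c("roc_curve", class(out))
  out
}

check_two_classes <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ", call. = FALSE)
  if (!all(obs %in% c(0, 1))) stop("obs must be 0/1", call. = FALSE)
  if (length(unique(obs)) < 2L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Computed two ways that must agree: the Mann-Whitney rank statistic
#' (`P(pred at a presence > pred at an absence) + 0.5 P(tie)`) and the
#' trapezoid rule on the ROC curve. A disagreement beyond 1e-9 aborts, as it
#' would indicate an internal inconsistency.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 0, 0, 0), c(0.6, 0.7, 0.2, 0.1))  # 2/3
#' @export
auc <- function(obs, pred) {
  check_two_classes(obs, pred)
  r <- rank(pred)
  n_pos <- sum(obs == 1); n_neg <- sum(obs == 0)
  auc_rank <- (sum(r[obs == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  roc <- roc_curve(obs, pred)
  fpr <- rev(1 - roc$spec); tpr <- rev(roc$sens)   # ascending fpr
  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  if (abs(auc_rank - auc_trap) > 1e-9) {
    stop("internal AUC inconsistency: rank ", auc_rank, " vs trapezoid ", auc_trap,
         call. = FALSE)
  }
  auc_rank
}

# Cohen's kappa and companions from (possibly non-integer) confusion counts.
metrics_from_counts <- function(tp, fp, fn, tn, threshold = NA_real_) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (isTRUE(all.equal(pe, 1))) {
    stop("kappa undefined: degenerate marginals (expected agreement 1)", call. = FALSE)
  }
  tibble::tibble(
    threshold = threshold,
    accuracy = po,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    kappa = (po - pe) / (1 - pe),
    predicted_prevalence = (tp + fp) / n
  )
}

#' Confusion-matrix metrics at a threshold
#'
#' Classifies `pred >= threshold` as presence and reports accuracy,
#' sensitivity, specificity, Cohen's kappa (`(Po - Pe) / (1 - Pe)` with `Pe`
#' from the marginal products) and predicted prevalence.
#' [metrics_from_rates()] reconstructs the same metrics from printed
#' sensitivity/specificity at a given prevalence and n — expected
#' (non-integer) counts — for table-consistency checks.
#'
#' @inheritParams roc_curve
#' @param threshold probability threshold in `[0, 1]`.
#' @return a one-row tibble of threshold metrics.
#' @examples
#' metrics_from_rates(0.42, 1.00, prevalence = 0.045, n = 273)$kappa  # 0.58
#' @export
confusion_metrics <- function(obs, pred, threshold) {
  check_two_classes(obs, pred)
  pos <- pred >= threshold
  metrics_from_counts(tp = sum(pos & obs == 1), fp = sum(pos & obs == 0),
                      fn = sum(!pos & obs == 1), tn = sum(!pos & obs == 0),
                      threshold = threshold)
}

#' @rdname confusion_metrics
#' @param sensitivity,specificity printed classification rates.
#' @param prevalence observed presence fraction.
#' @param n number of test sites.
#' @export
metrics_from_rates <- function(sensitivity, specificity, prevalence, n) {
  n_pos <- prevalence * n
  n_neg <- (1 - prevalence) * n
  metrics_from_counts(tp = sensitivity * n_pos, fn = (1 - sensitivity) * n_pos,
                      tn = specificity * n_neg, fp = (1 - specificity) * n_neg)
}

#' Optimize the presence/absence threshold four ways
#'
#' Scans every ROC candidate threshold and selects, per rule:
#' * `ses` — sensitivity equals specificity: argmin of `|sens - spec|`;
#' * `mss` — maximum sensitivity plus specificity: argmax of `sens + spec`;
#' * `ppop` — predicted prevalence equals observed prevalence: argmin of
#'   `|predicted prevalence - observed prevalence|` (observed prevalence
#'   taken from the test sites);
#' * `max_kappa` — argmax of Cohen's kappa.
#'
#' Ties resolve to the lowest threshold — the over-prediction
#' (precautionary) direction. With a good model SES and MSS can coincide.
#'
#' @inheritParams roc_curve
#' @return a `threshold_set` tibble: one row per method with its threshold
#'   and [confusion_metrics()].
#' @export
optimize_thresholds <- function(obs, pred) {
  check_two_classes(obs, pred)
  cands <- sort(unique(pred))
  tab <- dplyr::bind_rows(lapply(cands, function(t) confusion_metrics(obs, pred, t)))
  obs_prev <- mean(obs)
  pick <- c(
    ses = which.min(abs(tab$sensitivity - tab$specificity)),
    mss = which.max(tab$sensitivity + tab$specificity),
    ppop = which.min(abs(tab$predicted_prevalence - obs_prev)),
    max_kappa = which.max(tab$kappa)
  )
  out <- tab[pick, ]
  out <- dplyr::bind_cols(tibble::tibble(method = names(pick)), out)
  attr(out, "obs_prevalence") <- obs_prev
  attr(out, "n_test") <- length(obs)
  class(out) <- c("threshold_set", class(out))
  out
}

#' Reclassify a probability surface at a threshold
#'
#' @param prob a probability [grid_surface()].
#' @param threshold probability threshold in `[0, 1]`; cells with
#'   `prob >= threshold` become 1, others 0, nodata preserved.
#' @return a binary `grid_surface`.
#' @export
classify_surface <- function(prob, threshold) {
  stopifnot(is_grid_surface(prob))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single probability in [0, 1]", call. = FALSE)
  }
  grid_like(matrix(as.numeric(unclass(prob) >= threshold), nrow(prob), ncol(prob)),
            prob)
}
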