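test_that("ROC points match hand-worked separable cases", {
  obs <- c(0, 0, 1, 1); pred <- c(0.1, 0.2, 0.7, 0.9)
  roc <- roc_curve(obs, pred)
  at <- function(t) roc[roc$threshold == t, ]
  expect_equal(at(0.7)$sens, 1)
  expect_equal(at(0.7)$spec, 1)
  expect_equal(at(0)$sens, 1)     # below every prediction: everything present
  expect_equal(at(0)$spec, 0)
  expect_equal(at(1)$spec, 1)
  expect_equal(attr(roc, "obs_prevalence"), 0.5)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("ROC sens/spec equal exhaustive confusion-matrix enumeration", {
  op <- random_obs_pred(n = 8, seed = 2)
  roc <- roc_curve(op$obs, op$pred)
  for (i in seq_len(nrow(roc))) {
    t <- roc$threshold[i]
    tp <- sum(op$pred >= t & op$obs == 1); fn <- sum(op$pred < t & op$obs == 1)
    tn <- sum(op$pred < t & op$obs == 0); fp <- sum(op$pred >= t & op$obs == 0)
    expect_equal(roc$sens[i], tp / (tp + fn))
    expect_equal(roc$spec[i], tn / (tn + fp))
  }
  # monotone: sens non-increasing, spec non-decreasing in the threshold
  expect_true(all(diff(roc$sens) <= 0))
  expect_true(all(diff(roc$spec) >= 0))
})

test_that("AUC agrees with closed forms and concordant-pair counts", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 1)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_equal(auc(c(1, 0, 0, 0), c(0.6, 0.7, 0.2, 0.1)), 2 / 3)
})

test_that("AUC is invariant under strictly monotone transforms and matches pROC", {
  op <- random_obs_pred(n = 60, seed = 4)
  a <- auc(op$obs, op$pred)
  expect_equal(auc(op$obs, plogis(5 * op$pred - 2)), a, tolerance = 1e-12)
  expect_equal(auc(op$obs, op$pred^3), a, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(op$obs, op$pred, quiet = TRUE,
                                                 direction = "<",
                                                 levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("rank-statistic AUC equals the trapezoid on the ROC curve", {
  for (s in 1:20) {
    op <- random_obs_pred(n = 30 + s, seed = s)
    roc <- roc_curve(op$obs, op$pred)
    fpr <- rev(1 - roc$spec); tpr <- rev(roc$sens)
    trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(auc(op$obs, op$pred), trap, tolerance = 1e-12)
  }
})

test_that("confusion metrics reproduce printed performance-table rows", {
  # expected-count reconstructions at prevalence 4.5%, n = 273
  ses <- metrics_from_rates(0.92, 0.85, prevalence = 0.045, n = 273)
  expect_equal(round(ses$accuracy, 2), 0.85)
  ppop <- metrics_from_rates(0.50, 0.98, prevalence = 0.045, n = 273)
  expect_equal(round(ppop$accuracy, 2), 0.96)
  kap <- metrics_from_rates(0.42, 1.00, prevalence = 0.045, n = 273)
  expect_equal(round(kap$kappa, 2), 0.58)
  # accuracy identity: acc = sens * prev + spec * (1 - prev)
  expect_equal(ses$accuracy, 0.92 * 0.045 + 0.85 * 0.955, tolerance = 1e-12)
  expect_equal(ppop$accuracy, 0.50 * 0.045 + 0.98 * 0.955, tolerance = 1e-12)
})

test_that("kappa matches hand Po/Pe arithmetic on integer counts", {
  # TP = 5, FP = 0, FN = 7, TN = 261 (n = 273)
  obs <- c(rep(1, 12), rep(0, 261))
  pred <- c(rep(0.9, 5), rep(0.1, 7), rep(0.1, 261))
  cm <- confusion_metrics(obs, pred, threshold = 0.5)
  po <- 266 / 273
  pe <- ((5 / 273) * (12 / 273)) + ((268 / 273) * (261 / 273))
  expect_equal(cm$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(round(cm$kappa, 3), 0.577)
  expect_equal(cm$predicted_prevalence, 5 / 273)
})

test_that("degenerate marginals make kappa undefined", {
  expect_error(metrics_from_rates(1, 0.5, prevalence = 1, n = 100), "undefined")
})

test_that("the four optimizers match an exhaustive candidate scan", {
  obs <- c(0, 0, 1, 1); pred <- c(0.1, 0.2, 0.7, 0.9)
  ts <- optimize_thresholds(obs, pred)
  expect_equal(ts$threshold[ts$method == "mss"], 0.7)
  expect_equal(ts$sensitivity[ts$method == "mss"], 1)
  expect_equal(ts$specificity[ts$method == "mss"], 1)
  expect_equal(ts$threshold[ts$method == "ppop"], 0.7)
  expect_equal(ts$predicted_prevalence[ts$method == "ppop"], 0.5)

  for (s in 1:20) {
    op <- random_obs_pred(n = 12, seed = 100 + s)
    ts <- optimize_thresholds(op$obs, op$pred)
    cands <- sort(unique(op$pred))
    scan <- do.call(rbind, lapply(cands, function(t) {
      tp <- sum(op$pred >= t & op$obs == 1); fn <- sum(op$pred < t & op$obs == 1)
      tn <- sum(op$pred < t & op$obs == 0); fp <- sum(op$pred >= t & op$obs == 0)
      n <- length(op$obs)
      po <- (tp + tn) / n
      pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
      data.frame(t = t, sens = tp / (tp + fn), spec = tn / (tn + fp),
                 kappa = (po - pe) / (1 - pe), pp = (tp + fp) / n)
    }))
    pick_lowest <- function(score, maximize) {
      best <- if (maximize) max(score) else min(score)
      scan$t[which(score == best)[1]]
    }
    expect_equal(ts$threshold[ts$method == "ses"],
                 pick_lowest(-abs(scan$sens - scan$spec), TRUE))
    expect_equal(ts$threshold[ts$method == "mss"],
                 pick_lowest(scan$sens + scan$spec, TRUE))
    expect_equal(ts$threshold[ts$method == "ppop"],
                 pick_lowest(-abs(scan$pp - mean(op$obs)), TRUE))
    expect_equal(ts$threshold[ts$method == "max_kappa"],
                 pick_lowest(scan$kappa, TRUE))
  }
})

test_that("surface classification respects the >= rule and nodata", {
  m <- matrix(c(0.05, 0.17, 0.3, NA, 0.169, 0.9, 0.01, 0.17, 0.5), 3, 3)
  g <- grid_surface(m, 2)
  mask <- classify_surface(g, 0.17)
  expect_equal(as.numeric(mask), as.numeric(m >= 0.17))
  expect_true(is.na(mask[1, 2]))
  expect_equal(sum(classify_surface(g, 0) == 1, na.rm = TRUE), 8)  # all valid cells
  expect_equal(sum(classify_surface(g, 0.95) == 1, na.rm = TRUE), 0)
  expect_error(classify_surface(g, 1.5), "probability")
  # nesting: a higher threshold is a subset of a lower one
  m1 <- classify_surface(g, 0.1); m2 <- classify_surface(g, 0.4)
  expect_true(all(m2[m2 == 1] <= m1[m2 == 1], na.rm = TRUE))
  expect_true(all(which(m2 == 1) %in% which(m1 == 1)))
})
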