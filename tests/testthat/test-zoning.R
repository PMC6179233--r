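test_that("tercile breakpoints follow the interpolated order-statistic formula", {
  cov <- grid_surface(matrix(seq(0.1, 0.9, by = 0.1), 3, 3))
  fp <- grid_surface(matrix(1, 3, 3))
  pc <- precision_terciles(cov, fp)
  expect_equal(round(pc$q33, 4), 0.3667)
  expect_equal(round(pc$q67, 4), 0.6333)
  expect_equal(pc$qmax, 0.9)
  # oracle: position 1 + (n - 1) p interpolation, computed directly
  v <- sort(seq(0.1, 0.9, by = 0.1))
  pos <- 1 + (9 - 1) * (1 / 3)
  expect_equal(pc$q33, v[floor(pos)] + (pos - floor(pos)) * (v[ceiling(pos)] - v[floor(pos)]))
  expect_error(precision_terciles(cov, grid_surface(matrix(0, 3, 3))), "empty")
})

test_that("random tercile fixtures match the order-statistic oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- 20 + s
    vals <- runif(n)
    side <- ceiling(sqrt(n))
    m <- matrix(NA_real_, side, side); m[seq_len(n)] <- vals
    fp <- matrix(0, side, side); fp[seq_len(n)] <- 1
    pc <- precision_terciles(grid_surface(m), grid_surface(fp))
    v <- sort(vals)
    oracle <- function(p) {
      pos <- 1 + (n - 1) * p
      lo <- floor(pos); hi <- ceiling(pos)
      v[lo] + (pos - lo) * (v[hi] - v[lo])
    }
    expect_equal(pc$q33, oracle(1 / 3), tolerance = 1e-12)
    expect_equal(pc$q67, oracle(2 / 3), tolerance = 1e-12)
    expect_equal(pc$qmax, max(vals))
  }
})

test_that("terciles of a normal CoV field sit near its analytic quantiles", {
  set.seed(42)
  n <- 10000; side <- 100
  cov <- grid_surface(matrix(rnorm(n, 0.47, 0.12), side, side))
  fp <- grid_surface(matrix(1, side, side))
  pc <- precision_terciles(cov, fp)
  expect_equal(pc$q33, qnorm(1 / 3, 0.47, 0.12), tolerance = 0.02 / 0.43)
  expect_equal(pc$q67, qnorm(2 / 3, 0.47, 0.12), tolerance = 0.02 / 0.52)
})

test_that("a constant CoV collapses the three precision masks onto the footprint", {
  prob <- grid_surface(matrix(runif(36, 0.2, 0.8), 6, 6))
  cov <- grid_surface(matrix(0.5, 6, 6))
  maps <- combo_maps(prob, cov, c(0.3, 0.4, 0.5))
  for (lv in c("low", "moderate", "high")) {
    sub <- maps[maps$probability_level == lv, ]
    fp <- classify_surface(prob, sub$threshold[1])
    for (i in 1:3) {
      expect_equal(unclass(sub$mask[[i]]), unclass(fp), ignore_attr = TRUE)
    }
  }
})

test_that("nine combination maps equal manual cell-by-cell enumeration on a 6x6 grid", {
  set.seed(13)
  pm <- matrix(runif(36), 6, 6); cm <- matrix(runif(36, 0, 2), 6, 6)
  prob <- grid_surface(pm); cov <- grid_surface(cm)
  triple <- c(0.2, 0.45, 0.7)
  maps <- combo_maps(prob, cov, triple)
  expect_equal(nrow(maps), 9)
  for (i in seq_len(3)) {
    t <- triple[i]
    vals <- cm[pm >= t]
    cuts <- c(quantile(vals, 1 / 3, type = 7, names = FALSE),
              quantile(vals, 2 / 3, type = 7, names = FALSE), max(vals))
    lv <- c("low", "moderate", "high")[i]
    sub <- maps[maps$probability_level == lv, ]
    expect_equal(sub$precision_level, c("high", "moderate", "low"))
    expect_equal(sub$cov_cutoff, cuts)
    for (j in 1:3) {
      manual <- (pm >= t) & (cm <= cuts[j])
      expect_equal(unclass(sub$mask[[j]]), matrix(as.numeric(manual), 6, 6),
                   ignore_attr = TRUE)
    }
  }
})

test_that("combination masks nest cumulatively and bottom out at the footprint", {
  w <- small_world()
  prob <- w$sea$true_probability  # any probability surface exercises the logic
  set.seed(3)
  cov <- grid_surface(matrix(runif(length(prob), 0.1, 1.8), nrow(prob), ncol(prob)),
                      cell_size(prob))
  cov[is.na(prob)] <- NA
  triple <- quantile(prob[!is.na(prob)], c(0.5, 0.8, 0.95), names = FALSE)
  maps <- combo_maps(prob, cov, triple)
  for (lv in c("low", "moderate", "high")) {
    sub <- maps[maps$probability_level == lv, ]
    hi <- which(sub$mask[[1]] == 1); mo <- which(sub$mask[[2]] == 1)
    lo <- which(sub$mask[[3]] == 1)
    expect_true(all(hi %in% mo))
    expect_true(all(mo %in% lo))
    fp <- classify_surface(prob, sub$threshold[1])
    expect_equal(lo, which(fp == 1))  # low precision cutoff = footprint max
  }
  # footprints nest across probability thresholds
  fps <- lapply(triple, function(t) which(classify_surface(prob, t) == 1))
  expect_true(all(fps[[3]] %in% fps[[2]]))
  expect_true(all(fps[[2]] %in% fps[[1]]))
  # area monotonicity along both axes of the 3x3 table
  area <- function(p, c) maps$area_m2[maps$probability_level == p &
                                        maps$precision_level == c]
  for (cc in c("high", "moderate", "low")) {
    expect_true(area("low", cc) >= area("moderate", cc))
    expect_true(area("moderate", cc) >= area("high", cc))
  }
  for (pp in c("low", "moderate", "high")) {
    expect_true(area(pp, "low") >= area(pp, "moderate"))
    expect_true(area(pp, "moderate") >= area(pp, "high"))
  }
})

test_that("zonal areas match direct cell counting", {
  ones <- grid_surface(matrix(1, 10, 10), cell_size = 2)
  zones <- zone_set("z1", "exclusion", list(rect_zone(0, 10, 0, 10)))  # 25 cells
  za <- zonal_area(ones, zones)
  expect_equal(za$area_m2[za$zone_id == "z1"], 100)
  expect_equal(za$area_m2[za$zone_id == "outside"], 300)
  expect_equal(attr(za, "total_area_m2"), 400)
  # empty mask
  za0 <- zonal_area(grid_surface(matrix(0, 10, 10), 2), zones)
  expect_true(all(za0$area_m2 == 0))
  # zone tiling the whole grid leaves nothing outside
  tiling <- zone_set("all", "operation", list(rect_zone(0, 20, 0, 20)))
  zaf <- zonal_area(ones, tiling)
  expect_equal(zaf$area_m2[zaf$zone_id == "outside"], 0)
  expect_equal(zaf$area_m2[zaf$zone_id == "all"], 400)
})

test_that("zonal accounting conserves area on random fixtures", {
  for (s in 1:10) {
    set.seed(s)
    mask <- grid_surface(matrix(rbinom(400, 1, 0.3), 20, 20), cell_size = 2)
    zones <- zone_set(c("a", "b"), c("exclusion", "operation"),
                      list(rect_zone(0, 14, 0, 20), rect_zone(20, 34, 6, 30)))
    za <- zonal_area(mask, zones)
    expect_equal(sum(za$area_m2), attr(za, "total_area_m2"))
    expect_equal(attr(za, "total_area_m2"), sum(mask == 1, na.rm = TRUE) * 4)
    expect_true(all(za$area_m2 >= 0))
  }
})

test_that("the sensitivity report summarises totals, zone presence and ratios", {
  set.seed(21)
  prob <- grid_surface(matrix(runif(100), 10, 10), 2)
  cov <- grid_surface(matrix(runif(100, 0, 2), 10, 10), 2)
  zones <- zone_set(c("a", "b"), c("exclusion", "operation"),
                    list(rect_zone(0, 8, 0, 8), rect_zone(12, 20, 12, 20)))
  maps <- combo_maps(prob, cov, c(0.2, 0.5, 0.8))
  rep_all <- zonal_report_all(maps, zones)
  expect_equal(nrow(rep_all), 9 * 3)  # 2 zones + outside per combo
  sens <- sensitivity_report(rep_all)
  expect_equal(nrow(sens$totals), 9)
  expect_equal(sens$totals$area_m2[order(sens$totals$combo)],
               maps$area_m2[order(paste0(maps$probability_level, "_prob/",
                                         maps$precision_level, "_prec"))])
  # zone-presence counts agree with a brute-force recount
  for (i in seq_len(nrow(maps))) {
    mem <- zone_membership(maps$mask[[i]], zones)
    brute <- sum(vapply(1:2, function(k) {
      any(maps$mask[[i]][mem == k] == 1, na.rm = TRUE)
    }, logical(1)))
    got <- sens$zones_present$n_zones_present[
      sens$zones_present$probability_level == maps$probability_level[i] &
        sens$zones_present$precision_level == maps$precision_level[i]]
    expect_equal(got, brute)
  }
  # identical combos give unit ratios
  same <- maps
  for (i in seq_len(nrow(same))) same$mask[[i]] <- maps$mask[[1]]
  same$area_m2 <- maps$area_m2[1]
  sens_same <- sensitivity_report(zonal_report_all(same, zones))
  expect_true(all(abs(sens_same$ratios$ratio - 1) < 1e-12))
})
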