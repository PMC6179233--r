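#' Precision terciles within a probability footprint
#'
#' Splits the coefficient-of-variation values found inside a probability
#' footprint (cells at or above a probability threshold) at their empirical
#' 1/3 and 2/3 quantiles (linear interpolation of order statistics, position
#' `1 + (n - 1) p`) and the footprint maximum. The three cumulative cutoffs
#' define the high (`CoV <= q33`), moderate (`CoV <= q67`) and low
#' (`CoV <= max`) precision classes.
#'
#' @param cov a CoV [grid_surface()].
#' @param footprint a binary `grid_surface` (1 = inside the footprint).
#' @param probability_threshold optional threshold recorded for reporting.
#' @return a `precision_classing` list: `q33`, `q67`, `qmax`, `n_cells`,
#'   `probability_threshold`.
#' @examples
#' cov <- grid_surface(matrix(seq(0.1, 0.9, by = 0.1), 3, 3))
#' fp <- grid_surface(matrix(1, 3, 3))
#' precision_terciles(cov, fp)$q33  # 0.3667
#' @export
precision_terciles <- function(cov, footprint, probability_threshold = NA_real_) {
  check_aligned(list(cov, footprint))
  vals <- cov[!is.na(footprint) & footprint == 1]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("footprint is empty: no CoV values to class", call. = FALSE)
  q <- stats::quantile(vals, c(1, 2) / 3, type = 7, names = FALSE)
  structure(list(q33 = q[1L], q67 = q[2L], qmax = max(vals),
                 n_cells = length(vals),
                 probability_threshold = probability_threshold),
            class = "precision_classing")
}

#' @export
print.precision_classing <- function(x, ...) {
  cat(sprintf("<precision_classing> q33 %.4g, q67 %.4g, max %.4g (%d cells)\n",
              x$q33, x$q67, x$qmax, x$n_cells))
  invisible(x)
}

#' Nine probability-by-precision combination maps
#'
#' For each of three probability thresholds (low <= moderate <= high), takes
#' the footprint `prob >= t`, classes its CoV values into precision terciles,
#' and emits the three cumulative masks `prob >= t & CoV <= cutoff`
#' (high/moderate/low precision). Within a probability level the masks nest:
#' high precision is a subset of moderate, moderate of low, and the
#' low-precision mask equals the footprint. An empty footprint yields empty
#' masks with a warning.
#'
#' @param prob mean probability [grid_surface()].
#' @param cov CoV `grid_surface` from the same ensemble.
#' @param prob_thresholds numeric triple, ascending: the low, moderate and
#'   high probability thresholds (e.g. the SES/MSS, PPOP and max-kappa
#'   selections).
#' @return a `combo_maps` tibble with 9 rows: `probability_level`,
#'   `precision_level`, `threshold`, `cov_cutoff`, `n_cells`, `area_m2` and a
#'   `mask` list-column of binary grids.
#' @export
combo_maps <- function(prob, cov, prob_thresholds) {
  check_aligned(list(prob, cov))
  if (length(prob_thresholds) != 3L) stop("need three probability thresholds", call. = FALSE)
  if (is.unsorted(prob_thresholds)) {
    stop("prob_thresholds must be ascending (low <= moderate <= high)", call. = FALSE)
  }
  levels_p <- c("low", "moderate", "high")
  levels_c <- c("high", "moderate", "low")  # precision, strictest first
  area <- cell_area(prob)
  rows <- list()
  for (i in seq_len(3L)) {
    t <- prob_thresholds[i]
    fp <- classify_surface(prob, t)
    if (sum(fp == 1, na.rm = TRUE) == 0L) {
      warning("empty footprint at probability threshold ", t, call. = FALSE)
      for (j in seq_len(3L)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          probability_level = levels_p[i], precision_level = levels_c[j],
          threshold = t, cov_cutoff = NA_real_, n_cells = 0L, area_m2 = 0,
          mask = list(grid_like(matrix(0, nrow(prob), ncol(prob)), prob)))
      }
      next
    }
    pc <- precision_terciles(cov, fp, probability_threshold = t)
    cutoffs <- c(pc$q33, pc$q67, pc$qmax)
    for (j in seq_len(3L)) {
      m <- unclass(fp) == 1 & unclass(cov) <= cutoffs[j]
      m[is.na(unclass(fp))] <- NA
      mask <- grid_like(matrix(as.numeric(m), nrow(prob), ncol(prob)), prob)
      n_cells <- sum(mask == 1, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        probability_level = levels_p[i], precision_level = levels_c[j],
        threshold = t, cov_cutoff = cutoffs[j], n_cells = n_cells,
        area_m2 = n_cells * area, mask = list(mask))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("combo_maps", class(out))
  out
}

#' Zonal area accounting for a presence mask
#'
#' Splits the presence area of a binary mask across management-zone polygons:
#' a cell belongs to a zone when its centre lies inside the polygon (zones
#' must not overlap), inside-area per zone is the presence-cell count times
#' the cell area, and everything else is the outside-all-zones area, so the
#' zone areas plus the outside area always reproduce the mask total exactly.
#'
#' @param mask a binary [grid_surface()].
#' @param zones a [zone_set()].
#' @param cell_size cell edge in metres (default taken from `mask`).
#' @return a `zonal_report` tibble: one row per zone plus an `outside` row
#'   (`zone_id`, `zone_type`, `n_cells`, `area_m2`), with a `total_area_m2`
#'   attribute.
#' @export
zonal_area <- function(mask, zones, cell_size = NULL) {
  stopifnot(is_grid_surface(mask))
  if (is.null(cell_size)) cell_size <- cell_size(mask)
  member <- zone_membership(mask, zones)
  present <- !is.na(unclass(mask)) & unclass(mask) == 1
  counts <- vapply(seq_len(nrow(zones)), function(k) sum(present & member == k),
                   integer(1L))
  outside <- sum(present) - sum(counts)
  out <- tibble::tibble(
    zone_id = c(zones$id, "outside"),
    zone_type = c(zones$zone_type, "outside"),
    n_cells = c(counts, outside),
    area_m2 = c(counts, outside) * cell_size^2
  )
  attr(out, "total_area_m2") <- sum(present) * cell_size^2
  class(out) <- c("zonal_report", class(out))
  out
}

#' Zonal report for all nine combination maps
#'
#' @param combos a [combo_maps()] tibble.
#' @param zones a [zone_set()].
#' @return a tibble: one row per (combination, zone) plus outside rows, with
#'   `probability_level`, `precision_level` identifying the combination.
#' @export
zonal_report_all <- function(combos, zones) {
  purrr::pmap_dfr(
    combos[c("probability_level", "precision_level", "mask")],
    function(probability_level, precision_level, mask) {
      za <- zonal_area(mask, zones)
      dplyr::bind_cols(
        tibble::tibble(probability_level = probability_level,
                       precision_level = precision_level),
        za)
    })
}

#' Sensitivity summary across the nine combination maps
#'
#' Condenses the nine zonal reports into the quantities the workflow
#' compares: total predicted area per combination, inside/outside splits per
#' zone type, the number of zones with any predicted presence, and all
#' pairwise area ratios between combinations (e.g. lowest over highest
#' combination).
#'
#' @param report the output of [zonal_report_all()].
#' @return a list of tibbles: `totals`, `by_zone_type`, `zones_present`,
#'   `ratios`.
#' @export
sensitivity_report <- function(report) {
  combo_lab <- function(p, c) paste0(p, "_prob/", c, "_prec")
  totals <- report |>
    dplyr::group_by(.data$probability_level, .data$precision_level) |>
    dplyr::summarise(area_m2 = sum(.data$area_m2), .groups = "drop") |>
    dplyr::mutate(combo = combo_lab(.data$probability_level, .data$precision_level))
  by_zone_type <- report |>
    dplyr::group_by(.data$probability_level, .data$precision_level, .data$zone_type) |>
    dplyr::summarise(area_m2 = sum(.data$area_m2), .groups = "drop")
  zones_present <- report |>
    dplyr::filter(.data$zone_type != "outside") |>
    dplyr::group_by(.data$probability_level, .data$precision_level) |>
    dplyr::summarise(n_zones_present = sum(.data$area_m2 > 0), .groups = "drop")
  ratios <- tidyr::expand_grid(a = totals$combo, b = totals$combo) |>
    dplyr::filter(.data$a != .data$b) |>
    dplyr::mutate(
      area_a = totals$area_m2[match(.data$a, totals$combo)],
      area_b = totals$area_m2[match(.data$b, totals$combo)],
      ratio = ifelse(.data$area_b > 0, .data$area_a / .data$area_b, NA_real_)
    )
  list(totals = totals, by_zone_type = by_zone_type,
       zones_present = zones_present, ratios = ratios)
}
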