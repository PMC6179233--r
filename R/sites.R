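site_meta_cols <- c("site_id", "x", "y", "presence", "stratum")

# Predictor columns of a site table = everything that is not site metadata.
predictor_cols <- function(sites) setdiff(names(sites), site_meta_cols)

#' Extract predictor values at site locations
#'
#' Looks up, for every site, the value of each stack layer in the grid cell
#' containing the site (half-open cell rule: a point on a boundary belongs to
#' the cell to its south-east). Sites falling on a nodata cell in any layer,
#' or outside the grid, are dropped with a message reporting the count.
#'
#' @param sites a data frame with numeric `x`, `y` columns (metres).
#' @param stack a [predictor_stack()].
#' @return the site tibble with one added column per stack layer.
#' @export
extract_at_sites <- function(sites, stack) {
  stopifnot(is.data.frame(sites), all(c("x", "y") %in% names(sites)))
  out <- tibble::as_tibble(sites)
  ref <- stack[[1L]]
  idx <- point_to_cell(ref, out$x, out$y)
  inside <- !is.na(idx$row)
  vals <- matrix(NA_real_, nrow(out), length(stack),
                 dimnames = list(NULL, names(stack)))
  lin <- cbind(idx$row[inside], idx$col[inside])
  for (nm in names(stack)) vals[inside, nm] <- stack[[nm]][lin]
  keep <- inside & !apply(is.na(vals), 1L, any)
  if (any(!keep)) {
    message(sum(!keep), " site(s) outside the grid or on nodata cells were excluded")
  }
  dplyr::bind_cols(out[keep, ], tibble::as_tibble(vals[keep, , drop = FALSE]))
}

#' Drop highly rank-correlated predictors
#'
#' Computes pairwise Spearman rank correlations between predictor columns at
#' the sites and greedily removes redundant layers: scanning predictors in
#' stack (column) order, a predictor is dropped when its absolute Spearman
#' correlation with any earlier *retained* predictor reaches the threshold,
#' so the earlier-ordered member of each redundant pair survives. Constant
#' predictors have undefined rank correlation and are treated as
#' uncorrelated, with a warning.
#'
#' @param sites a site tibble carrying predictor columns (see
#'   [extract_at_sites()]); columns `site_id`, `x`, `y`, `presence`,
#'   `stratum` are ignored.
#' @param rho_threshold absolute Spearman correlation at or above which the
#'   later predictor is dropped (default 0.9).
#' @return a `correlation_filter` list: `retained` (names in original
#'   order), `dropped` (tibble of `name`, `partner`, `rho`), and the
#'   threshold.
#' @examples
#' site_tbl <- tibble::tibble(a = 1:10, b = (1:10)^2, c = rnorm(10))
#' filter_correlated(site_tbl)$dropped  # b is a monotone copy of a
#' @export
filter_correlated <- function(sites, rho_threshold = 0.9) {
  preds <- predictor_cols(sites)
  if (length(preds) < 2L) stop("need at least two predictors", call. = FALSE)
  if (nrow(sites) < 3L) stop("need at least three sites", call. = FALSE)
  x <- as.matrix(sites[preds])
  const <- apply(x, 2L, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning("constant predictor(s) treated as uncorrelated: ",
            paste(preds[const], collapse = ", "), call. = FALSE)
  }
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  retained <- character(0)
  dropped <- list()
  for (nm in preds) {
    if (length(retained)) {
      r <- rho[retained, nm]
      hit <- which(abs(r) >= rho_threshold)
      if (length(hit)) {
        k <- hit[which.max(abs(r[hit]))]
        dropped[[length(dropped) + 1L]] <-
          tibble::tibble(name = nm, partner = retained[k], rho = unname(r[k]))
        next
      }
    }
    retained <- c(retained, nm)
  }
  structure(
    list(retained = retained,
         dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                   else tibble::tibble(name = character(), partner = character(),
                                       rho = numeric()),
         rho_threshold = rho_threshold),
    class = "correlation_filter"
  )
}

#' @export
print.correlation_filter <- function(x, ...) {
  cat(sprintf("<correlation_filter> |rho| >= %g: %d retained, %d dropped\n",
              x$rho_threshold, length(x$retained), nrow(x$dropped)))
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

#' @rdname filter_correlated
#' @param x a `correlation_filter`.
#' @param ... unused.
#' @export
tidy.correlation_filter <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(name = x$retained, status = "retained",
                   partner = NA_character_, rho = NA_real_),
    dplyr::mutate(x$dropped, status = "dropped", .after = "name")
  )
}
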