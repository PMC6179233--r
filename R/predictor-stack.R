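#' Aligned stack of predictor grids
#'
#' An ordered, named collection of aligned [grid_surface()] layers, each
#' tagged with a predictor family: `"spectral"` (image-derived reflectance
#' proxies), `"topographic"` (derivatives of the depth grid) or
#' `"geographic"` (position and distance-to-feature proxies).
#'
#' @param grids named list of aligned `grid_surface` objects.
#' @param family character vector (one per grid, recycled if length 1) giving
#'   each predictor's family.
#' @return a `predictor_stack`.
#' @export
predictor_stack <- function(grids, family) {
  if (is.null(names(grids)) || anyDuplicated(names(grids))) {
    stop("grids must be uniquely named", call. = FALSE)
  }
  check_aligned(grids)
  if (length(family) == 1L) family <- rep(family, length(grids))
  if (length(family) != length(grids)) {
    stop("family must have one entry per grid", call. = FALSE)
  }
  if (!all(family %in% c("spectral", "topographic", "geographic"))) {
    stop("family must be spectral, topographic or geographic", call. = FALSE)
  }
  names(family) <- names(grids)
  structure(list(grids = grids, family = family), class = "predictor_stack")
}

#' @export
names.predictor_stack <- function(x) names(x$grids)

#' @export
length.predictor_stack <- function(x) length(x$grids)

#' @export
`[[.predictor_stack` <- function(x, i) x$grids[[i]]

#' @export
print.predictor_stack <- function(x, ...) {
  fam <- table(factor(x$family, c("spectral", "topographic", "geographic")))
  cat(sprintf("<predictor_stack> %d layers (%d spectral, %d topographic, %d geographic), %d x %d cells\n",
              length(x), fam[[1L]], fam[[2L]], fam[[3L]],
              nrow(x$grids[[1L]]), ncol(x$grids[[1L]])))
  invisible(x)
}

#' Combine predictor stacks
#'
#' @param ... `predictor_stack` objects with disjoint names.
#' @return a single `predictor_stack` in argument order.
#' @export
c_stacks <- function(...) {
  stacks <- list(...)
  grids <- do.call(c, lapply(stacks, function(s) s$grids))
  family <- do.call(c, lapply(stacks, function(s) s$family))
  predictor_stack(grids, unname(family))
}

#' Subset a predictor stack by name
#'
#' @param stack a `predictor_stack`.
#' @param keep character vector of layer names to retain, in the order given.
#' @return a `predictor_stack`.
#' @export
subset_stack <- function(stack, keep) {
  missing <- setdiff(keep, names(stack))
  if (length(missing)) {
    stop("unknown predictor(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  predictor_stack(stack$grids[keep], unname(stack$family[keep]))
}
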