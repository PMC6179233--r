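#' Single-band raster surface
#'
#' A `grid_surface` is a numeric matrix with a cell size attribute, the
#' package's container for any single-band raster: a predictor, a depth grid,
#' a probability-of-occurrence surface, a coefficient-of-variation surface, or
#' a binary presence mask. Rows run north to south, columns west to east;
#' `NA` marks nodata. Cell `(1, 1)` sits at the north-west corner and the
#' centre of cell `(r, c)` is at `x = (c - 0.5) * cell_size`,
#' `y = (r - 0.5) * cell_size` with `y` measured southward from the north
#' edge. Points on a cell boundary belong to the cell on the half-open
#' interval `[x, x + cell_size)`.
#'
#' @param data numeric matrix (rows = north to south).
#' @param cell_size cell edge length in metres (default 2, the survey grid
#'   resolution this package targets).
#' @return a `grid_surface` object.
#' @examples
#' g <- grid_surface(matrix(runif(16), 4, 4), cell_size = 2)
#' cell_area(g)
#' @export
grid_surface <- function(data, cell_size = 2) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number", call. = FALSE)
  }
  structure(data, cell_size = as.numeric(cell_size),
            class = c("grid_surface", class(data)))
}

#' @export
print.grid_surface <- function(x, ...) {
  cat(sprintf("<grid_surface> %d x %d cells, %.3g m cells, %d nodata\n",
              nrow(x), ncol(x), cell_size(x), sum(is.na(x))))
  v <- x[!is.na(x)]
  if (length(v)) {
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n", min(v), max(v), mean(v)))
  }
  invisible(x)
}

#' @rdname grid_surface
#' @param x a `grid_surface`.
#' @export
cell_size <- function(x) {
  cs <- attr(x, "cell_size")
  if (is.null(cs)) stop("object has no cell_size attribute", call. = FALSE)
  cs
}

#' @rdname grid_surface
#' @export
cell_area <- function(x) cell_size(x)^2

#' @rdname grid_surface
#' @export
is_grid_surface <- function(x) inherits(x, "grid_surface")

# Rebuild a grid_surface from a plain matrix, inheriting geometry from `like`.
grid_like <- function(data, like) grid_surface(data, cell_size = cell_size(like))

# Stop unless all grids share shape and cell size.
check_aligned <- function(grids) {
  stopifnot(length(grids) >= 1L)
  ref <- grids[[1L]]
  ok <- vapply(grids, function(g) {
    all(dim(g) == dim(ref)) && isTRUE(all.equal(cell_size(g), cell_size(ref)))
  }, logical(1L))
  if (!all(ok)) stop("grids are not aligned (shape or cell size differ)", call. = FALSE)
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' Returns the x (eastward) and y (southward from the north edge) coordinates
#' of every cell centre, in metres.
#'
#' @param x a `grid_surface`.
#' @return a list with matrices `x` and `y` of the same shape as the grid.
#' @export
cell_centres <- function(x) {
  cs <- cell_size(x)
  list(
    x = matrix(rep((seq_len(ncol(x)) - 0.5) * cs, each = nrow(x)), nrow(x)),
    y = matrix(rep((seq_len(nrow(x)) - 0.5) * cs, times = ncol(x)), nrow(x))
  )
}

# Map point coordinates to (row, col) by the half-open cell rule; returns NA
# indices for points outside the grid.
point_to_cell <- function(grid, x, y) {
  cs <- cell_size(grid)
  col <- floor(x / cs) + 1L
  row <- floor(y / cs) + 1L
  bad <- row < 1L | row > nrow(grid) | col < 1L | col > ncol(grid)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Convert a grid surface to a tibble
#'
#' One row per cell with row/column indices, centre coordinates and value;
#' useful for dplyr summaries and ggplot2 maps.
#'
#' @param x a `grid_surface`.
#' @param drop_na drop nodata cells (default `FALSE`).
#' @param ... unused.
#' @return a tibble with columns `row`, `col`, `x`, `y`, `value`.
#' @export
as_tibble.grid_surface <- function(x, drop_na = FALSE, ...) {
  cc <- cell_centres(x)
  vals <- as.numeric(x)
  out <- tibble::tibble(
    row = as.integer(row(x)[TRUE]),
    col = as.integer(col(x)[TRUE]),
    x = as.numeric(cc$x),
    y = as.numeric(cc$y),
    value = vals
  )
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text single-band raster IO in the ESRI ASCII grid (`.asc`) dialect:
#' a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values from the north edge southward.
#' Nodata cells are written as -9999.
#'
#' @param path file path.
#' @param grid a `grid_surface`.
#' @param digits significant digits written (default 7, single precision).
#' @return `read_ascii_grid()` returns a `grid_surface`;
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    kv <- strsplit(trimws(ln), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- suppressWarnings(as.numeric(kv[2L]))
  }
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)) || anyNA(unlist(hdr[need]))) {
    stop("not an ESRI ASCII grid: header incomplete in ", path, call. = FALSE)
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("grid body has ", length(vals), " values, expected ", nr * nc, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid_surface(m, cell_size = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path, digits = 7) {
  stopifnot(is_grid_surface(grid))
  cs <- cell_size(grid)
  hdr <- c(
    paste("ncols", ncol(grid)),
    paste("nrows", nrow(grid)),
    "xllcorner 0",
    # ESRI y axis points north; our row 1 is the north edge
    paste("yllcorner", format(-nrow(grid) * cs, scientific = FALSE)),
    paste("cellsize", format(cs, scientific = FALSE)),
    "NODATA_value -9999"
  )
  m <- unclass(grid)
  m[is.na(m)] <- -9999
  body <- apply(m, 1L, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
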