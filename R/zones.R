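#' Management zone polygons
#'
#' A `zone_set` is a tibble of simple polygons in grid coordinates (metres;
#' x eastward, y southward from the north edge) with one row per zone:
#' an `id`, a `zone_type` (`"exclusion"`, `"operation"` or `"corridor"`) and a
#' `vertices` list-column of two-column matrices. Polygons are closed
#' implicitly (last vertex joins the first) and must be simple.
#'
#' @param id character or integer zone identifiers (unique).
#' @param zone_type character vector, each one of `"exclusion"`,
#'   `"operation"`, `"corridor"`.
#' @param vertices list of n-by-2 numeric matrices (columns x, y).
#' @return a tibble of class `zone_set`.
#' @export
zone_set <- function(id, zone_type, vertices) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("zone ids must be unique", call. = FALSE)
  if (!all(zone_type %in% c("exclusion", "operation", "corridor"))) {
    stop("zone_type must be exclusion, operation or corridor", call. = FALSE)
  }
  ok <- vapply(vertices, function(v) is.matrix(v) && ncol(v) == 2L && nrow(v) >= 3L,
               logical(1L))
  if (!all(ok)) stop("each polygon needs an n-by-2 vertex matrix, n >= 3", call. = FALSE)
  out <- tibble::tibble(id = id, zone_type = zone_type, vertices = vertices)
  class(out) <- c("zone_set", class(out))
  out
}

#' @rdname zone_set
#' @param xmin,xmax,ymin,ymax rectangle bounds in metres.
#' @export
rect_zone <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Even-odd ray-casting point-in-polygon, vectorised over points. Points on a
# boundary follow the half-open convention of the crossing test (left/bottom
# edges count as inside for axis-aligned rectangles).
point_in_polygon <- function(px, py, vertices) {
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Zone membership of grid cells
#'
#' Assigns each valid cell of a grid to the zone whose polygon contains the
#' cell centre. Errors if any cell centre lies inside two zones, because area
#' accounting would then be ambiguous.
#'
#' @param grid a `grid_surface` supplying the geometry.
#' @param zones a [zone_set()].
#' @return an integer matrix (same shape as `grid`): the zone row index, or 0
#'   outside all zones.
#' @export
zone_membership <- function(grid, zones) {
  cc <- cell_centres(grid)
  member <- matrix(0L, nrow(grid), ncol(grid))
  for (k in seq_len(nrow(zones))) {
    inz <- point_in_polygon(as.numeric(cc$x), as.numeric(cc$y), zones$vertices[[k]])
    inz <- matrix(inz, nrow(grid))
    if (any(inz & member != 0L)) {
      stop("zones overlap at cell centres; area accounting is ambiguous", call. = FALSE)
    }
    member[inz] <- k
  }
  member
}

#' Read and write zone polygons as GeoJSON
#'
#' Zones are exchanged as a GeoJSON FeatureCollection of Polygon features with
#' `id` and `zone_type` properties. Coordinates are grid metres (x eastward,
#' y southward), matching the package's grid convention.
#'
#' @param zones a [zone_set()].
#' @param path file path.
#' @return `read_zones_geojson()` returns a `zone_set`;
#'   `write_zones_geojson()` returns `path` invisibly.
#' @export
write_zones_geojson <- function(zones, path) {
  features <- purrr::pmap(zones, function(id, zone_type, vertices) {
    ring <- rbind(vertices, vertices[1L, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(id = id, zone_type = zone_type),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
      )
    )
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zones_geojson
#' @export
read_zones_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  feats <- doc$features
  id <- vapply(feats, function(f) as.character(f$properties$id), character(1L))
  zone_type <- vapply(feats, function(f) as.character(f$properties$zone_type), character(1L))
  vertices <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    # drop the closing vertex GeoJSON requires
    if (nrow(m) > 1L && all(m[1L, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  })
  zone_set(id, zone_type, vertices)
}
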