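# Neighbour shift: value of the cell (dr, dc) away, NA off-grid.
shift_mat <- function(z, dr, dc) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- z[rs + dr, cs + dc]
  out
}

#' Topographic derivatives of a depth grid
#'
#' Derives the nine seafloor-topography predictors used by the modelling
#' workflow from a bathymetry grid (depth in metres, positive downward):
#'
#' * `depth` — the input grid itself;
#' * `slope` — degrees, Horn's method on the 3x3 window;
#' * `eastness`, `northness` — unit downslope direction components (0 on flat
#'   cells), an aspect encoding free of circular discontinuity;
#' * `profile_curvature`, `plan_curvature` — Zevenbergen-Thorne curvatures
#'   (1/m) along and across the slope direction;
#' * `rugosity` — surface-to-planar area ratio of the triangulated 3x3
#'   neighbourhood (1 on flat terrain);
#' * `local_sd` — sample standard deviation of depth over the window;
#' * `tpi` — topographic position index, centre depth minus the mean of the
#'   other window cells.
#'
#' Slope, aspect, curvature and rugosity use the standard 3x3 stencil;
#' `local_sd` and `tpi` use the full `window_cells` square. Any derived cell
#' whose window touches nodata or the grid edge is nodata.
#'
#' @param depth a `grid_surface` of depth in metres, positive downward.
#' @param window_cells odd window width >= 3 (default 3).
#' @return a [predictor_stack()] of 9 topographic layers.
#' @examples
#' d <- grid_surface(matrix(0.1 * (1:6)[col(matrix(0, 6, 6))], 6, 6))
#' topo <- derive_topographic(d)
#' topo[["slope"]][3, 3]  # constant-slope plane
#' @export
derive_topographic <- function(depth, window_cells = 3L) {
  stopifnot(is_grid_surface(depth))
  w <- as.integer(window_cells)
  if (w < 3L || w %% 2L == 0L) stop("window_cells must be odd and >= 3", call. = FALSE)
  if (w >= min(dim(depth))) stop("window_cells must be smaller than the grid extent", call. = FALSE)
  cs <- cell_size(depth)
  z <- unclass(depth)

  # 3x3 neighbours (rows north to south)
  zN <- shift_mat(z, -1L, 0L); zS <- shift_mat(z, 1L, 0L)
  zE <- shift_mat(z, 0L, 1L);  zW <- shift_mat(z, 0L, -1L)
  zNE <- shift_mat(z, -1L, 1L); zNW <- shift_mat(z, -1L, -1L)
  zSE <- shift_mat(z, 1L, 1L);  zSW <- shift_mat(z, 1L, -1L)

  # Horn gradients; y axis points south
  dzdx <- ((zNE + 2 * zE + zSE) - (zNW + 2 * zW + zSW)) / (8 * cs)
  dzdy <- ((zSW + 2 * zS + zSE) - (zNW + 2 * zN + zNE)) / (8 * cs)
  g <- sqrt(dzdx^2 + dzdy^2)
  g[is.na(z)] <- NA_real_  # Horn's stencil skips the centre; nodata still voids it
  slope <- atan(g) * 180 / pi
  # downslope unit vector in (east, north) components; flat cells -> 0
  eastness <- ifelse(g > 0, -dzdx / g, 0)
  northness <- ifelse(g > 0, dzdy / g, 0)
  eastness[is.na(g)] <- NA_real_
  northness[is.na(g)] <- NA_real_

  # Zevenbergen-Thorne quadratic coefficients
  D <- ((zW + zE) / 2 - z) / cs^2
  E <- ((zN + zS) / 2 - z) / cs^2
  Fc <- (-zNW + zNE + zSW - zSE) / (4 * cs^2)
  G <- (zE - zW) / (2 * cs)
  H <- (zN - zS) / (2 * cs)
  g2 <- G^2 + H^2
  prof <- ifelse(g2 > 0, -2 * (D * G^2 + E * H^2 + Fc * G * H) / g2, 0)
  plan <- ifelse(g2 > 0, 2 * (D * H^2 + E * G^2 - Fc * G * H) / g2, 0)
  prof[is.na(g2)] <- NA_real_
  plan[is.na(g2)] <- NA_real_

  rug <- rugosity_3x3(z, cs)

  # general-window focal statistics
  offs <- expand.grid(dr = -(w %/% 2L):(w %/% 2L), dc = -(w %/% 2L):(w %/% 2L))
  n_win <- nrow(offs)
  s1 <- 0; s2 <- 0
  for (k in seq_len(n_win)) {
    zz <- shift_mat(z, offs$dr[k], offs$dc[k])
    s1 <- s1 + zz; s2 <- s2 + zz^2
  }
  var_w <- (s2 - s1^2 / n_win) / (n_win - 1L)
  local_sd <- sqrt(pmax(var_w, 0))
  tpi <- z - (s1 - z) / (n_win - 1L)

  predictor_stack(
    list(depth = depth,
         slope = grid_like(slope, depth),
         eastness = grid_like(eastness, depth),
         northness = grid_like(northness, depth),
         profile_curvature = grid_like(prof, depth),
         plan_curvature = grid_like(plan, depth),
         rugosity = grid_like(rug, depth),
         local_sd = grid_like(local_sd, depth),
         tpi = grid_like(tpi, depth)),
    family = "topographic"
  )
}

# Surface-to-planar area ratio: fan of 8 triangles from the cell centre to its
# ring of neighbours; planar reference area is the (2*cs)^2 square.
rugosity_3x3 <- function(z, cs) {
  ring <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  zs <- lapply(ring, function(o) shift_mat(z, o[1L], o[2L]))
  total <- 0
  for (i in seq_along(ring)) {
    j <- if (i == length(ring)) 1L else i + 1L
    # u, v from centre to two adjacent neighbours; dx east, dy south
    ux <- ring[[i]][2L] * cs; uy <- ring[[i]][1L] * cs; uz <- zs[[i]] - z
    vx <- ring[[j]][2L] * cs; vy <- ring[[j]][1L] * cs; vz <- zs[[j]] - z
    cx <- uy * vz - uz * vy
    cy <- uz * vx - ux * vz
    cz <- ux * vy - uy * vx
    total <- total + 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  total / (4 * cs^2)
}

#' Geographic predictor grids
#'
#' Builds the four geographic proxy predictors: cell-centre x and y
#' coordinates (stand-ins for longitude/latitude) and Euclidean distance from
#' each cell centre to the nearest boundary or interior of the first and
#' second feature polygon (e.g. a reef-crest proxy and a shoreline proxy).
#'
#' @param grid_template a `grid_surface` supplying the geometry.
#' @param features a [zone_set()] with at least two polygons; the first two
#'   rows define the two distance features.
#' @return a [predictor_stack()] of 4 geographic layers
#'   (`x_coord`, `y_coord`, `dist_feature1`, `dist_feature2`).
#' @export
derive_geographic <- function(grid_template, features) {
  stopifnot(is_grid_surface(grid_template))
  if (!inherits(features, "zone_set") || nrow(features) < 2L) {
    stop("`features` must be a zone_set with at least two polygons", call. = FALSE)
  }
  cc <- cell_centres(grid_template)
  d1 <- distance_to_polygon(cc$x, cc$y, features$vertices[[1L]])
  d2 <- distance_to_polygon(cc$x, cc$y, features$vertices[[2L]])
  predictor_stack(
    list(x_coord = grid_like(cc$x, grid_template),
         y_coord = grid_like(cc$y, grid_template),
         dist_feature1 = grid_like(d1, grid_template),
         dist_feature2 = grid_like(d2, grid_template)),
    family = "geographic"
  )
}

# Euclidean distance from points to a polygon (0 inside), vectorised over a
# coordinate matrix/vector.
distance_to_polygon <- function(px, py, vertices) {
  shape <- dim(px)
  px <- as.numeric(px); py <- as.numeric(py)
  n <- nrow(vertices)
  dmin <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vertices[i, 1L]; ay <- vertices[i, 2L]
    bx <- vertices[j, 1L]; by <- vertices[j, 2L]
    abx <- bx - ax; aby <- by - ay
    len2 <- abx^2 + aby^2
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - ax) * abx + (py - ay) * aby) / len2)) else 0
    dmin <- pmin(dmin, sqrt((px - (ax + t * abx))^2 + (py - (ay + t * aby))^2))
  }
  dmin[point_in_polygon(px, py, vertices)] <- 0
  if (!is.null(shape)) dmin <- matrix(dmin, shape[1L], shape[2L])
  dmin
}
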