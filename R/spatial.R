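# Least-cost marine distances: a regular lat/lon grid with land masked out,
# an 8-neighbour water-cell graph weighted by great-circle distance, and
# Dijkstra shortest paths between river-mouth cells.

#' Construct a land/water cost raster
#'
#' @param water Logical matrix, `TRUE` = water; rows index latitude from
#'   the southern edge upward, columns longitude from the western edge.
#' @param lat_min,lon_min Coordinates of the lower-left cell *corner*.
#' @param resolution Cell size in degrees.
#' @return A list of class `cost_raster`: `water`, `lat` and `lon` vectors
#'   of cell-center coordinates, `resolution`.
#' @export
cost_raster <- function(water, lat_min, lon_min, resolution) {
  water <- as.matrix(water)
  if (!is.logical(water)) stop("`water` must be a logical matrix")
  if (resolution <= 0) stop("resolution must be positive")
  structure(list(water = water,
                 lat = lat_min + (seq_len(nrow(water)) - 0.5) * resolution,
                 lon = lon_min + (seq_len(ncol(water)) - 0.5) * resolution,
                 resolution = resolution),
            class = "cost_raster")
}

#' Rasterize a synthetic coastline
#'
#' Builds a [cost_raster()] from parametric landmass polygons so tests and
#' simulations need no bathymetry download. A cell is land when its center
#' falls inside any polygon (even-odd rule).
#'
#' @param land_polygons List of two-column matrices `(lon, lat)` of polygon
#'   vertices.
#' @param lat_range,lon_range `c(min, max)` extents of the grid.
#' @param resolution Cell size in degrees.
#' @return A `cost_raster`.
#' @export
synthetic_coastline <- function(land_polygons, lat_range, lon_range,
                                resolution = 0.1) {
  nr <- ceiling(diff(lat_range) / resolution)
  nc <- ceiling(diff(lon_range) / resolution)
  lat <- lat_range[1] + (seq_len(nr) - 0.5) * resolution
  lon <- lon_range[1] + (seq_len(nc) - 0.5) * resolution
  land <- matrix(FALSE, nr, nc)
  for (poly in land_polygons) {
    px <- poly[, 1]; py <- poly[, 2]
    for (i in seq_len(nr)) {
      inside <- point_in_polygon(lon, rep(lat[i], nc), px, py)
      land[i, inside] <- TRUE
    }
  }
  cost_raster(!land, lat_range[1], lon_range[1], resolution)
}

# even-odd ray casting, vectorized over query points
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Read / write a plain ASCII grid raster
#'
#' Header lines `ncols,nrows,xllcorner,yllcorner,cellsize,nodata_value`
#' followed by the matrix, northernmost row first (the common ASCII-grid
#' layout). Cells equal to `nodata` or 0 are land; anything else water.
#'
#' @param path File path.
#' @return A `cost_raster` for the reader; `path` for the writer.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]   # south row first internally
  water <- !(m == 0 | m == hdr$nodata_value)
  cost_raster(water, hdr$yllcorner, hdr$xllcorner, hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @param raster A `cost_raster` to write.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "cost_raster"))
  m <- (raster$water + 0L)[rev(seq_len(nrow(raster$water))), , drop = FALSE]
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", raster$lon[1] - raster$resolution / 2),
           paste("yllcorner", raster$lat[1] - raster$resolution / 2),
           paste("cellsize", raster$resolution),
           paste("nodata_value", -9999))
  writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Least-cost over-water distances between river mouths
#'
#' Builds a graph over water cells (8-neighbour connectivity, edge weight =
#' great-circle distance between cell centers) and runs Dijkstra shortest
#' paths between the cells nearest each population's coordinates. Land is
#' an impermeable barrier. Each population must snap to a water cell within
#' `snap_radius` cells of its position.
#'
#' @param populations Data frame with `population`, `latitude`, `longitude`.
#' @param raster A [cost_raster()].
#' @param snap_radius Maximum snap distance in cells.
#' @return Symmetric matrix of distances in km, zero diagonal.
#' @export
least_cost_distances <- function(populations, raster, snap_radius = 3) {
  stopifnot(inherits(raster, "cost_raster"))
  w <- raster$water
  nr <- nrow(w); nc <- ncol(w)
  cell_id <- matrix(seq_len(nr * nc), nr, nc)
  water_id <- cell_id[w]
  if (!length(water_id)) stop("raster has no water cells")

  # edges: horizontal, vertical and both diagonals between water cells
  edges <- list(); weights <- list()
  add_edges <- function(r1, c1, r2, c2) {
    ok <- w[cbind(r1, c1)] & w[cbind(r2, c2)]
    if (!any(ok)) return()
    d <- geosphere::distHaversine(
      cbind(raster$lon[c1[ok]], raster$lat[r1[ok]]),
      cbind(raster$lon[c2[ok]], raster$lat[r2[ok]])) / 1000
    edges[[length(edges) + 1L]] <<- rbind(cell_id[cbind(r1[ok], c1[ok])],
                                          cell_id[cbind(r2[ok], c2[ok])])
    weights[[length(weights) + 1L]] <<- d
  }
  rr <- rep(seq_len(nr - 1), nc);     cc <- rep(seq_len(nc), each = nr - 1)
  add_edges(rr, cc, rr + 1L, cc)                                   # vertical
  rr <- rep(seq_len(nr), nc - 1);     cc <- rep(seq_len(nc - 1), each = nr)
  add_edges(rr, cc, rr, cc + 1L)                                   # horizontal
  rr <- rep(seq_len(nr - 1), nc - 1); cc <- rep(seq_len(nc - 1), each = nr - 1)
  add_edges(rr, cc, rr + 1L, cc + 1L)                              # diag NE
  add_edges(rr + 1L, cc, rr, cc + 1L)                              # diag SE

  el <- do.call(cbind, edges)
  gr <- igraph::graph_from_edgelist(t(matrix(match(el, water_id), 2)),
                                    directed = FALSE)
  gr <- igraph::set_edge_attr(gr, "weight", value = unlist(weights))
  if (igraph::vcount(gr) < length(water_id))
    gr <- igraph::add_vertices(gr, length(water_id) - igraph::vcount(gr))

  # snap each population to the nearest water cell within the radius
  snap <- integer(nrow(populations))
  for (i in seq_len(nrow(populations))) {
    r0 <- which.min(abs(raster$lat - populations$latitude[i]))
    c0 <- which.min(abs(raster$lon - populations$longitude[i]))
    rs <- max(1, r0 - snap_radius):min(nr, r0 + snap_radius)
    cs <- max(1, c0 - snap_radius):min(nc, c0 + snap_radius)
    cand <- expand.grid(r = rs, c = cs)
    cand <- cand[w[cbind(cand$r, cand$c)], , drop = FALSE]
    if (!nrow(cand))
      stop("population ", populations$population[i],
           " cannot be snapped to water within ", snap_radius, " cells")
    dd <- (cand$r - r0)^2 + (cand$c - c0)^2
    best <- cand[which.min(dd), ]
    snap[i] <- match(cell_id[best$r, best$c], water_id)
  }

  dm <- igraph::distances(gr, v = snap, to = snap, algorithm = "dijkstra")
  if (any(is.infinite(dm)))
    stop("some population pairs are not connected by water")
  dimnames(dm) <- list(populations$population, populations$population)
  diag(dm) <- 0
  dm
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Re-projects least-cost marine distances to Cartesian coordinates by
#' minimizing Kruskal stress-1 (monotone regression on ranks, iterative
#' majorization via `vegan::monoMDS`), keeping the best of several seeded
#' starts (one metric-scaling start plus random starts). Coordinates are
#' centered at the origin.
#'
#' @param dist_matrix Symmetric matrix of finite distances (>= 3 points).
#' @param dims Embedding dimensionality.
#' @param seed Integer seed for the random starts.
#' @param n_starts Number of random starts beyond the metric one.
#' @param maxit Iteration cap per start.
#' @return A list of class `nmds_embedding`: `points` (n x dims, centered),
#'   `stress` (Kruskal stress-1, in [0, 1]), `iters`.
#' @export
nmds_project <- function(dist_matrix, dims = 2, seed = 1, n_starts = 4,
                         maxit = 200) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) < 3) stop("need >= 3 populations")
  if (any(!is.finite(dist_matrix))) stop("non-finite distances")
  d <- stats::as.dist(dist_matrix)
  set.seed(as.integer(seed))
  best <- vegan::monoMDS(d, k = dims, model = "global", maxit = maxit)
  for (i in seq_len(n_starts)) {
    init <- matrix(stats::rnorm(nrow(dist_matrix) * dims),
                   nrow(dist_matrix), dims)
    cand <- vegan::monoMDS(d, y = init, k = dims, model = "global",
                           maxit = maxit)
    if (cand$stress < best$stress) best <- cand
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  rownames(pts) <- rownames(dist_matrix)
  structure(list(points = pts, stress = best$stress,
                 iters = best$iters),
            class = "nmds_embedding")
}

#' @export
print.nmds_embedding <- function(x, ...) {
  cat("nmds_embedding:", nrow(x$points), "points in", ncol(x$points),
      "dimensions; stress =", format(x$stress, digits = 4), "\n")
  invisible(x)
}
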