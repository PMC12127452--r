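#' Construct a parcel polygon
#'
#' Polygons are stored as a list with an `outer` ring (two-column matrix of
#' x,y vertices, not repeated at the end) and an optional list of hole rings.
#' All coordinates are planar map units (metres); no CRS handling is done.
#'
#' @param outer Two-column numeric matrix of outer-ring vertices.
#' @param holes Optional list of two-column matrices, one per hole ring.
#' @return An object of class `pitt_polygon`.
#' @export
pitt_polygon <- function(outer, holes = list()) {
  outer <- ring_matrix(outer)
  holes <- lapply(holes, ring_matrix)
  poly <- structure(list(outer = outer, holes = holes), class = "pitt_polygon")
  validate_polygon(poly)
  poly
}

ring_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2) stop("a polygon ring needs two coordinate columns", call. = FALSE)
  # drop an explicitly closed last vertex
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  m
}

validate_polygon <- function(poly) {
  if (nrow(unique(poly$outer)) < 3)
    stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
  if (abs(ring_area(poly$outer)) <= 0)
    stop("degenerate polygon: zero area", call. = FALSE)
  invisible(poly)
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Polygon area (holes subtracted)
#' @param poly A `pitt_polygon`.
#' @return Area in squared map units.
#' @export
polygon_area <- function(poly) {
  abs(ring_area(poly$outer)) - sum(vapply(poly$holes, function(h) abs(ring_area(h)), 0))
}

polygon_bbox <- function(poly) {
  rng_x <- range(poly$outer[, 1]); rng_y <- range(poly$outer[, 2])
  c(xmin = rng_x[1], ymin = rng_y[1], xmax = rng_x[2], ymax = rng_y[2])
}

polygon_rings <- function(poly) c(list(poly$outer), poly$holes)

# all ring edges as one matrix: x1 y1 x2 y2
polygon_edges <- function(poly) {
  do.call(rbind, lapply(polygon_rings(poly), function(r) {
    nxt <- c(seq_len(nrow(r))[-1], 1)
    cbind(r[, 1], r[, 2], r[nxt, 1], r[nxt, 2])
  }))
}

#' Test points for polygon containment (even-odd rule, holes respected)
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param poly A `pitt_polygon`.
#' @return Logical vector; points exactly on the boundary are not guaranteed
#'   either way (use [polygon_distance()] when boundary cases matter).
#' @export
point_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  for (ring in polygon_rings(poly)) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    for (i in seq_len(n)) {
      xi <- x[i]; yi <- y[i]; xj <- x[j[i]]; yj <- y[j[i]]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

# unsigned distance from points to the polygon boundary (any ring)
dist_to_boundary <- function(px, py, poly) {
  edges <- polygon_edges(poly)
  d2 <- rep(Inf, length(px))
  for (e in seq_len(nrow(edges))) {
    x1 <- edges[e, 1]; y1 <- edges[e, 2]; x2 <- edges[e, 3]; y2 <- edges[e, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    dd <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Signed distance to the polygon boundary
#'
#' Positive inside (outside holes), negative outside.
#' @inheritParams point_in_polygon
#' @return Numeric vector of signed distances in map units.
#' @export
polygon_distance <- function(px, py, poly) {
  d <- dist_to_boundary(px, py, poly)
  ifelse(point_in_polygon(px, py, poly), d, -d)
}

#' Maximum inscribed circle of a polygon
#'
#' Pole-of-inaccessibility search: a quadtree subdivision of the bounding box
#' where each cell carries the upper bound `d(center) + h*sqrt(2)` on the
#' inscribed radius attainable inside it; cells that cannot beat the incumbent
#' are pruned, so the result is within `precision` of the true optimum. Holes
#' are respected (the circle cannot overlap them).
#'
#' @param poly A `pitt_polygon`.
#' @param precision Convergence tolerance in map units; default one thousandth
#'   of the shorter bounding-box side.
#' @return A list with `center` (length-2 numeric) and `radius`.
#' @export
max_inscribed_circle <- function(poly, precision = NULL) {
  validate_polygon(poly)
  bb <- polygon_bbox(poly)
  w <- bb["xmax"] - bb["xmin"]; h <- bb["ymax"] - bb["ymin"]
  if (is.null(precision)) precision <- max(min(w, h) * 1e-3, 1e-9)
  cell <- min(w, h) / 2
  if (cell <= 0) stop("degenerate polygon: zero-extent bounding box", call. = FALSE)

  cx <- seq(bb["xmin"] + cell, bb["xmax"], by = 2 * cell)
  cy <- seq(bb["ymin"] + cell, bb["ymax"], by = 2 * cell)
  grid <- expand.grid(x = cx, y = cy)
  qx <- grid$x; qy <- grid$y; qh <- rep(cell, nrow(grid))
  qd <- polygon_distance(qx, qy, poly)

  # seed with the centroid of the outer ring as a good interior guess
  cen <- colMeans(poly$outer)
  best_d <- polygon_distance(cen[1], cen[2], poly)
  best_x <- cen[1]; best_y <- cen[2]
  if (length(qd) && max(qd) > best_d) {
    i <- which.max(qd); best_d <- qd[i]; best_x <- qx[i]; best_y <- qy[i]
  }

  repeat {
    keep <- (qd + qh * sqrt(2)) > best_d + precision
    if (!any(keep)) break
    qx <- qx[keep]; qy <- qy[keep]; qh <- qh[keep]; qd <- qd[keep]
    i <- which.max(qd + qh * sqrt(2))
    x0 <- qx[i]; y0 <- qy[i]; h0 <- qh[i] / 2
    qx <- qx[-i]; qy <- qy[-i]; qh <- qh[-i]; qd <- qd[-i]
    nx <- c(x0 - h0, x0 + h0, x0 - h0, x0 + h0)
    ny <- c(y0 - h0, y0 - h0, y0 + h0, y0 + h0)
    nd <- polygon_distance(nx, ny, poly)
    qx <- c(qx, nx); qy <- c(qy, ny); qh <- c(qh, rep(h0, 4)); qd <- c(qd, nd)
    j <- which.max(nd)
    if (nd[j] > best_d) { best_d <- nd[j]; best_x <- nx[j]; best_y <- ny[j] }
  }
  list(center = c(x = unname(best_x), y = unname(best_y)), radius = unname(best_d))
}

# scale a polygon about a point by a factor
scale_polygon <- function(poly, center, factor) {
  tr <- function(r) cbind(center[1] + (r[, 1] - center[1]) * factor,
                          center[2] + (r[, 2] - center[2]) * factor)
  pitt_polygon(tr(poly$outer), lapply(poly$holes, tr))
}
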