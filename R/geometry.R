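# Planar geometry helpers shared by the template, deformation and I/O
# modules. Polygons are n x 2 matrices of vertices, closed implicitly
# (last vertex joins back to the first).

#' Signed area of a closed polygon
#'
#' Positive for counter-clockwise vertex order (shoelace formula).
#'
#' @param poly numeric matrix with two columns (x, y); closed implicitly.
#' @return Signed area in squared grid units.
#' @keywords internal
signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ensure_ccw <- function(poly) {
  if (signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_bbox_diag <- function(poly) {
  rng <- apply(poly, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

#' Simple-polygon test
#'
#' A polygon is simple when no two non-adjacent edges intersect and no two
#' distinct vertices coincide. Brute-force O(n^2) proper-crossing test,
#' adequate for outlines of a few hundred vertices.
#'
#' @param poly closed polygon, n x 2 matrix, n >= 3.
#' @return `TRUE` if the polygon is simple.
#' @keywords internal
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  if (anyDuplicated(round(poly, 12)) > 0) return(FALSE)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2)) {
    # candidate partner edges, excluding the two neighbours of edge i
    j <- (i + 2):n
    if (i == 1) j <- j[j != n]
    if (length(j) == 0) next
    d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Resample a closed polyline at equal arc-length spacing
#'
#' @param poly closed polygon (n x 2).
#' @param n number of output samples (the closing vertex is not repeated).
#' @return n x 2 matrix of points on the polygon boundary.
#' @keywords internal
resample_closed <- function(poly, n) {
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n + 1)[-(n + 1)]
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(p)] <- nrow(p) - 1
  t <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  p[idx, , drop = FALSE] * (1 - t) + p[idx + 1, , drop = FALSE] * t
}

# Arc-length table of an open polyline: cumulative and normalized positions.
polyline_arcs <- function(path) {
  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  list(seg = seg, cum = cum, total = cum[length(cum)])
}

# Point, unit tangent and left normal of an open polyline at normalized
# arc-length positions s in [0, 1].
polyline_eval <- function(path, s) {
  arc <- polyline_arcs(path)
  a <- pmin(pmax(s, 0), 1) * arc$total
  idx <- findInterval(a, arc$cum, rightmost.closed = TRUE)
  idx[idx >= nrow(path)] <- nrow(path) - 1
  t <- (a - arc$cum[idx]) / pmax(arc$seg[idx], .Machine$double.eps)
  pt <- path[idx, , drop = FALSE] * (1 - t) + path[idx + 1, , drop = FALSE] * t
  d <- path[idx + 1, , drop = FALSE] - path[idx, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  tan <- d / pmax(len, .Machine$double.eps)
  list(point = pt, tangent = tan, normal = cbind(-tan[, 2], tan[, 1]))
}

#' Nearest points on a polyline
#'
#' For each query point returns the distance to, normalized arc position of,
#' and coordinates of its nearest point on a polyline (closed or open).
#'
#' @param pts query points (N x 2).
#' @param poly polyline vertices (M x 2).
#' @param closed close the polyline back to its first vertex?
#' @keywords internal
nearest_on_polyline <- function(pts, poly, closed = TRUE) {
  p <- if (closed) rbind(poly, poly[1, ]) else poly
  nseg <- nrow(p) - 1
  seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  seglen2 <- pmax(rowSums(seg^2), .Machine$double.eps)
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  total <- cum[nseg + 1]
  n <- nrow(pts)
  best <- rep(Inf, n); bs <- numeric(n); bx <- numeric(n); by <- numeric(n)
  for (k in seq_len(nseg)) {
    t <- ((pts[, 1] - p[k, 1]) * seg[k, 1] + (pts[, 2] - p[k, 2]) * seg[k, 2]) / seglen2[k]
    t <- pmin(pmax(t, 0), 1)
    qx <- p[k, 1] + t * seg[k, 1]
    qy <- p[k, 2] + t * seg[k, 2]
    d2 <- (pts[, 1] - qx)^2 + (pts[, 2] - qy)^2
    upd <- d2 < best
    if (any(upd)) {
      best[upd] <- d2[upd]
      bs[upd] <- (cum[k] + t[upd] * sqrt(seglen2[k])) / total
      bx[upd] <- qx[upd]; by[upd] <- qy[upd]
    }
  }
  list(dist = sqrt(best), s = bs, point = cbind(bx, by))
}

# Minimum distances only (convenience wrapper).
dist_to_polyline <- function(pts, poly, closed = TRUE) {
  nearest_on_polyline(pts, poly, closed = closed)$dist
}

# Point on a closed polyline at normalized arc positions s (vectorized).
closed_polyline_at <- function(poly, s) {
  p <- rbind(poly, poly[1, ])
  arc <- polyline_arcs(p)
  a <- (s %% 1) * arc$total
  idx <- findInterval(a, arc$cum, rightmost.closed = TRUE)
  idx[idx >= nrow(p)] <- nrow(p) - 1
  t <- (a - arc$cum[idx]) / pmax(arc$seg[idx], .Machine$double.eps)
  p[idx, , drop = FALSE] * (1 - t) + p[idx + 1, , drop = FALSE] * t
}

#' Intersections of a line with a polygon boundary
#'
#' Line through `origin` with direction `dir` (not necessarily unit length);
#' returns the sorted signed parameters t of crossings, so intersection
#' points are `origin + t * dir`.
#'
#' @keywords internal
line_polygon_intersections <- function(origin, dir, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  e <- b - a
  denom <- dir[1] * e[, 2] - dir[2] * e[, 1]
  ok <- abs(denom) > 1e-14
  ax <- a[, 1] - origin[1]; ay <- a[, 2] - origin[2]
  t <- (ax * e[, 2] - ay * e[, 1]) / denom
  u <- (ax * dir[2] - ay * dir[1]) / denom
  hit <- ok & u >= 0 & u < 1
  sort(t[hit])
}

#' Polygon intersection-over-union by rasterization
#'
#' Area IoU estimated on a regular grid over the joint bounding box; grid
#' membership uses [pracma::inpolygon()]. Deterministic for fixed `grid_n`.
#'
#' @param a,b simple closed polygons (n x 2 matrices).
#' @param grid_n grid resolution per axis (default 160).
#' @return IoU in `[0, 1]`.
#' @keywords internal
polygon_iou <- function(a, b, grid_n = 160) {
  xr <- range(a[, 1], b[, 1]); yr <- range(a[, 2], b[, 2])
  if (diff(xr) <= 0 || diff(yr) <= 0) return(0)
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  px <- rep(gx, times = grid_n)
  py <- rep(gy, each = grid_n)
  ina <- pracma::inpolygon(px, py, a[, 1], a[, 2])
  inb <- pracma::inpolygon(px, py, b[, 1], b[, 2])
  un <- sum(ina | inb)
  if (un == 0) return(0)
  sum(ina & inb) / un
}

# Deterministic quasi-uniform unit directions on the sphere (Fibonacci
# lattice); used by the convex-hull support-function certificate.
fibonacci_directions <- function(n = 256) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# 3D rotation matrix about a coordinate axis, angle in degrees
# (anti-clockwise looking down the positive axis).
rotation_matrix_3d <- function(axis = c("x", "y", "z"), degrees) {
  axis <- match.arg(axis)
  th <- degrees * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3),
    y = matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3),
    z = matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
  )
}
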