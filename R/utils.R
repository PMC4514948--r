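# Small numeric helpers shared across modules.

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues rotation about an arbitrary axis, used for phantom tilts and for
#' the rigid-motion invariance checks.
#'
#' @param axis length-3 axis (need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Distance from points (n x 2) to the segment p1-p2; returns list(d, closest).
point_segment_distance <- function(pts, p1, p2) {
  pts <- matrix(pts, ncol = 2)
  v <- p2 - p1
  L2 <- sum(v^2)
  if (L2 < 1e-24) {
    d <- sqrt((pts[, 1] - p1[1])^2 + (pts[, 2] - p1[2])^2)
    return(list(d = d, closest = matrix(rep(p1, each = nrow(pts)), ncol = 2)))
  }
  t <- ((pts[, 1] - p1[1]) * v[1] + (pts[, 2] - p1[2]) * v[2]) / L2
  t <- pmin(1, pmax(0, t))
  cx <- p1[1] + t * v[1]
  cy <- p1[2] + t * v[2]
  list(d = sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2), closest = cbind(cx, cy))
}

# Nearest point on a closed polyline (m x 2, implicitly closed) to point p.
# Edge-based (continuous), not vertex-only. Returns list(point, dist).
nearest_on_polyline <- function(poly, p) {
  m <- nrow(poly)
  a <- poly
  b <- poly[c(2:m, 1), , drop = FALSE]
  vx <- b[, 1] - a[, 1]
  vy <- b[, 2] - a[, 2]
  L2 <- vx^2 + vy^2
  L2[L2 < 1e-24] <- 1e-24
  t <- ((p[1] - a[, 1]) * vx + (p[2] - a[, 2]) * vy) / L2
  t <- pmin(1, pmax(0, t))
  cx <- a[, 1] + t * vx
  cy <- a[, 2] + t * vy
  d2 <- (p[1] - cx)^2 + (p[2] - cy)^2
  i <- which.min(d2)
  list(point = c(cx[i], cy[i]), dist = sqrt(d2[i]))
}

# Signed perpendicular distance of points (n x 2) from the line through a, b;
# positive on the left of a->b.
signed_line_distance <- function(pts, a, b) {
  pts <- matrix(pts, ncol = 2)
  v <- unit(b - a)
  (pts[, 1] - a[1]) * (-v[2]) + (pts[, 2] - a[2]) * v[1]
}

# Polygon area (shoelace); positive when counter-clockwise.
polygon_area <- function(poly) {
  m <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:m, 1)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(poly) {
  m <- nrow(poly)
  j <- c(2:m, 1)
  x <- poly[, 1]; y <- poly[, 2]
  cr <- x * y[j] - x[j] * y
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) return(colMeans(poly))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * A)
}

# Are points (n x 2) inside the closed polygon? Even-odd rule, vectorized over
# points with a loop over edges (polygon vertex counts are small).
points_in_polygon <- function(pts, poly) {
  pts <- matrix(pts, ncol = 2)
  n <- nrow(pts)
  inside <- rep(FALSE, n)
  m <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Intersection point of two infinite lines given as (point, direction).
line_intersection <- function(p1, d1, p2, d2) {
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(NULL)
  t <- ((p2[1] - p1[1]) * d2[2] - (p2[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
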