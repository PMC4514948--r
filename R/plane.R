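#' Anatomic plane
#'
#' A plane in 3-D given by a point on the plane and a unit normal, the
#' container for the tibial plafond plane (plane X) and the individualized
#' measurement plane (plane Y).
#'
#' @param point numeric length-3, a point on the plane (mm).
#' @param normal numeric length-3, plane normal; normalized internally.
#' @return An object of class `anatomic_plane`.
#' @examples
#' pl <- anatomic_plane(c(0, 0, 0), c(0, 0, 1))
#' plane_distance(pl, c(0, 0, 5))
#' @export
anatomic_plane <- function(point, normal) {
  stopifnot(length(point) == 3, length(normal) == 3,
            all(is.finite(point)), all(is.finite(normal)))
  structure(list(point = as.numeric(point), normal = unit(as.numeric(normal))),
            class = "anatomic_plane")
}

#' @export
print.anatomic_plane <- function(x, ...) {
  cat(sprintf("<anatomic_plane> point (%.3f, %.3f, %.3f)  normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed distance from a plane
#'
#' Positive along the plane normal (proximal, for plane X in the canonical
#' frame).
#'
#' @param plane an [anatomic_plane()].
#' @param pts a length-3 point or an n x 3 matrix of points (mm).
#' @return numeric vector of signed distances (mm).
#' @export
plane_distance <- function(plane, pts) {
  pts <- matrix(pts, ncol = 3)
  (pts[, 1] - plane$point[1]) * plane$normal[1] +
    (pts[, 2] - plane$point[2]) * plane$normal[2] +
    (pts[, 3] - plane$point[3]) * plane$normal[3]
}

#' Shift a plane along its normal
#'
#' @param plane an [anatomic_plane()].
#' @param offset_mm signed distance to move the plane along its normal.
#' @return an [anatomic_plane()].
#' @export
plane_offset <- function(plane, offset_mm) {
  anatomic_plane(plane$point + offset_mm * plane$normal, plane$normal)
}

# Orthonormal in-plane axes (e1, e2) with e1 = canonical +x and e2 = +y
# projected into the plane (falling back to +z when degenerate), so that 2-D
# contour coordinates keep their anatomical reading: e1 ~ lateral, e2 ~
# anterior for a near-axial plane.
plane_frame <- function(plane) {
  n <- plane$normal
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
  if (vec_norm(ex) < 1e-6) ex <- c(0, 0, 1) - sum(c(0, 0, 1) * n) * n
  e1 <- unit(ex)
  ey <- c(0, 1, 0) - sum(c(0, 1, 0) * n) * n - sum(c(0, 1, 0) * e1) * e1
  if (vec_norm(ey) < 1e-6) {
    e2 <- unit(cross3(n, e1))
  } else {
    e2 <- unit(ey)
  }
  # right-handed (e1, e2, n)
  if (sum(cross3(e1, e2) * n) < 0) e2 <- -e2
  list(origin = plane$point, e1 = e1, e2 = e2, normal = n)
}

plane_to_2d <- function(frame, pts) {
  pts <- matrix(pts, ncol = 3)
  dp <- sweep(pts, 2, frame$origin)
  cbind(dp %*% frame$e1, dp %*% frame$e2)
}

plane_to_3d <- function(frame, uv) {
  uv <- matrix(uv, ncol = 2)
  sweep(uv %*% rbind(frame$e1, frame$e2), 2, frame$origin, "+")
}
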