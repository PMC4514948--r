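#' Triangulated bone surface
#'
#' Container for one bone surface: vertex coordinates in mm (canonical frame:
#' +x lateral, +y anterior, +z proximal for a right ankle), triangle index
#' matrix, a bone label and a closedness flag.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param label bone label: "tibia", "fibula", "talus", "other" or "".
#' @param closed logical; TRUE if every edge is shared by exactly two faces.
#'   Computed when `NA`.
#' @return An object of class `bone_surface`.
#' @export
bone_surface <- function(vertices, faces, label = "", closed = NA) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!all(is.finite(vertices))) stop("bone_surface: non-finite vertex coordinates")
  if (nrow(faces) > 0 && (max(faces) > nrow(vertices) || min(faces) < 1))
    stop("bone_surface: face index out of range")
  if (is.na(closed)) closed <- mesh_is_closed(list(vertices = vertices, faces = faces))
  structure(list(vertices = vertices, faces = faces, label = label,
                 closed = closed),
            class = "bone_surface")
}

#' @export
print.bone_surface <- function(x, ...) {
  cat(sprintf("<bone_surface> label=%s  %d vertices, %d faces, %s\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

mesh_edge_keys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

mesh_is_closed <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(table(mesh_edge_keys(mesh$faces)) == 2L)
}

# Per-face unit normals and areas (counter-clockwise outward convention).
mesh_face_normals <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  list(normals = n / pmax(len, 1e-300), areas = len / 2)
}

#' Surface area of a mesh
#' @param surface a [bone_surface()].
#' @return total area in mm^2.
#' @export
mesh_area <- function(surface) sum(mesh_face_normals(surface)$areas)

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces.
#'
#' @param surface a [bone_surface()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Apply a rigid (or affine) transform to a surface
#'
#' @param surface a [bone_surface()].
#' @param rotation 3x3 matrix applied to vertices.
#' @param translation length-3 shift applied after rotation.
#' @return a transformed [bone_surface()].
#' @export
mesh_transform <- function(surface, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- sweep(surface$vertices %*% t(rotation), 2, translation, "+")
  faces <- surface$faces
  if (det(rotation) < 0) faces <- faces[, c(1, 3, 2), drop = FALSE]  # keep outward orientation
  bone_surface(v, faces, label = surface$label, closed = surface$closed)
}

#' Mirror a surface across the sagittal plane (x -> -x)
#' @param surface a [bone_surface()].
#' @return the mirrored [bone_surface()].
#' @export
mesh_mirror_x <- function(surface) {
  m <- diag(c(-1, 1, 1))
  mesh_transform(surface, rotation = m)
}

# ---- plane slicing ------------------------------------------------------

# Crossing points of mesh edges with a horizontal plane z = z0, without
# chaining into polylines (enough for silhouette extents).
mesh_slice_points_z <- function(surface, z0, eps = 1e-9) {
  v <- surface$vertices
  f <- surface$faces
  d <- v[, 3] - z0
  d[abs(d) < eps] <- eps
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cross <- (d[e[, 1]] > 0) != (d[e[, 2]] > 0)
  if (!any(cross)) return(NULL)
  ia <- e[cross, 1]; ib <- e[cross, 2]
  t <- d[ia] / (d[ia] - d[ib])
  v[ia, 1:2, drop = FALSE] + t * (v[ib, 1:2, drop = FALSE] - v[ia, 1:2, drop = FALSE])
}

# Intersect a triangle mesh with a plane. Returns a list of closed polylines
# (k x 3 matrices, last vertex != first, implicitly closed). Vertices exactly
# on the plane are nudged by eps so every crossing is a clean edge crossing.
mesh_slice_3d <- function(surface, plane, eps = 1e-9) {
  v <- surface$vertices
  f <- surface$faces
  d <- plane_distance(plane, v)
  d[abs(d) < eps] <- eps
  sf <- d[f]
  dim(sf) <- dim(f)
  side <- sf > 0
  ns <- side[, 1] + side[, 2] + side[, 3]
  crossing <- which(ns == 1L | ns == 2L)
  if (length(crossing) == 0) return(list())

  fc <- f[crossing, , drop = FALSE]
  sc <- side[crossing, , drop = FALSE]
  # For each crossing face, find the lone vertex on its own side; the two
  # crossed edges are (lone, other1), (lone, other2).
  lone_is_pos <- ns[crossing] == 1L
  lone_idx <- integer(length(crossing))
  for (k in 1:3) {
    hit <- (sc[, k] == lone_is_pos) & lone_idx == 0L
    lone_idx[hit] <- k
  }
  oth1 <- c(2L, 1L, 1L)[lone_idx]
  oth2 <- c(3L, 3L, 2L)[lone_idx]
  i_l <- fc[cbind(seq_along(crossing), lone_idx)]
  i_1 <- fc[cbind(seq_along(crossing), oth1)]
  i_2 <- fc[cbind(seq_along(crossing), oth2)]

  interp <- function(ia, ib) {
    ta <- d[ia] / (d[ia] - d[ib])
    v[ia, , drop = FALSE] + ta * (v[ib, , drop = FALSE] - v[ia, , drop = FALSE])
  }
  p1 <- interp(i_l, i_1)
  p2 <- interp(i_l, i_2)

  # Chain segments into closed polylines using edge identity (the crossed
  # edge of the mesh), which is exact -- no coordinate rounding needed.
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  k1 <- ekey(i_l, i_1)
  k2 <- ekey(i_l, i_2)
  nseg <- length(k1)
  keys <- unique(c(k1, k2))
  id1 <- match(k1, keys)
  id2 <- match(k2, keys)
  # adjacency: each edge key appears in exactly two segments on a closed mesh
  seg_at <- vector("list", length(keys))
  for (s in seq_len(nseg)) {
    seg_at[[id1[s]]] <- c(seg_at[[id1[s]]], s)
    seg_at[[id2[s]]] <- c(seg_at[[id2[s]]], s)
  }
  pts <- vector("list", nseg)
  used <- rep(FALSE, nseg)
  out <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    # walk from segment s0 following shared edge keys
    loop_pts <- list()
    s <- s0
    enter <- id1[s]
    repeat {
      used[s] <- TRUE
      if (id1[s] == enter) {
        loop_pts[[length(loop_pts) + 1L]] <- p1[s, ]
        leave <- id2[s]
        leave_pt <- p2[s, ]
      } else {
        loop_pts[[length(loop_pts) + 1L]] <- p2[s, ]
        leave <- id1[s]
        leave_pt <- p1[s, ]
      }
      nxt <- setdiff(seg_at[[leave]], s)
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) {
        # open chain (boundary) or loop closed
        if (leave != id1[s0] || length(loop_pts) < 3) {
          loop_pts[[length(loop_pts) + 1L]] <- leave_pt
        }
        break
      }
      s <- nxt[1]
      enter <- leave
    }
    out[[length(out) + 1L]] <- do.call(rbind, loop_pts)
  }
  out[vapply(out, nrow, 1L) >= 3]
}
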