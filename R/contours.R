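# Planar cross-section contours and the tangent-line tubercle construction.

new_contour <- function(uv, frame, label = "") {
  uv <- matrix(uv, ncol = 2)
  if (polygon_area(uv) < 0) uv <- uv[rev(seq_len(nrow(uv))), , drop = FALSE]
  structure(list(uv = uv, frame = frame, label = label), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour> label=%s, %d vertices, area %.2f mm^2\n",
              if (nzchar(x$label)) x$label else "(unlabeled)",
              nrow(x$uv), polygon_area(x$uv)))
  invisible(x)
}

contour_to_3d <- function(contour, uv = contour$uv) plane_to_3d(contour$frame, uv)

#' Slice bone surfaces with a plane
#'
#' Cross-sections of each surface with the plane, expressed in an orthonormal
#' 2-D frame whose axes are the canonical +x / +y directions projected into
#' the plane. Degenerate contours (area < `min_area_mm2`) are dropped.
#'
#' @param surfaces a [bone_surface()] or list of them.
#' @param plane an [anatomic_plane()].
#' @param min_area_mm2 cleanup threshold for tangent slivers (default 1).
#' @return list of `contour` objects (possibly empty, with a warning when the
#'   plane misses everything).
#' @export
slice_contours <- function(surfaces, plane, min_area_mm2 = 1) {
  if (inherits(surfaces, "bone_surface")) surfaces <- list(surfaces)
  frame <- plane_frame(plane)
  out <- list()
  for (s in surfaces) {
    polys <- mesh_slice_3d(s, plane)
    for (p in polys) {
      uv <- plane_to_2d(frame, p)
      if (abs(polygon_area(uv)) < min_area_mm2) next
      out[[length(out) + 1L]] <- new_contour(uv, frame, label = s$label)
    }
  }
  if (length(out) == 0) warning("slice_contours: plane intersects no surface")
  out
}

contour_by_label <- function(contours, label) {
  hits <- contours[vapply(contours, function(ct) identical(ct$label, label), TRUE)]
  if (length(hits) == 0) return(NULL)
  hits[[which.max(vapply(hits, function(ct) abs(polygon_area(ct$uv)), 0))]]
}

# Convex-hull concavity analysis of a closed polygon. Returns all "bridges":
# pairs of consecutive hull vertices with contour vertices strictly between
# them, with the maximum perpendicular sag of the bridged arc.
contour_concavities <- function(uv) {
  m <- nrow(uv)
  h <- sort(grDevices::chull(uv))       # hull vertices in contour (CCW) order
  if (length(h) < 3) return(list())
  out <- list()
  for (q in seq_along(h)) {
    i1 <- h[q]
    i2 <- h[if (q == length(h)) 1L else q + 1L]
    arc <- if (i2 > i1) {
      seq(i1 + 1L, length.out = i2 - i1 - 1L)
    } else if (i2 == i1) {
      integer(0)
    } else {
      c(if (i1 < m) (i1 + 1L):m else integer(0),
        if (i2 > 1L) 1L:(i2 - 1L) else integer(0))
    }
    if (length(arc) == 0) next
    # sag of arc points on the interior side of the chord; for a CCW polygon
    # the interior is to the left of i1 -> i2
    sag <- signed_line_distance(uv[arc, , drop = FALSE], uv[i1, ], uv[i2, ])
    depth <- max(sag)
    out[[length(out) + 1L]] <- list(i1 = i1, i2 = i2, arc = arc, depth = depth,
                                    deepest = arc[which.max(sag)])
  }
  out
}

# The incisura: the deepest concavity, or NULL when none exceeds min_depth.
incisura_concavity <- function(uv, min_depth = 0.5) {
  cc <- contour_concavities(uv)
  if (length(cc) == 0) return(NULL)
  depths <- vapply(cc, function(b) b$depth, 0)
  best <- cc[[which.max(depths)]]
  if (best$depth < min_depth) return(NULL)
  best
}

#' Tubercle corner by tangent-line intersection
#'
#' Locates the anterior or posterior tubercle corner bounding the incisura:
#' the supporting (tangent) line along the tubercle's outer flank is
#' intersected with the chord spanning the incisura opening, and the
#' intersection is snapped to the nearest contour vertex within `snap_tol`
#' (the corner lies on the bone), falling back to the nearest contour point.
#'
#' @param tibia_contour a `contour` from [slice_contours()] (tibia).
#' @param which "anterior" or "posterior".
#' @param notch_min_depth minimum concavity depth (mm) for the incisura to
#'   count as present.
#' @param snap_tol vertex snap tolerance (mm).
#' @return list with `point` (2-D, contour frame), `point3d`, and the raw
#'   `intersection` before snapping.
#' @export
tubercle_corner <- function(tibia_contour, which = c("anterior", "posterior"),
                            notch_min_depth = 0.5, snap_tol = 1) {
  which <- match.arg(which)
  uv <- tibia_contour$uv
  notch <- incisura_concavity(uv, min_depth = notch_min_depth)
  if (is.null(notch)) stop("no incisura at this level")
  ends <- c(notch$i1, notch$i2)
  # +v in the contour frame is the canonical anterior direction
  ord <- order(-uv[ends, 2], -uv[ends, 1])
  tip <- if (which == "anterior") ends[ord[1]] else ends[ord[2]]

  # If the tubercle top runs exactly along the opening chord (the chord
  # itself is the tangent there), the corner is where the contour leaves the
  # chord: advance along the bridged arc over any chord-collinear run.
  arc_from_tip <- if (tip == notch$i1) notch$arc else rev(notch$arc)
  sag <- abs(signed_line_distance(uv[arc_from_tip, , drop = FALSE],
                                  uv[notch$i1, ], uv[notch$i2, ]))
  run <- which(cumsum(sag > 1e-9) == 0)
  if (length(run) > 0) {
    pt <- uv[arc_from_tip[run[length(run)]], ]
    return(list(point = pt,
                point3d = drop(contour_to_3d(tibia_contour, matrix(pt, ncol = 2))),
                intersection = pt))
  }

  # otherwise: outer-flank supporting line (hull edge adjacent to the tip on
  # the side away from the notch) intersected with the chord line
  h <- sort(grDevices::chull(uv))
  pos <- match(tip, h)
  nb <- if (tip == notch$i1) h[if (pos == 1) length(h) else pos - 1L]
        else h[if (pos == length(h)) 1L else pos + 1L]
  chord_dir <- uv[notch$i2, ] - uv[notch$i1, ]
  flank_dir <- uv[tip, ] - uv[nb, ]
  inter <- line_intersection(uv[tip, ], flank_dir, uv[notch$i1, ], chord_dir)
  if (is.null(inter)) inter <- uv[tip, ]
  d2v <- sqrt((uv[, 1] - inter[1])^2 + (uv[, 2] - inter[2])^2)
  if (min(d2v) <= snap_tol) {
    pt <- uv[which.min(d2v), ]
  } else {
    pt <- nearest_on_polyline(uv, inter)$point
  }
  list(point = pt,
       point3d = drop(contour_to_3d(tibia_contour, matrix(pt, ncol = 2))),
       intersection = inter)
}
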