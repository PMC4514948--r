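# Simulated non-weight-bearing AP radiograph: orthographic (parallel)
# projection of the bone surfaces along -y onto the coronal x-z plane, and
# the radiographic measurements TCS, TFO, IFH at the plane-Y level.
#
# The silhouette of each bone is stored as per-row horizontal extents
# (piecewise linear in z, exact for polyhedral surfaces). The lateral border
# of the *posterior* tubercle -- occluded by the anterior tubercle in a pure
# outline -- is the tangency edge of the tibial surface posterior to the
# sagittal split y <= y_split, as it appears on film inside the bone shadow.

#' Orthographic AP projection of bone surfaces
#'
#' @param surfaces list of [bone_surface()] (tibia and fibula required for
#'   the radiographic measurements; any bone may be projected).
#' @param dz_mm row spacing of the silhouette tracks (0.2).
#' @param y_split sagittal split (mm) separating the posterior tubercle edge
#'   on the tibial projection.
#' @return an `ap_silhouette`: named list of tibbles with columns `z`,
#'   `x_min`, `x_max` (and `x_post` for the tibia).
#' @export
project_ap <- function(surfaces, dz_mm = 0.2, y_split = 0) {
  out <- list()
  for (s in surfaces) {
    lab <- if (nzchar(s$label)) s$label else sprintf("bone%d", length(out) + 1L)
    zr <- range(s$vertices[, 3])
    zs <- seq(zr[1] + 1e-6, zr[2] - 1e-6, by = dz_mm)
    rows <- lapply(zs, function(z) {
      pts <- mesh_slice_points_z(s, z)
      if (is.null(pts))
        return(c(NA_real_, NA_real_, NA_real_))
      xp <- pts[pts[, 2] <= y_split, 1]
      c(min(pts[, 1]), max(pts[, 1]), if (length(xp)) max(xp) else NA_real_)
    })
    m <- do.call(rbind, rows)
    tb <- tibble::tibble(z = zs, x_min = m[, 1], x_max = m[, 2])
    if (identical(s$label, "tibia")) tb$x_post <- m[, 3]
    out[[lab]] <- tb
  }
  structure(list(bones = out, y_split = y_split, dz_mm = dz_mm),
            class = "ap_silhouette")
}

#' @export
print.ap_silhouette <- function(x, ...) {
  cat("<ap_silhouette>", paste(names(x$bones), collapse = ", "),
      sprintf(" (dz %.3g mm)\n", x$dz_mm))
  invisible(x)
}

# Linear interpolation of a silhouette track column at height z (NA outside).
sil_at <- function(track, col, z) {
  ok <- is.finite(track[[col]])
  if (!any(ok)) return(NA_real_)
  stats::approx(track$z[ok], track[[col]][ok], xout = z, rule = 1)$y
}

#' Project plane X into the AP image
#'
#' @param plane_x the plafond plane.
#' @return list with `point` (x, z), `dir` (unit, along the projected plane
#'   trace) and `up` (unit, image-plane projection of the plane normal).
#' @export
project_plane_line <- function(plane_x) {
  n <- plane_x$normal
  u <- cross3(n, c(0, 1, 0))            # plane trace in the image
  dir <- c(u[1], u[3])
  up <- c(n[1], n[3])
  if (vec_norm(dir) < 1e-9 || vec_norm(up) < 1e-9)
    stop("project_plane_line: plane X is parallel to the beam")
  list(point = c(plane_x$point[1], plane_x$point[3]),
       dir = unit(dir), up = unit(up))
}

#' Radiographic TCS, TFO and IFH at the plane-Y level
#'
#' At height `h` above the plafond line (measured along the line's image
#' normal), the scan line crosses the silhouettes: TCS is the gap between the
#' lateral border of the posterior tubercle and the medial border of the
#' fibula; TFO the overlap between the medial fibular border and the lateral
#' border of the anterior tubercle (floored at 0); IFH the height of the
#' projected incisura tip -- the most proximal level at which the anterior
#' and posterior tubercle borders still separate by > 0.5 mm.
#'
#' @param sil an `ap_silhouette` with tibia and fibula.
#' @param h plane-Y height above the plafond (mm), from the 3-D pipeline.
#' @param plafond_line from [project_plane_line()].
#' @param subject,side identifiers for the output record.
#' @return one-row tibble (modality "radiograph") with `TCS`, `TFO`, `IFH`.
#' @export
measure_radiograph <- function(sil, h, plafond_line,
                               subject = NA_character_, side = "right") {
  stopifnot(inherits(sil, "ap_silhouette"), h >= 0)
  tib <- sil$bones$tibia
  fib <- sil$bones$fibula
  if (is.null(tib) || is.null(fib))
    stop("measure_radiograph: silhouette must contain tibia and fibula")

  borders_at <- function(hh) {
    if (abs(plafond_line$dir[2]) < 1e-9) {
      # horizontal plafond: the scan line is a silhouette row
      z <- plafond_line$point[2] + hh * plafond_line$up[2]
      c(fib_med = sil_at(fib, "x_min", z),
        tib_lat = sil_at(tib, "x_max", z),
        tib_post = sil_at(tib, "x_post", z))
    } else {
      # tilted plafond: 0.1 mm ray scan along the inclined line
      p0 <- plafond_line$point + hh * plafond_line$up
      xr <- range(c(tib$x_min, tib$x_max, fib$x_min, fib$x_max), na.rm = TRUE)
      tt <- seq(-diff(xr) - 10, diff(xr) + 10, by = 0.1)
      px <- p0[1] + tt * plafond_line$dir[1]
      pz <- p0[2] + tt * plafond_line$dir[2]
      occ <- function(track, lo_col = "x_min", hi_col = "x_max") {
        lo <- stats::approx(track$z, track[[lo_col]], xout = pz, rule = 1)$y
        hi <- stats::approx(track$z, track[[hi_col]], xout = pz, rule = 1)$y
        is.finite(lo) & is.finite(hi) & px >= lo & px <= hi
      }
      of <- occ(fib)
      ot <- occ(tib)
      op <- if (!is.null(tib$x_post)) occ(tib, "x_min", "x_post") else rep(FALSE, length(px))
      c(fib_med = if (any(of)) min(px[of]) else NA_real_,
        tib_lat = if (any(ot)) max(px[ot]) else NA_real_,
        tib_post = if (any(op)) max(px[op]) else NA_real_)
    }
  }
  b <- borders_at(h)
  if (!is.finite(b["fib_med"]) || !is.finite(b["tib_lat"]))
    stop("measure_radiograph: the h-line misses a bone silhouette")
  tcs <- unname(b["fib_med"] - b["tib_post"])
  tfo <- max(0, unname(b["tib_lat"] - b["fib_med"]))

  # IFH: track the tubercle-edge separation upward from h
  sep_at <- function(hh) {
    bb <- borders_at(hh)
    if (!is.finite(bb["tib_lat"]) || !is.finite(bb["tib_post"])) return(0)
    unname(bb["tib_lat"] - bb["tib_post"])
  }
  # generous upper bound on reachable heights for the upward tracking
  h_top <- (max(tib$z) - plafond_line$point[2]) / max(abs(plafond_line$up[2]), 0.2)
  ifh <- NA_real_
  if (sep_at(h) > 0.5) {
    g <- h
    z <- h
    step <- max(sil$dz_mm, 0.2)
    repeat {
      z <- z + step
      if (z >= h_top) { g <- h_top; break }
      if (sep_at(z) > 0.5) g <- z else break
    }
    if (z < h_top) {
      bad <- z
      while (bad - g > 1e-4) {
        mid <- (g + bad) / 2
        if (sep_at(mid) > 0.5) g <- mid else bad <- mid
      }
    }
    ifh <- g
  }
  tibble::tibble(subject = as.character(subject), side = side,
                 modality = "radiograph", XY = NA_real_, TCS_A = NA_real_,
                 TCS_P = NA_real_, IFD = NA_real_, IFH = ifh,
                 TCS = tcs, TFO = tfo)
}
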