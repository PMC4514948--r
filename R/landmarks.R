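# Plane X, plane Y, landmarks A-F, and the 3-D / 2-D axial measurements.

#' Fit the tibial plafond plane (plane X)
#'
#' Grows an articular patch over the distal tibial surface from a seed point
#' (faces whose normals stay within `normal_tol_deg` of the seed face's
#' normal, within a geodesic radius), then fits a total-least-squares plane to
#' the patch vertices. The normal is oriented proximally (away from the patch,
#' toward the bone centroid side).
#'
#' @param tibia tibial [bone_surface()].
#' @param articular_seed length-3 point within 5 mm of the distal articular
#'   surface.
#' @param normal_tol_deg face-normal tolerance for region growth (30).
#' @param radius_mm geodesic radius limit (25).
#' @param min_faces minimum patch size; below it the fit aborts.
#' @return an [anatomic_plane()] with attribute `patch_faces`.
#' @export
fit_plafond_plane <- function(tibia, articular_seed, normal_tol_deg = 30,
                              radius_mm = 25, min_faces = 50) {
  v <- tibia$vertices
  f <- tibia$faces
  fn <- mesh_face_normals(tibia)
  cent <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
             v[f[, 3], , drop = FALSE]) / 3
  seed <- as.numeric(articular_seed)
  d_vert <- sqrt(colSums((t(v) - seed)^2))
  if (min(d_vert) > 5)
    stop("fit_plafond_plane: articular seed is more than 5 mm from the surface")
  v0 <- which.min(d_vert)
  f0 <- which(f[, 1] == v0 | f[, 2] == v0 | f[, 3] == v0)[1]
  n0 <- fn$normals[f0, ]
  cos_tol <- cos(normal_tol_deg * pi / 180)
  eligible <- (fn$normals %*% n0)[, 1] >= cos_tol

  # face adjacency over shared edges, restricted to eligible faces
  ek <- mesh_edge_keys(f)
  fid <- rep(seq_len(nrow(f)), 3)
  keep <- eligible[fid]
  ek <- ek[keep]; fid <- fid[keep]
  sp <- split(fid, ek)
  sp <- sp[lengths(sp) == 2]
  el <- do.call(rbind, sp)
  # BFS with approximate geodesic distance via centroid hops
  dist <- rep(Inf, nrow(f))
  dist[f0] <- 0
  if (!is.null(el) && nrow(el) > 0) {
    adj <- split(c(el[, 2], el[, 1]), c(el[, 1], el[, 2]))
    frontier <- f0
    while (length(frontier)) {
      nxt <- integer(0)
      for (fc in frontier) {
        nbs <- adj[[as.character(fc)]]
        if (is.null(nbs)) next
        for (nb in nbs) {
          nd <- dist[fc] + sqrt(sum((cent[nb, ] - cent[fc, ])^2))
          if (nd < dist[nb] && nd <= radius_mm) {
            dist[nb] <- nd
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  patch <- which(is.finite(dist))
  if (length(patch) < min_faces) stop("articular patch too small")
  pv <- unique(as.vector(f[patch, ]))
  P <- v[pv, , drop = FALSE]
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  n <- sv$v[, 3]
  # orient proximally: the bone lies on the normal side of the plafond
  if (sum((colMeans(v) - ctr) * n) < 0) n <- -n
  pl <- anatomic_plane(ctr, n)
  attr(pl, "patch_faces") <- patch
  pl
}

#' Locate point A and the measurement level
#'
#' Scans candidate levels above plane X, computing at each the incisura
#' concavity depth of the tibial cross-section (the IFD at that level). Point
#' A is the anterior tubercle corner at the level of maximal depth -- the
#' individualized measurement level; ties break toward the most distal level.
#' A golden-section refinement (on by default) sharpens the coarse scan.
#'
#' @param tibia tibial [bone_surface()].
#' @param plane_x plafond plane from [fit_plafond_plane()].
#' @param window_mm search window above plane X (default `c(4, 20)`).
#' @param step_mm scan step (default 0.625, one slice spacing).
#' @param refine logical; refine the maximizing level by continuous search.
#' @param notch_min_depth,snap_tol passed to [tubercle_corner()].
#' @return list with `point` (A, 3-D), `z_star` (= XY, mm above plane X),
#'   `contour` (tibial contour at the level) and `profile` (tibble of the
#'   scanned levels and depths).
#' @export
locate_point_A <- function(tibia, plane_x, window_mm = c(4, 20),
                           step_mm = 0.625, refine = TRUE,
                           notch_min_depth = 0.5, snap_tol = 1) {
  depth_at <- function(z) {
    ct <- tibia_section(tibia, plane_x, z)
    if (is.null(ct)) return(-Inf)
    notch <- incisura_concavity(ct$uv, min_depth = 0)
    if (is.null(notch)) return(0)
    notch$depth
  }
  zs <- seq(window_mm[1], window_mm[2], by = step_mm)
  depths <- vapply(zs, depth_at, 0)
  if (!any(is.finite(depths) & depths > notch_min_depth))
    stop("locate_point_A: no level in the window shows an incisura")
  z_best <- zs[which.max(depths)]       # first maximum = most distal tie-break
  if (refine) {
    lo <- max(window_mm[1], z_best - step_mm)
    hi <- min(window_mm[2], z_best + step_mm)
    opt <- stats::optimize(depth_at, c(lo, hi), maximum = TRUE, tol = 1e-9)
    if (opt$objective >= depths[which.max(depths)] - 1e-12) z_best <- opt$maximum
  }
  ct <- tibia_section(tibia, plane_x, z_best)
  corner <- tubercle_corner(ct, "anterior", notch_min_depth = notch_min_depth,
                            snap_tol = snap_tol)
  A <- corner$point3d
  list(point = A, z_star = plane_distance(plane_x, A)[1], contour = ct,
       profile = tibble::tibble(z = zs, depth = depths))
}

# Largest tibial cross-section at height z above plane X (NULL if none).
tibia_section <- function(tibia, plane_x, z) {
  pl <- plane_offset(plane_x, z)
  cts <- withCallingHandlers(
    slice_contours(tibia, pl),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(cts) == 0) return(NULL)
  cts[[which.max(vapply(cts, function(ct) abs(polygon_area(ct$uv)), 0))]]
}

#' Build the measurement plane (plane Y)
#'
#' The plane through point A parallel to plane X; XY is the signed height of
#' A above plane X (proximal positive).
#'
#' @param plane_x plafond plane.
#' @param A point A (3-D, mm).
#' @return list with `plane_y` ([anatomic_plane()]) and `xy_mm`.
#' @export
build_plane_Y <- function(plane_x, A) {
  xy <- plane_distance(plane_x, A)[1]
  if (xy < -1e-9)
    stop("build_plane_Y: point A lies below plane X")
  list(plane_y = anatomic_plane(as.numeric(A), plane_x$normal), xy_mm = xy)
}

#' Locate landmarks A-E in plane Y
#'
#' B is the fibular point nearest A (over contour edges, not vertices only);
#' C the posterior tubercle corner; D the fibular point nearest C; E the
#' deepest point of the incisura notch, i.e. the notch-arc point at maximal
#' perpendicular distance from line AC on the medial side.
#'
#' @param tibia_contour,fibula_contour contours in plane Y.
#' @param A point A as a 3-D point (from [locate_point_A()]).
#' @param notch_min_depth,snap_tol passed to [tubercle_corner()].
#' @return a `landmark_set`: list with 3-D points `A` ... `E`, their 2-D
#'   counterparts in the plane frame (`uv`), and the frame.
#' @export
locate_landmarks <- function(tibia_contour, fibula_contour, A,
                             notch_min_depth = 0.5, snap_tol = 1) {
  if (is.null(fibula_contour)) stop("fibula not present at plane Y")
  frame <- tibia_contour$frame
  A2 <- drop(plane_to_2d(frame, matrix(A, ncol = 3)))
  fib_uv <- fibula_contour$uv
  nb <- nearest_on_polyline(fib_uv, A2)
  B2 <- nb$point
  corner_c <- tubercle_corner(tibia_contour, "posterior",
                              notch_min_depth = notch_min_depth,
                              snap_tol = snap_tol)
  C2 <- corner_c$point
  nd <- nearest_on_polyline(fib_uv, C2)
  D2 <- nd$point
  notch <- incisura_concavity(tibia_contour$uv, min_depth = notch_min_depth)
  if (is.null(notch)) stop("locate_landmarks: no incisura notch in the tibial contour")
  arc_uv <- tibia_contour$uv[notch$arc, , drop = FALSE]
  medial_sign <- sign(signed_line_distance(
    matrix(polygon_centroid(tibia_contour$uv), ncol = 2), A2, C2))
  sag <- medial_sign * signed_line_distance(arc_uv, A2, C2)
  E2 <- arc_uv[which.max(sag), ]
  to3 <- function(p2) drop(contour_to_3d(tibia_contour, matrix(p2, ncol = 2)))
  structure(list(A = as.numeric(A), B = to3(B2), C = to3(C2), D = to3(D2),
                 E = to3(E2),
                 uv = list(A = A2, B = B2, C = C2, D = D2, E = E2),
                 frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  for (nm in c("A", "B", "C", "D", "E"))
    cat(sprintf("  %s: (%8.3f, %8.3f, %8.3f)\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Locate point F (proximal tip of the incisura)
#'
#' Tracks the incisura notch upward from plane Y section by section; F is the
#' deepest notch point at the most proximal level where the concavity depth
#' still exceeds `notch_min_depth` (bisection-refined by default).
#'
#' @param tibia tibial [bone_surface()].
#' @param plane_x,plane_y the two planes.
#' @param step_mm tracking step (default 0.5).
#' @param notch_min_depth depth threshold ending the notch (0.5 mm).
#' @param refine bisection-refine the crossing level.
#' @return list with `point` (F, 3-D) and `height_mm` above plane X (= IFH).
#' @export
locate_point_F <- function(tibia, plane_x, plane_y, step_mm = 0.5,
                           notch_min_depth = 0.5, refine = TRUE) {
  z0 <- plane_distance(plane_x, plane_y$point)[1]
  z_top <- max(plane_distance(plane_x, tibia$vertices))
  depth_at <- function(z) {
    ct <- tibia_section(tibia, plane_x, z)
    if (is.null(ct)) return(0)
    notch <- incisura_concavity(ct$uv, min_depth = 0)
    if (is.null(notch)) 0 else notch$depth
  }
  if (depth_at(z0) <= notch_min_depth)
    stop("locate_point_F: no incisura notch at plane Y")
  z_good <- z0
  z <- z0
  repeat {
    z <- z + step_mm
    if (z >= z_top)
      stop("incisura not closed within volume")
    if (depth_at(z) > notch_min_depth) z_good <- z else break
  }
  z_bad <- z
  if (refine) {
    while (z_bad - z_good > 1e-7) {
      mid <- (z_good + z_bad) / 2
      if (depth_at(mid) > notch_min_depth) z_good <- mid else z_bad <- mid
    }
  }
  ct <- tibia_section(tibia, plane_x, z_good)
  notch <- incisura_concavity(ct$uv, min_depth = 0)
  F2 <- ct$uv[notch$deepest, ]
  F3 <- drop(contour_to_3d(ct, matrix(F2, ncol = 2)))
  list(point = F3, height_mm = plane_distance(plane_x, F3)[1])
}

#' Assemble a 3-D measurement record
#'
#' @param landmarks a `landmark_set` from [locate_landmarks()].
#' @param plane_x,plane_y the two planes.
#' @param F_point optional point F (3-D) for IFH.
#' @param subject,side identifiers carried into the record.
#' @return one-row tibble: `subject`, `side`, `modality`, `XY`, `TCS_A`,
#'   `TCS_P`, `IFD`, `IFH` (mm).
#' @export
measure_3d <- function(landmarks, plane_x, plane_y, F_point = NULL,
                       subject = NA_character_, side = "right") {
  lk <- landmarks
  tcs_a <- vec_norm(lk$B - lk$A)
  tcs_p <- vec_norm(lk$D - lk$C)
  # IFD: perpendicular distance from E to the (infinite) line AC
  ac <- lk$C - lk$A
  w <- lk$E - lk$A
  ifd <- vec_norm(w - sum(w * ac) / sum(ac * ac) * ac)
  xy <- plane_distance(plane_x, plane_y$point)[1]
  ifh <- if (is.null(F_point)) NA_real_ else plane_distance(plane_x, F_point)[1]
  tibble::tibble(subject = as.character(subject), side = side, modality = "3-D",
                 XY = xy, TCS_A = tcs_a, TCS_P = tcs_p, IFD = ifd, IFH = ifh,
                 TCS = NA_real_, TFO = NA_real_)
}

#' Full mesh-path measurement of one subject
#'
#' Runs the complete 3-D procedure on labeled surfaces: plane X from the
#' articular seed, point A and plane Y, landmarks, point F, and (optionally)
#' the simulated-radiograph parameters.
#'
#' @param surfaces named list with `tibia` and `fibula` (and optionally
#'   `talus`, ignored) [bone_surface()] objects, canonical frame. Left-side
#'   scenes (per `side`) are mirrored to the right-handed canonical frame
#'   before measurement.
#' @param articular_seed seed on the distal tibial articular surface.
#' @param side "right" or "left" (tag carried to the output).
#' @param subject subject identifier.
#' @param radiograph logical; also compute the AP-projection record.
#' @param window_mm,step_mm passed to [locate_point_A()].
#' @param refine passed to the level searches.
#' @return tibble with one row per modality, plus attributes `landmarks`,
#'   `plane_x`, `plane_y`.
#' @export
measure_surfaces <- function(surfaces, articular_seed, side = "right",
                             subject = NA_character_, radiograph = TRUE,
                             window_mm = c(4, 20), step_mm = 0.625,
                             refine = TRUE) {
  stopifnot(!is.null(surfaces$tibia), !is.null(surfaces$fibula))
  if (side == "left") {
    surfaces <- lapply(surfaces, mesh_mirror_x)
    articular_seed <- articular_seed * c(-1, 1, 1)
  }
  plane_x <- fit_plafond_plane(surfaces$tibia, articular_seed)
  ptA <- locate_point_A(surfaces$tibia, plane_x, window_mm = window_mm,
                        step_mm = step_mm, refine = refine)
  py <- build_plane_Y(plane_x, ptA$point)
  cts <- slice_contours(surfaces[c("tibia", "fibula")], py$plane_y)
  lk <- locate_landmarks(contour_by_label(cts, "tibia"),
                         contour_by_label(cts, "fibula"), ptA$point)
  ptF <- locate_point_F(surfaces$tibia, plane_x, py$plane_y)
  rec <- measure_3d(lk, plane_x, py$plane_y, F_point = ptF$point,
                    subject = subject, side = side)
  if (radiograph) {
    sil <- project_ap(surfaces[c("tibia", "fibula")])
    rx <- measure_radiograph(sil, h = py$xy_mm, plafond_line = project_plane_line(plane_x),
                             subject = subject, side = side)
    rec <- dplyr::bind_rows(rec, rx)
  }
  attr(rec, "landmarks") <- lk
  attr(rec, "plane_x") <- plane_x
  attr(rec, "plane_y") <- py$plane_y
  attr(rec, "F_point") <- ptF$point
  rec
}
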