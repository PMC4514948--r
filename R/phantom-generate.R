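# Parametric distal tibia / fibula / talus phantom.
#
# Anatomy family: the tibial shaft is a superelliptical tube whose lateral
# aspect carries two tubercle ridges bounding a concave incisura notch; the
# fibula is a tapered elliptical tube placed so the requested clear spaces and
# overlap are realized exactly; the talus is an ellipsoid below the plafond.
# The plafond is the flat distal cap at z = 0 in the phantom frame (+x lateral,
# +y anterior, +z proximal, right side).
#
# Truth is defined on the discrete geometry the meshes actually carry: the
# notch apex and tubercle tips are mesh vertices, and the fibula placement is
# solved against its discretized ring polygon, so measuring the meshes can
# recover every truth value to machine precision.

phantom_anatomy <- function(detail = 1) {
  even <- function(n) max(4L, 2L * as.integer(round(n / 2)))
  list(
    a_t = 10, b_t = 14, m = 2.5,        # tibial base superellipse (mm, exponent)
    tipA = c(19, 8),                     # anterior tubercle tip (constant below taper)
    y_C = -8,                            # posterior tubercle tip y
    att_y = 11,                          # |y| of the tubercle attachment on the base
    fib_a = 11, fib_b = 6.5,             # fibular ellipse semi-axes (y, x)
    talus_centre = c(0, -2, -13), talus_semi = c(18, 14, 10),
    d_end = 0.5,                         # notch depth at the incisura tip (mm)
    fade = 0.4,                          # depth fade-out length above the tip (mm)
    d_slope = 0.35,                      # depth slope at the peak (mm per mm)
    d_floor = 0.8,                       # distal depth floor (mm)
    d_close = 1.5, close_run = 3,        # steeper closure run below the tip
    taper_lead = 4,                      # taper starts this far above plane Y
    fib_bot_lead = 5, fib_top_lead = 3,  # fibular stub spans plane Y -/+ these
    n_base = even(180 * detail), n_fl = even(12 * detail),
    n_notch = even(120 * detail), n_fib = even(180 * detail),
    dz = 0.75 / detail^0,                # ring spacing (kept fixed; counts scale)
    debris_y = -32
  )
}

superellipse_point <- function(theta, a, b, m) {
  ct <- cos(theta); st <- sin(theta)
  cbind(a * sign(ct) * abs(ct)^(2 / m), b * sign(st) * abs(st)^(2 / m))
}

# Notch depth profile: a piecewise-linear tent peaking at exactly ifd at
# z = xy (the slope at the peak is what makes plane Y identifiable, also at
# voxel resolution), descending proximally to d_end exactly at z = ifh, then
# fading to zero over `fade` mm. All slope breaks coincide with mesh knot
# rings, so the linearly interpolated mesh realizes the profile exactly.
notch_depth <- function(z, spec, an) {
  xy <- spec$xy_true_mm; ifh <- spec$ifh_true_mm; ifd <- spec$ifd_true_mm
  d <- numeric(length(z))
  lo <- z <= xy
  d[lo] <- pmax(ifd - an$d_slope * (xy - z[lo]), an$d_floor)
  z1 <- xy + an$taper_lead                # slope break, shared with the taper
  d1 <- ifd - an$d_slope * an$taper_lead
  mid <- z > xy & z <= z1
  d[mid] <- ifd - an$d_slope * (z[mid] - xy)
  z2 <- ifh - an$close_run                # steeper closure run up to the tip
  hi <- z > z1 & z <= z2
  d[hi] <- an$d_close + (d1 - an$d_close) * (z2 - z[hi]) / (z2 - z1)
  cl <- z > z2 & z <= ifh
  d[cl] <- an$d_end + (an$d_close - an$d_end) * (ifh - z[cl]) / an$close_run
  top <- z > ifh & z < ifh + an$fade
  d[top] <- an$d_end * (1 - (z[top] - ifh) / an$fade)
  pmax(d, 0)
}

# Tubercle taper factor: 1 (full tips) at and below plane Y + taper_lead,
# 0 (tips merged into the base) at and above the incisura tip.
tubercle_taper <- function(z, spec, an) {
  z0 <- spec$xy_true_mm + an$taper_lead
  z1 <- spec$ifh_true_mm
  pmin(1, pmax(0, (z1 - z) / (z1 - z0)))
}

phantom_attachments <- function(an) {
  # attachment points of the tubercle flanks on the base superellipse at y = +-att_y
  s <- (an$att_y / an$b_t)^(an$m / 2)
  th <- asin(s)
  attA <- drop(superellipse_point(th, an$a_t, an$b_t, an$m))
  attC <- c(attA[1], -attA[2])
  list(attA = attA, attC = attC, theta = th)
}

phantom_tips <- function(z, spec, an, x_C) {
  t <- tubercle_taper(z, spec, an)
  att <- phantom_attachments(an)
  tipA0 <- an$tipA
  tipC0 <- c(x_C, an$y_C)
  list(tipA = att$attA + t * (tipA0 - att$attA),
       tipC = att$attC + t * (tipC0 - att$attC))
}

# V-shaped notch from P to Q sagging to depth d at the chord midpoint:
# straight walls P -> apex and apex -> Q. The V keeps the tubercle tips
# blunt enough to survive voxelization (a circular arc would leave the
# anterior tip as a razor-thin wedge). Returns n+1 points including both
# endpoints, apex exactly at the middle (n even).
notch_path <- function(P, Q, d, n) {
  M <- (P + Q) / 2
  u <- unit(Q - P)
  n_out <- c(u[2], -u[1])
  # sag medially (toward the origin of the section frame)
  if (sum((M - d * n_out)^2) > sum((M + d * n_out)^2)) n_out <- -n_out
  apex <- M - d * n_out
  h <- n / 2
  s1 <- seq(0, 1, length.out = h + 1)
  w1 <- cbind(P[1] + s1 * (apex[1] - P[1]), P[2] + s1 * (apex[2] - P[2]))
  s2 <- seq(0, 1, length.out = h + 1)[-1]
  w2 <- cbind(apex[1] + s2 * (Q[1] - apex[1]), apex[2] + s2 * (Q[2] - apex[2]))
  rbind(w1, w2)
}

# One tibial cross-section ring (closed polygon, counter-clockwise) at depth d
# with tubercle tips at tipA / tipC. Fixed vertex count and segment layout so
# rings can be stacked into a watertight extrusion.
tibia_ring <- function(d, tipA, tipC, an) {
  att <- phantom_attachments(an)
  th <- att$theta
  theta_base <- seq(th, 2 * pi - th, length.out = an$n_base + 1)[-(an$n_base + 1)]
  base <- superellipse_point(theta_base, an$a_t, an$b_t, an$m)
  sfl <- seq(0, 1, length.out = an$n_fl + 1)[-(an$n_fl + 1)]
  flank_post <- cbind(att$attC[1] + sfl * (tipC[1] - att$attC[1]),
                      att$attC[2] + sfl * (tipC[2] - att$attC[2]))
  # notch from posterior tip to anterior tip, sagging medially
  arc <- notch_path(tipC, tipA, d, an$n_notch)
  arc <- arc[-(an$n_notch + 1), , drop = FALSE]
  flank_ant <- cbind(tipA[1] + sfl * (att$attA[1] - tipA[1]),
                     tipA[2] + sfl * (att$attA[2] - tipA[2]))
  rbind(base, flank_post, arc, flank_ant)
}

fibula_ring <- function(cx, cy, an, scale = 1) {
  phi <- 2 * pi * (0:(an$n_fib - 1)) / an$n_fib
  cbind(cx + scale * an$fib_b * cos(phi), cy + scale * an$fib_a * sin(phi))
}

signed_polydist <- function(p, poly) {
  d <- nearest_on_polyline(poly, p)$dist
  if (points_in_polygon(matrix(p, ncol = 2), poly)) -d else d
}

# Solve the fibular placement (centre) and the posterior tubercle tip x so
# that TCS-A, TCS-P and TFO are realized exactly on the discrete ring.
solve_fibula <- function(spec, an) {
  tipA <- an$tipA
  cx <- tipA[1] - spec$tfo_true_mm + an$fib_b
  g <- function(cy) signed_polydist(tipA, fibula_ring(cx, cy, an)) - spec$tcsa_true_mm
  lo <- tipA[2] - an$fib_a - spec$tcsa_true_mm - 8
  hi <- tipA[2]
  if (g(hi) > 0)
    stop("infeasible phantom: tfo_true_mm too large for the tubercle geometry ",
         "(anterior clear space cannot be realized)")
  cy <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  ring <- fibula_ring(cx, cy, an)
  h <- function(x) signed_polydist(c(x, an$y_C), ring) - spec$tcsp_true_mm
  xlo <- cx - an$fib_b - spec$tcsp_true_mm - 10
  if (h(cx) > 0)
    stop("infeasible phantom: posterior clear space cannot be realized ",
         "(fibula too far from the posterior tubercle line)")
  x_C <- stats::uniroot(h, c(xlo, cx), tol = 1e-12)$root

  att <- phantom_attachments(an)
  base_x <- an$a_t * (1 - (abs(an$y_C) / an$b_t)^an$m)^(1 / an$m)
  if (x_C < base_x + 0.8)
    stop("infeasible phantom: posterior tubercle does not protrude from the shaft")
  # the posterior tip must stay on the convex hull of the section
  s <- (an$y_C - tipA[2]) / (att$attC[2] - tipA[2])
  x_line <- tipA[1] + s * (att$attC[1] - tipA[1])
  if (x_C < x_line + 0.3)
    stop("infeasible phantom: posterior tubercle too shallow to form a hull corner")
  if ((tipA[1] - spec$tfo_true_mm) - x_C <= 0)
    stop("infeasible phantom: projected posterior clear space non-positive")
  list(cx = cx, cy = cy, x_C = x_C, ring = ring)
}

tibia_z_knots <- function(spec, an) {
  H <- spec$ifh_true_mm + 6
  z_floor <- spec$xy_true_mm - (spec$ifd_true_mm - an$d_floor) / an$d_slope
  z <- sort(unique(c(seq(0, H, by = an$dz), spec$xy_true_mm,
                     if (z_floor > 0) z_floor,
                     spec$xy_true_mm + an$taper_lead,
                     spec$ifh_true_mm - an$close_run, spec$ifh_true_mm,
                     spec$ifh_true_mm + an$fade, H)))
  z[c(TRUE, diff(z) > 1e-9)]
}

# Stack same-count rings into a closed extrusion with flat centroid-fan caps.
extrude_rings <- function(rings2d, z_levels, label = "") {
  K <- length(z_levels)
  N <- nrow(rings2d[[1]])
  verts <- do.call(rbind, lapply(seq_len(K), function(k)
    cbind(rings2d[[k]], z_levels[k])))
  idx <- function(k, i) (k - 1L) * N + i
  i1 <- seq_len(N)
  i2 <- c(2:N, 1L)
  faces <- vector("list", K - 1L)
  for (k in seq_len(K - 1L)) {
    a <- idx(k, i1); b <- idx(k, i2); a2 <- idx(k + 1L, i1); b2 <- idx(k + 1L, i2)
    faces[[k]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  cb <- colMeans(rings2d[[1]])
  ct <- colMeans(rings2d[[K]])
  vb <- nrow(verts) + 1L
  vt <- nrow(verts) + 2L
  verts <- rbind(verts, c(cb, z_levels[1]), c(ct, z_levels[K]))
  cap_b <- cbind(vb, idx(1L, i2), idx(1L, i1))
  cap_t <- cbind(vt, idx(K, i1), idx(K, i2))
  bone_surface(verts, rbind(do.call(rbind, faces), cap_b, cap_t),
               label = label, closed = TRUE)
}

ellipsoid_surface <- function(centre, semi, n_u = 48, n_v = 24, label = "talus") {
  u <- 2 * pi * (0:(n_u - 1)) / n_u
  v <- pi * (1:(n_v - 1)) / n_v            # interior stacks; poles added separately
  vg <- expand.grid(u = u, v = v)
  verts <- cbind(centre[1] + semi[1] * sin(vg$v) * cos(vg$u),
                 centre[2] + semi[2] * sin(vg$v) * sin(vg$u),
                 centre[3] + semi[3] * cos(vg$v))
  north <- centre + c(0, 0, semi[3])
  south <- centre - c(0, 0, semi[3])
  iN <- nrow(verts) + 1L
  iS <- nrow(verts) + 2L
  verts <- rbind(verts, north, south)
  at <- function(i, j) (j - 1L) * n_u + i   # i in 1..n_u, j in 1..n_v-1
  i1 <- seq_len(n_u); i2 <- c(2:n_u, 1L)
  faces <- list(cbind(iN, at(i1, 1L), at(i2, 1L)))
  if (n_v > 2) for (j in seq_len(n_v - 2L)) {
    a <- at(i1, j); b <- at(i2, j); a2 <- at(i1, j + 1L); b2 <- at(i2, j + 1L)
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b2, b), cbind(a, a2, b2))
  }
  faces[[length(faces) + 1L]] <- cbind(iS, at(i2, n_v - 1L), at(i1, n_v - 1L))
  bone_surface(verts, do.call(rbind, faces), label = label, closed = TRUE)
}

phantom_transform <- function(spec) {
  R <- rotation_matrix(c(0, 1, 0), spec$plafond_tilt_deg[2]) %*%
    rotation_matrix(c(1, 0, 0), spec$plafond_tilt_deg[1])
  M <- if (spec$side == "left") diag(c(-1, 1, 1)) else diag(3)
  R %*% M
}

#' Generate the ankle phantom
#'
#' Builds watertight tibia, fibula and talus surfaces realizing the requested
#' morphometry exactly, an optional voxelized CT-like volume with debris and
#' noise, and the analytic ground truth for every measured parameter.
#'
#' @param spec a [phantom_spec()].
#' @param voxelize logical; also rasterize the surfaces into a [vox_vol()]
#'   (the slower part; skip for mesh-path work).
#' @param detail ring-density factor in (0, 1]; 1 is the default density,
#'   smaller values give coarser but internally consistent phantoms.
#' @return a list with elements `surfaces` (named list of [bone_surface()]:
#'   tibia, fibula, talus), `volume` (a [vox_vol()] or `NULL`), and `truth`
#'   (a `phantom_truth` object, see [phantom_truth_values()]).
#' @examples
#' ph <- generate_phantom(phantom_preset("male"), voxelize = FALSE, detail = 0.5)
#' ph$truth$xy
#' @export
generate_phantom <- function(spec, voxelize = TRUE, detail = 1) {
  validate_phantom_spec(spec)
  an <- phantom_anatomy(detail)
  fib <- solve_fibula(spec, an)

  zt <- tibia_z_knots(spec, an)
  rings <- lapply(zt, function(z) {
    tips <- phantom_tips(z, spec, an, fib$x_C)
    tibia_ring(notch_depth(z, spec, an), tips$tipA, tips$tipC, an)
  })
  tibia <- extrude_rings(rings, zt, label = "tibia")

  fib_bot <- spec$xy_true_mm - an$fib_bot_lead
  fib_top <- spec$xy_true_mm + an$fib_top_lead
  # the fibular stub and the notch must never touch (segmentation relies on
  # it); require clearance comfortably above the voxel diagonal
  in_range <- zt >= fib_bot - 0.5 & zt <= fib_top
  fv <- fibula_ring(fib$cx, fib$cy, an)
  min_clear <- min(1, 1.6 * max(spec$voxel_spacing_mm))
  for (k in which(in_range)) {
    tv <- rings[[k]]
    min_vv <- sqrt(min(outer(fv[, 1], tv[, 1], "-")^2 +
                       outer(fv[, 2], tv[, 2], "-")^2))
    if (min_vv > min_clear + 1) next          # vertex gap bounds the true gap
    if (any(points_in_polygon(fv, tv)))
      stop("infeasible phantom: fibula intersects the incisura")
    dmin <- min(vapply(seq_len(nrow(fv)), function(i)
      nearest_on_polyline(tv, fv[i, ])$dist, 0))
    if (dmin < min_clear)
      stop("infeasible phantom: tibia-fibula clearance below ",
           signif(min_clear, 3), " mm at z = ", signif(zt[k], 4))
  }

  zf <- sort(unique(c(seq(fib_bot, fib_top, by = 1), fib_bot + 2, fib_top)))
  zf <- zf[c(TRUE, diff(zf) > 1e-9)]
  fib_scale <- function(z) ifelse(z >= fib_bot + 2, 1,
                                  0.45 + 0.55 * (z - fib_bot) / 2)
  frings <- lapply(zf, function(z) fibula_ring(fib$cx, fib$cy, an, scale = fib_scale(z)))
  fibula <- extrude_rings(frings, zf, label = "fibula")

  talus <- ellipsoid_surface(an$talus_centre, an$talus_semi)

  truth <- phantom_truth(spec, an, fib)
  Tr <- phantom_transform(spec)
  surfaces <- lapply(list(tibia = tibia, fibula = fibula, talus = talus),
                     mesh_transform, rotation = Tr)
  truth <- transform_truth(truth, Tr)

  volume <- if (voxelize) voxelize_phantom(spec, surfaces, an) else NULL
  list(surfaces = surfaces, volume = volume, truth = truth)
}

phantom_truth <- function(spec, an, fib) {
  xy <- spec$xy_true_mm
  tipA <- an$tipA
  tipC <- c(fib$x_C, an$y_C)
  nb <- nearest_on_polyline(fib$ring, tipA)
  B2 <- nb$point
  nd <- nearest_on_polyline(fib$ring, tipC)
  D2 <- nd$point
  M <- (tipA + tipC) / 2
  u <- unit(tipC - tipA)
  n_out <- c(u[2], -u[1])
  if (sum((M + n_out)^2) < sum(M^2)) n_out <- -n_out   # ensure lateral
  E2 <- M - spec$ifd_true_mm * n_out
  # F: notch apex at the incisura tip level (tips fully tapered there)
  tipsF <- phantom_tips(spec$ifh_true_mm, spec, an, fib$x_C)
  MF <- (tipsF$tipA + tipsF$tipC) / 2
  uF <- unit(tipsF$tipC - tipsF$tipA)
  nF <- c(uF[2], -uF[1])
  if (sum((MF + nF)^2) < sum(MF^2)) nF <- -nF
  F2 <- MF - an$d_end * nF

  structure(list(
    spec = spec,
    plane_x = anatomic_plane(c(0, 0, 0), c(0, 0, 1)),
    plane_y = anatomic_plane(c(0, 0, xy), c(0, 0, 1)),
    A = c(tipA, xy), B = c(B2, xy), C = c(tipC, xy), D = c(D2, xy),
    E = c(E2, xy), F = c(F2, spec$ifh_true_mm),
    fibula_centre = c(fib$cx, fib$cy),
    xy = xy, tcsa = spec$tcsa_true_mm, tcsp = spec$tcsp_true_mm,
    ifd = spec$ifd_true_mm, ifh = spec$ifh_true_mm, tfo = spec$tfo_true_mm
  ), class = "phantom_truth")
}

transform_truth <- function(truth, Tr) {
  tp <- function(p) as.numeric(Tr %*% p)
  for (nm in c("A", "B", "C", "D", "E", "F")) truth[[nm]] <- tp(truth[[nm]])
  for (nm in c("plane_x", "plane_y")) {
    truth[[nm]] <- anatomic_plane(tp(truth[[nm]]$point),
                                  as.numeric(Tr %*% truth[[nm]]$normal) * det(Tr))
  }
  truth
}

#' Ground-truth values of a phantom as a tidy table
#'
#' @param truth the `truth` element returned by [generate_phantom()].
#' @return a tibble with columns `parameter`, `modality`, `value_mm`.
#' @export
phantom_truth_values <- function(truth) {
  tibble::tibble(
    parameter = c("XY", "TCS_A", "TCS_P", "IFD", "IFH",
                  "TCS_A", "TCS_P", "IFD", "TFO", "IFH"),
    modality = c(rep("3-D", 5), rep("2-D axial", 3), "radiograph", "radiograph"),
    value_mm = c(truth$xy, truth$tcsa, truth$tcsp, truth$ifd, truth$ifh,
                 truth$tcsa, truth$tcsp, truth$ifd, truth$tfo, NA_real_)
  )
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_truth> %s side\n",
                     "  XY %.3f  TCS-A %.3f  TCS-P %.3f  IFD %.3f  IFH %.3f  TFO %.3f (mm)\n"),
              x$spec$side, x$xy, x$tcsa, x$tcsp, x$ifd, x$ifh, x$tfo))
  invisible(x)
}
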