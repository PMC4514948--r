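# 2-D axial measurement: resample one oblique CT section at plane Y,
# re-segment in-plane at the density threshold, and measure with the same
# landmark constructions as the 3-D path.

trilinear_sample <- function(vol, pts, fill = -1000) {
  pts <- matrix(pts, ncol = 3)
  d <- dim(vol$values)
  fi <- sweep(sweep(pts, 2, vol$origin), 2, vol$spacing, "/") + 1
  i0 <- floor(fi)
  fr <- fi - i0
  ok <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] < d[1] & i0[, 2] < d[2] & i0[, 3] < d[3]
  out <- rep(fill, nrow(pts))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  fr <- fr[ok, , drop = FALSE]
  at <- function(dx, dy, dz)
    vol$values[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  w <- function(dx, dy, dz)
    (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
    (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
    (if (dz == 1) fr[, 3] else 1 - fr[, 3])
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    acc <- acc + w(dx, dy, dz) * at(dx, dy, dz)
  out[ok] <- acc
  out
}

# Extract closed sub-voxel contours of `level` from a resampled section.
section_contours <- function(u, v, hu, level, frame) {
  cl <- grDevices::contourLines(u, v, hu, levels = level)
  out <- list()
  for (ln in cl) {
    p <- cbind(ln$x, ln$y)
    closed <- sqrt(sum((p[1, ] - p[nrow(p), ])^2)) < 1e-9
    if (!closed) next
    p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3 || abs(polygon_area(p)) < 1) next
    out[[length(out) + 1L]] <- new_contour(p, frame)
  }
  out
}

#' Measure the syndesmosis on the 2-D axial section at plane Y
#'
#' Resamples one oblique section of the volume at plane Y (one-voxel
#' thickness, trilinear interpolation), re-segments it in-plane at
#' `threshold_hu` with sub-voxel contouring, identifies the tibial and
#' fibular contours from the seed points, and applies the same tubercle /
#' landmark constructions as the 3-D path.
#'
#' @param vol a [vox_vol()].
#' @param plane_y measurement plane from the 3-D pipeline.
#' @param seeds named list with `tibia` and `fibula` interior points (3-D mm;
#'   their in-plane projections identify the contours).
#' @param threshold_hu density threshold (150).
#' @param pitch_mm in-plane sampling pitch; defaults to the smallest voxel
#'   spacing.
#' @param subject,side identifiers for the output record.
#' @return one-row tibble (modality "2-D axial") with `TCS_A`, `TCS_P`,
#'   `IFD`; attribute `landmarks`.
#' @export
measure_axial_2d <- function(vol, plane_y, seeds, threshold_hu = 150,
                             pitch_mm = NULL, subject = NA_character_,
                             side = vol$side) {
  stopifnot(inherits(vol, "vox_vol"))
  lo <- vol$origin
  hi <- vol$origin + (dim(vol$values) - 1) * vol$spacing
  p0 <- plane_y$point
  if (any(p0 < lo) || any(p0 > hi))
    stop("measure_axial_2d: plane Y lies outside the volume")
  pitch <- pitch_mm %||% min(vol$spacing)
  frame <- plane_frame(plane_y)
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  cuv <- plane_to_2d(frame, corners)
  u <- seq(min(cuv[, 1]), max(cuv[, 1]), by = pitch)
  v <- seq(min(cuv[, 2]), max(cuv[, 2]), by = pitch)
  g <- as.matrix(expand.grid(u = u, v = v))
  hu <- matrix(trilinear_sample(vol, plane_to_3d(frame, g)), length(u), length(v))
  cts <- section_contours(u, v, hu, threshold_hu, frame)
  if (length(cts) == 0) stop("measure_axial_2d: no bone contour at plane Y")
  find_ct <- function(seed) {
    suv <- plane_to_2d(frame, matrix(seed, ncol = 3))
    hit <- vapply(cts, function(ct) points_in_polygon(suv, ct$uv), TRUE)
    if (!any(hit)) return(NULL)
    cts[hit][[which.max(vapply(cts[hit], function(ct) abs(polygon_area(ct$uv)), 0))]]
  }
  tib <- find_ct(seeds$tibia)
  fib <- find_ct(seeds$fibula)
  if (is.null(tib)) stop("measure_axial_2d: tibia contour not found at plane Y")
  if (is.null(fib)) stop("fibula not present at plane Y")
  tib$label <- "tibia"; fib$label <- "fibula"
  corner_a <- tubercle_corner(tib, "anterior")
  lk <- locate_landmarks(tib, fib, corner_a$point3d)
  rec <- measure_3d(lk, plane_y, plane_y, subject = subject, side = side)
  rec$modality <- "2-D axial"
  rec$XY <- NA_real_
  rec$IFH <- NA_real_
  attr(rec, "landmarks") <- lk
  rec
}
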