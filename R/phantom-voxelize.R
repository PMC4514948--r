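# Rasterization of the phantom surfaces into a CT-like volume.
#
# Each bone mesh is cut by every axial grid plane and scanline-filled with a
# partial-volume edge model: within every voxel row the covered fraction
# along x is computed exactly from the polygon crossings, and three sub-rows
# per voxel average the coverage in y. Voxel HU is interpolated between the
# soft-tissue and bone levels by that occupancy fraction, emulating the
# partial-volume effect at bone edges that real CT shows -- and what makes
# sub-voxel isosurface extraction meaningful downstream. Debris blobs are
# small spheres placed far (>= 5 mm) from any bone; noise is additive
# Gaussian, clipped at air (-1000 HU).

# Fractional x-coverage of each voxel cell of one row by the crossing
# intervals of `poly` rows at scanline y.
row_coverage <- function(polys, y, xs, dx) {
  cov <- numeric(length(xs))
  xl <- xs - dx / 2
  for (poly in polys) {
    m <- nrow(poly)
    x1 <- poly[, 1]; y1 <- poly[, 2]
    x2 <- poly[c(2:m, 1), 1]; y2 <- poly[c(2:m, 1), 2]
    cr <- (y1 > y) != (y2 > y)
    if (!any(cr)) next
    xc <- sort(x1[cr] + (y - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    k <- 1L
    while (k + 1L <= length(xc)) {
      a <- xc[k]; b <- xc[k + 1L]
      i0 <- max(1L, floor((a - xl[1]) / dx) + 1L)
      i1 <- min(length(xs), floor((b - xl[1]) / dx) + 1L)
      if (i1 >= i0) {
        idx <- i0:i1
        lo <- pmax(a, xl[idx])
        hi <- pmin(b, xl[idx] + dx)
        cov[idx] <- cov[idx] + pmax(0, hi - lo) / dx
      }
      k <- k + 2L
    }
  }
  pmin(cov, 1)
}

slice_coverage <- function(polys, xs, ys, n_sub = 3) {
  cov <- matrix(0, length(xs), length(ys))
  dx <- xs[2] - xs[1]
  dy <- ys[2] - ys[1]
  offs <- (seq_len(n_sub) - (n_sub + 1) / 2) / n_sub * dy
  yr <- range(unlist(lapply(polys, function(p) range(p[, 2]))))
  jset <- which(ys > yr[1] - dy & ys < yr[2] + dy)
  for (j in jset) {
    acc <- 0
    for (o in offs) acc <- acc + row_coverage(polys, ys[j] + o, xs, dx)
    cov[, j] <- acc / n_sub
  }
  cov
}

debris_positions <- function(n, an) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  i <- seq_len(n) - 1L
  cbind(-15 + 7 * (i %% 6L), an$debris_y, -10 + 9 * (i %/% 6L))
}

voxelize_phantom <- function(spec, surfaces, an) {
  sp <- spec$voxel_spacing_mm
  allv <- do.call(rbind, lapply(surfaces, function(s) s$vertices))
  lo <- apply(allv, 2, min) - 3
  hi <- apply(allv, 2, max) + 3
  deb <- debris_positions(spec$n_debris, an)
  r_d <- (3 * spec$debris_volume_mm3 / (4 * pi))^(1 / 3)
  if (nrow(deb) > 0) {
    Tr <- phantom_transform(spec)
    deb <- deb %*% t(Tr)
    lo <- pmin(lo, apply(deb, 2, min) - r_d - 3)
    hi <- pmax(hi, apply(deb, 2, max) + r_d + 3)
  }
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * sp[1]
  ys <- lo[2] + (seq_len(dims[2]) - 1) * sp[2]
  zs <- lo[3] + (seq_len(dims[3]) - 1) * sp[3]

  frac <- array(0, dim = dims)
  for (s in surfaces) {
    zr <- range(s$vertices[, 3])
    for (k in which(zs > zr[1] & zs < zr[2])) {
      polys <- mesh_slice_3d(s, anatomic_plane(c(0, 0, zs[k]), c(0, 0, 1)))
      if (length(polys) == 0) next
      polys2d <- lapply(polys, function(p) p[, 1:2, drop = FALSE])
      frac[, , k] <- pmin(1, frac[, , k] + slice_coverage(polys2d, xs, ys))
    }
  }
  if (nrow(deb) > 0) {
    for (q in seq_len(nrow(deb))) {
      ix <- which(abs(xs - deb[q, 1]) <= r_d)
      iy <- which(abs(ys - deb[q, 2]) <= r_d)
      iz <- which(abs(zs - deb[q, 3]) <= r_d)
      if (!length(ix) || !length(iy) || !length(iz)) next
      g <- expand.grid(i = ix, j = iy, k = iz)
      d2 <- (xs[g$i] - deb[q, 1])^2 + (ys[g$j] - deb[q, 2])^2 + (zs[g$k] - deb[q, 3])^2
      hit <- g[d2 <= r_d^2, ]
      frac[cbind(hit$i, hit$j, hit$k)] <- 1
    }
  }
  vals <- spec$soft_tissue_hu + (spec$bone_hu - spec$soft_tissue_hu) * frac
  if (spec$noise_sd_hu > 0) {
    set.seed(spec$seed)
    vals <- vals + stats::rnorm(length(vals), sd = spec$noise_sd_hu)
    vals <- pmax(vals, -1000)
    dim(vals) <- dims
  }
  vox_vol(vals, sp, origin = lo, side = spec$side)
}
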