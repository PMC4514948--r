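test_that("plafond plane fit recovers flat and tilted plafonds", {
  ph <- male_mesh()
  px <- fit_plafond_plane(ph$surfaces$tibia, c(0, 0, 0))
  expect_lt(sum(abs(px$normal - c(0, 0, 1))), 1e-6)

  tilted <- generate_phantom(phantom_preset("male", plafond_tilt_deg = c(5, 3)),
                             voxelize = FALSE, detail = 0.5)
  px_t <- fit_plafond_plane(tilted$surfaces$tibia, tilted$truth$plane_x$point)
  ang <- acos(min(1, abs(sum(px_t$normal * tilted$truth$plane_x$normal)))) * 180 / pi
  expect_lt(ang, 0.5)

  tiny <- syndesmo3d:::ellipsoid_surface(c(0, 0, 0), c(3, 3, 3), 6, 3)
  expect_error(fit_plafond_plane(tiny, c(0, 0, -3)), "articular patch too small")
})

test_that("plane slicing returns exact circles and filters tangent slivers", {
  sph <- sphere_mesh(10)
  cts <- slice_contours(sph, anatomic_plane(c(0, 0, 0), c(0, 0, 1)))
  r <- sqrt(rowSums(cts[[1]]$uv^2))
  expect_lt(max(abs(r - 10)) / 10, 0.01)
  # through z = 5 the section radius is sqrt(75)
  cts5 <- slice_contours(sph, anatomic_plane(c(0, 0, 5), c(0, 0, 1)))
  expect_lt(max(abs(sqrt(rowSums(cts5[[1]]$uv^2)) - sqrt(75))) / sqrt(75), 0.01)
  # tangent plane: degenerate contour filtered, empty result with warning
  expect_warning(out <- slice_contours(sph, anatomic_plane(c(0, 0, 9.9999),
                                                           c(0, 0, 1))),
                 "intersects no surface")
  expect_length(out, 0)
})

test_that("tubercle corners: notched rectangle recovered exactly, with mirror symmetry", {
  ct <- axial_contour(notched_rectangle())
  expect_equal(tubercle_corner(ct, "anterior")$point, c(7, 4))
  expect_equal(tubercle_corner(ct, "posterior")$point, c(3, 4))
  # mirroring across the u axis swaps anterior and posterior (phantom contour,
  # whose notch ends differ in v)
  rec <- male_mesh_rec()
  cts <- slice_contours(male_mesh()$surfaces$tibia, attr(rec, "plane_y"))
  tib <- cts[[1]]
  ant <- tubercle_corner(tib, "anterior")$point
  mir <- tib
  mir$uv <- (tib$uv %*% diag(c(1, -1)))[rev(seq_len(nrow(tib$uv))), ]
  post_m <- tubercle_corner(mir, "posterior")$point
  expect_equal(post_m, ant * c(1, -1), tolerance = 1e-9)
  # convex contour: no incisura
  circle <- axial_contour(cbind(cos(seq(0, 2 * pi, length.out = 60)[-60]),
                                sin(seq(0, 2 * pi, length.out = 60)[-60])) * 5)
  expect_error(tubercle_corner(circle, "anterior"), "no incisura")
})

test_that("point A maximizes incisura depth; refinement agrees with exhaustive scan", {
  ph <- male_mesh()
  px <- fit_plafond_plane(ph$surfaces$tibia, c(0, 0, 0))
  coarse <- locate_point_A(ph$surfaces$tibia, px, refine = FALSE)
  expect_lt(abs(coarse$z_star - 12.1), 0.625)
  fine <- locate_point_A(ph$surfaces$tibia, px, step_mm = 0.1, refine = FALSE)
  expect_lt(abs(fine$z_star - coarse$z_star), 0.625)
  refined <- locate_point_A(ph$surfaces$tibia, px)
  expect_lt(abs(refined$z_star - 12.1), 1e-6)
  # female phantom: the level lands at its own group mean, not the male one
  phf <- female_mesh()
  pxf <- fit_plafond_plane(phf$surfaces$tibia, c(0, 0, 0))
  expect_lt(abs(locate_point_A(phf$surfaces$tibia, pxf)$z_star - 7.8), 1e-6)
})

test_that("plane Y construction: parallelism, zero height, and below-plane error", {
  px <- anatomic_plane(c(0, 0, 0), c(0, 0, 1))
  on_plane <- build_plane_Y(px, c(5, 3, 0))
  expect_identical(on_plane$xy_mm, 0)
  expect_error(build_plane_Y(px, c(0, 0, -2)), "below plane X")
  py <- build_plane_Y(px, c(1, 2, 7))
  expect_identical(py$plane_y$normal, px$normal)
  expect_equal(py$xy_mm, 7)
})

test_that("landmarks match dense brute-force search within 0.05 mm", {
  ph <- male_mesh()
  rec <- male_mesh_rec()
  lk <- attr(rec, "landmarks")
  py <- attr(rec, "plane_y")
  cts <- slice_contours(ph$surfaces[c("tibia", "fibula")], py)
  tib <- syndesmo3d:::contour_by_label(cts, "tibia")
  fib <- syndesmo3d:::contour_by_label(cts, "fibula")
  resample <- function(uv, step = 0.01) {
    m <- nrow(uv)
    out <- vector("list", m)
    for (i in seq_len(m)) {
      a <- uv[i, ]; b <- uv[if (i == m) 1 else i + 1, ]
      L <- sqrt(sum((b - a)^2))
      t <- seq(0, 1, length.out = max(2, ceiling(L / step) + 1))
      t <- t[-length(t)]
      out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    }
    do.call(rbind, out)
  }
  fib_dense <- resample(fib$uv)
  A2 <- lk$uv$A
  C2 <- lk$uv$C
  bf_B <- fib_dense[which.min((fib_dense[, 1] - A2[1])^2 + (fib_dense[, 2] - A2[2])^2), ]
  bf_D <- fib_dense[which.min((fib_dense[, 1] - C2[1])^2 + (fib_dense[, 2] - C2[2])^2), ]
  expect_lt(sqrt(sum((bf_B - lk$uv$B)^2)), 0.05)
  expect_lt(sqrt(sum((bf_D - lk$uv$D)^2)), 0.05)
  # E by brute force: densely resample the contour arc between A and C that
  # runs through the notch (the shorter way), take the point at maximal
  # perpendicular distance from line AC
  m <- nrow(tib$uv)
  iA <- which.min(rowSums(sweep(tib$uv, 2, A2)^2))
  iC <- which.min(rowSums(sweep(tib$uv, 2, C2)^2))
  fwd <- if (iC >= iA) iA:iC else c(iA:m, 1:iC)
  bwd <- if (iA >= iC) iC:iA else c(iC:m, 1:iA)
  arc_idx <- if (length(fwd) <= length(bwd)) fwd else bwd
  arc_dense <- resample(tib$uv[arc_idx, , drop = FALSE])
  sg <- abs(syndesmo3d:::signed_line_distance(arc_dense, A2, C2))
  bf_E <- arc_dense[which.max(sg), ]
  expect_lt(sqrt(sum((bf_E - lk$uv$E)^2)), 0.05)
})

test_that("a circular fibula puts B on the segment from A to the centre", {
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  centre <- c(20, -3)
  fib <- axial_contour(cbind(centre[1] + 6 * cos(th), centre[2] + 6 * sin(th)),
                       label = "fibula")
  tib <- axial_contour(notched_rectangle() %*% diag(c(1, 1)) - 12, label = "tibia")
  A <- c(-5, -8, 0)   # 2-D (-5, -8) in the axial frame
  lk <- locate_landmarks(tib, fib, A)
  # B lies on the segment from A to the circle centre (up to the polygonal
  # approximation of the circle, edge length ~0.16 mm)
  d <- syndesmo3d:::point_segment_distance(matrix(lk$uv$B, ncol = 2),
                                           lk$uv$A, centre)$d
  expect_lt(d, 0.08)
  expect_equal(sqrt(sum((lk$uv$B - centre)^2)), 6, tolerance = 1e-3)
  expect_error(locate_landmarks(tib, NULL, A), "fibula not present")
})

test_that("3-D measures: collinear A, C, E give IFD zero; heights are signed", {
  lk <- structure(list(A = c(0, 0, 5), B = c(1, 0, 5), C = c(4, 0, 5),
                       D = c(4, 1, 5), E = c(2, 0, 5),
                       uv = NULL, frame = NULL), class = "landmark_set")
  px <- anatomic_plane(c(0, 0, 0), c(0, 0, 1))
  py <- anatomic_plane(c(0, 0, 5), c(0, 0, 1))
  rec <- measure_3d(lk, px, py, F_point = c(0, 0, 30))
  expect_equal(rec$IFD, 0)
  expect_equal(rec$TCS_A, 1)
  expect_equal(rec$TCS_P, 1)
  expect_equal(rec$XY, 5)
  expect_equal(rec$IFH, 30)
})

test_that("point F tracking: step halving tightens the unrefined error bound", {
  ph <- male_mesh()
  rec <- male_mesh_rec()
  px <- attr(rec, "plane_x")
  py <- attr(rec, "plane_y")
  f1 <- locate_point_F(ph$surfaces$tibia, px, py, step_mm = 0.5, refine = FALSE)
  f2 <- locate_point_F(ph$surfaces$tibia, px, py, step_mm = 1, refine = FALSE)
  expect_lte(abs(f1$height_mm - 35.1), 0.5 + 1e-9)
  expect_lte(abs(f2$height_mm - 35.1), 1 + 1e-9)
  expect_lt(abs(locate_point_F(ph$surfaces$tibia, px, py)$height_mm - 35.1), 1e-6)
})

test_that("trilinear resampling reproduces an axial slice at a slice centre exactly", {
  ph <- male_vox()
  vol <- ph$volume
  k <- 40
  z <- vol$origin[3] + (k - 1) * vol$spacing[3]
  pts <- cbind(syndesmo3d:::vox_axis(vol, 1)[10:40],
               vol$origin[2] + 20 * vol$spacing[2], z)
  expect_equal(syndesmo3d:::trilinear_sample(vol, pts),
               vol$values[10:40, 21, k], tolerance = 1e-12)
})

test_that("every parameter is invariant under rigid motion (mesh path, 1e-6)", {
  ph <- male_mesh()
  rec0 <- male_mesh_rec()
  set.seed(11)
  for (i in 1:3) {
    R <- rotation_matrix(stats::rnorm(3), stats::runif(1, -15, 15))
    tr <- stats::runif(3, -40, 40)
    surf <- lapply(ph$surfaces, mesh_transform, rotation = R, translation = tr)
    seed <- as.numeric(R %*% c(0, 0, 0) + tr)
    rec <- measure_surfaces(surf, seed, radiograph = FALSE)
    d <- c(rec$XY - rec0$XY[1], rec$TCS_A - rec0$TCS_A[1],
           rec$TCS_P - rec0$TCS_P[1], rec$IFD - rec0$IFD[1],
           rec$IFH - rec0$IFH[1])
    expect_lt(max(abs(d)), 1e-6)
  }
})

test_that("scaling the geometry scales every parameter linearly", {
  ph <- male_mesh()
  rec0 <- male_mesh_rec()
  s <- 1.7
  surfs <- lapply(ph$surfaces, mesh_transform, rotation = diag(3) * s)
  px <- fit_plafond_plane(surfs$tibia, c(2 * s, 0, 0))
  pa <- locate_point_A(surfs$tibia, px, window_mm = c(4, 20) * s,
                       notch_min_depth = 0.5 * s)
  py <- build_plane_Y(px, pa$point)
  cts <- slice_contours(surfs[c("tibia", "fibula")], py$plane_y)
  lk <- locate_landmarks(syndesmo3d:::contour_by_label(cts, "tibia"),
                         syndesmo3d:::contour_by_label(cts, "fibula"),
                         pa$point, notch_min_depth = 0.5 * s)
  ptF <- locate_point_F(surfs$tibia, px, py$plane_y, notch_min_depth = 0.5 * s)
  rec <- measure_3d(lk, px, py$plane_y, F_point = ptF$point)
  d <- c(rec$XY - s * rec0$XY[1], rec$TCS_A - s * rec0$TCS_A[1],
         rec$TCS_P - s * rec0$TCS_P[1], rec$IFD - s * rec0$IFD[1],
         rec$IFH - s * rec0$IFH[1])
  expect_lt(max(abs(d)), 1e-6)
})

test_that("mesh-path recovery stays below 0.5 mm over random feasible phantoms", {
  n_ok <- 0L
  worst <- 0
  for (i in 1:100) {
    spec <- phantom_random(seed = 1000 + i)
    ph <- generate_phantom(spec, voxelize = FALSE, detail = 0.4)
    rec <- measure_surfaces(ph$surfaces, c(0, 0, 0))
    errs <- recovery_errors(rec, ph$truth)
    expect_true(all(rec$XY[1] >= 0, rec$TCS_A[1] >= 0, rec$TCS_P[1] >= 0,
                    rec$IFD[1] >= 0, rec$IFH[1] >= 0, rec$TFO[2] >= 0))
    worst <- max(worst, max(abs(errs)))
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 100L)
  expect_lt(worst, 0.5)
})
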