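test_that("orthographic projection of a sphere is a circle of equal radius", {
  sil <- project_ap(list(sphere_mesh(10)))
  tb <- sil$bones[[1]]
  ok <- is.finite(tb$x_min)
  widths <- tb$x_max[ok] - tb$x_min[ok]
  expect_lt(abs(max(widths) - 20) / 20, 0.01)
  # width at height z follows the circle equation
  at5 <- which.min(abs(tb$z - 5))
  expect_lt(abs((tb$x_max[at5] - tb$x_min[at5]) - 2 * sqrt(75)) / (2 * sqrt(75)), 0.02)
})

test_that("radiographic borders respond exactly to a lateral fibular shift", {
  ph <- male_mesh()
  rec <- male_mesh_rec()
  h <- rec$XY[1]
  pl <- project_plane_line(attr(rec, "plane_x"))
  sil0 <- project_ap(ph$surfaces[c("tibia", "fibula")])
  r0 <- measure_radiograph(sil0, h, pl)
  shifted <- ph$surfaces
  shifted$fibula <- mesh_transform(shifted$fibula, translation = c(1, 0, 0))
  r1 <- measure_radiograph(project_ap(shifted[c("tibia", "fibula")]), h, pl)
  expect_equal(r1$TCS - r0$TCS, 1, tolerance = 1e-9)
  expect_equal(r1$TFO - r0$TFO, -1, tolerance = 1e-9)
})

test_that("radiographic measurements are invariant under in-plane translation", {
  ph <- male_mesh()
  rec <- male_mesh_rec()
  h <- rec$XY[1]
  px <- attr(rec, "plane_x")
  r0 <- measure_radiograph(project_ap(ph$surfaces[c("tibia", "fibula")]), h,
                           project_plane_line(px))
  tr <- c(13.5, 0, -7.25)
  moved <- lapply(ph$surfaces[c("tibia", "fibula")], mesh_transform,
                  translation = tr)
  px_m <- anatomic_plane(px$point + tr, px$normal)
  r1 <- measure_radiograph(project_ap(moved), h, project_plane_line(px_m))
  expect_equal(r1$TCS, r0$TCS, tolerance = 1e-9)
  expect_equal(r1$TFO, r0$TFO, tolerance = 1e-9)
  expect_equal(r1$IFH, r0$IFH, tolerance = 1e-3)
})

test_that("left/right phantoms give mirror-identical radiographic values", {
  pr <- generate_phantom(phantom_preset("male", seed = 1), voxelize = FALSE,
                         detail = 0.5)
  pl <- generate_phantom(phantom_preset("male", seed = 1, side = "left"),
                         voxelize = FALSE, detail = 0.5)
  rr <- measure_surfaces(pr$surfaces, c(0, 0, 0))
  rl <- measure_surfaces(pl$surfaces, c(0, 0, 0), side = "left")
  expect_equal(rl$TFO[2], rr$TFO[2], tolerance = 1e-9)
  expect_equal(rl$TCS[2], rr$TCS[2], tolerance = 1e-9)
})

test_that("projected fibula overlaps the anterior tubercle iff TFO > 0", {
  ph <- male_mesh()
  rec <- male_mesh_rec()
  h <- rec$XY[1]
  sil <- project_ap(ph$surfaces[c("tibia", "fibula")])
  z <- ph$truth$plane_y$point[3]
  fib_med <- syndesmo3d:::sil_at(sil$bones$fibula, "x_min", z)
  tib_lat <- syndesmo3d:::sil_at(sil$bones$tibia, "x_max", z)
  expect_gt(tib_lat - fib_med, 0)       # tfo_true 5.5 > 0
  expect_equal(tib_lat - fib_med, 5.5, tolerance = 1e-6)
})

test_that("zero-tilt TCS and TFO agree with a dense ray-casting oracle", {
  ph <- male_mesh()
  rec <- male_mesh_rec()
  h <- rec$XY[1]
  r0 <- rec[rec$modality == "radiograph", ]
  # oracle: dense point raster of the cross-section at the scan height,
  # windowed +-3 mm around each border
  z <- h + attr(rec, "plane_x")$point[3]
  occupied_x <- function(surf, x_window, y_max = Inf) {
    polys <- syndesmo3d:::mesh_slice_3d(surf, anatomic_plane(c(0, 0, z), c(0, 0, 1)))
    xg <- seq(x_window[1], x_window[2], by = 0.01)
    occ <- rep(FALSE, length(xg))
    for (p in polys) {
      ys <- seq(min(p[, 2]), min(y_max, max(p[, 2])), by = 0.05)
      if (length(ys) == 0) next
      g <- cbind(rep(xg, each = length(ys)), rep(ys, length(xg)))
      hit <- syndesmo3d:::points_in_polygon(g, p[, 1:2])
      occ <- occ | colSums(matrix(hit, length(ys))) > 0
    }
    xg[occ]
  }
  sil <- project_ap(ph$surfaces[c("tibia", "fibula")])
  fm <- syndesmo3d:::sil_at(sil$bones$fibula, "x_min", z)
  tl <- syndesmo3d:::sil_at(sil$bones$tibia, "x_max", z)
  tp <- syndesmo3d:::sil_at(sil$bones$tibia, "x_post", z)
  fib_x <- occupied_x(ph$surfaces$fibula, fm + c(-3, 3))
  tib_x <- occupied_x(ph$surfaces$tibia, tl + c(-3, 3))
  tib_post_x <- occupied_x(ph$surfaces$tibia, tp + c(-3, 3), y_max = 0)
  tcs_oracle <- min(fib_x) - max(tib_post_x)
  tfo_oracle <- max(tib_x) - min(fib_x)
  expect_lt(abs(r0$TCS - tcs_oracle), 0.2)
  expect_lt(abs(r0$TFO - tfo_oracle), 0.2)
})

test_that("projection foreshortening lowers radiographic IFH below 3-D IFH on tilt", {
  tilted <- generate_phantom(phantom_preset("male", plafond_tilt_deg = c(6, 4)),
                             voxelize = FALSE, detail = 0.5)
  rec <- measure_surfaces(tilted$surfaces, tilted$truth$plane_x$point)
  expect_lt(rec$IFH[rec$modality == "radiograph"],
            rec$IFH[rec$modality == "3-D"])
})
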