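test_that("phantom truth echoes the specification and presets carry the group means", {
  spec <- phantom_preset("male", seed = 1)
  tr <- male_mesh()$truth
  expect_identical(tr$xy, spec$xy_true_mm)
  expect_identical(tr$tcsa, 2.8)
  expect_identical(tr$tcsp, 3.6)
  expect_identical(tr$ifd, 5.1)
  expect_identical(tr$ifh, 35.1)
  expect_identical(tr$tfo, 5.5)
  fem <- phantom_preset("female")
  expect_equal(c(fem$xy_true_mm, fem$tcsa_true_mm, fem$tcsp_true_mm,
                 fem$ifd_true_mm, fem$ifh_true_mm, fem$tfo_true_mm),
               c(7.8, 1.8, 2.9, 4.2, 33.7, 3.8))
  vals <- phantom_truth_values(tr)
  expect_true(all(c("parameter", "modality", "value_mm") %in% names(vals)))
})

test_that("truth values are mutually consistent", {
  tr <- male_mesh()$truth
  expect_equal(syndesmo3d::plane_distance(tr$plane_x, tr$plane_y$point)[1],
               tr$xy, tolerance = 1e-12)
  expect_equal(sqrt(sum((tr$A - tr$B)^2)), tr$tcsa, tolerance = 1e-9)
  expect_equal(sqrt(sum((tr$C - tr$D)^2)), tr$tcsp, tolerance = 1e-9)
  ac <- tr$C - tr$A
  w <- tr$E - tr$A
  expect_equal(sqrt(sum((w - sum(w * ac) / sum(ac^2) * ac)^2)), tr$ifd,
               tolerance = 1e-9)
  expect_equal(plane_distance(tr$plane_x, tr$F)[1], tr$ifh, tolerance = 1e-12)
})

test_that("measuring the analytic surfaces recovers every truth value to 1e-6 mm", {
  expect_lt(max(abs(recovery_errors(male_mesh_rec(), male_mesh()$truth))), 1e-6)
  expect_lt(max(abs(recovery_errors(female_mesh_rec(), female_mesh()$truth))), 1e-6)
})

test_that("generation is deterministic and noise is confined to the noise field", {
  spec_a <- phantom_preset("male", seed = 5)
  spec_b <- phantom_preset("male", seed = 99)
  pa <- generate_phantom(spec_a, voxelize = FALSE, detail = 0.3)
  pb <- generate_phantom(spec_b, voxelize = FALSE, detail = 0.3)
  expect_identical(pa$surfaces$tibia$vertices, pb$surfaces$tibia$vertices)

  va <- generate_phantom(phantom_preset("male", seed = 5, noise_sd_hu = 20,
                                        voxel_spacing_mm = rep(2, 3)))$volume
  va2 <- generate_phantom(phantom_preset("male", seed = 5, noise_sd_hu = 20,
                                         voxel_spacing_mm = rep(2, 3)))$volume
  vb <- generate_phantom(phantom_preset("male", seed = 6, noise_sd_hu = 20,
                                        voxel_spacing_mm = rep(2, 3)))$volume
  expect_identical(va$values, va2$values)
  expect_false(identical(va$values, vb$values))
  # the noise-free rasterization underneath is the same field
  v0 <- generate_phantom(phantom_preset("male", seed = 5,
                                        voxel_spacing_mm = rep(2, 3)))$volume
  expect_lt(max(abs((va$values - v0$values))), 20 * 6)   # pure noise, ~N(0, 20)
})

test_that("a left-side phantom is the exact sagittal mirror of the right side", {
  pr <- generate_phantom(phantom_preset("male", seed = 1), voxelize = FALSE,
                         detail = 0.3)
  pl <- generate_phantom(phantom_preset("male", seed = 1, side = "left"),
                         voxelize = FALSE, detail = 0.3)
  vm <- pr$surfaces$tibia$vertices %*% diag(c(-1, 1, 1))
  expect_equal(pl$surfaces$tibia$vertices, vm, tolerance = 1e-12)
  expect_equal(pl$truth$A, pr$truth$A * c(-1, 1, 1), tolerance = 1e-12)
  rec <- measure_surfaces(pl$surfaces, c(0, 0, 0), side = "left")
  expect_lt(max(abs(recovery_errors(rec, pr$truth))), 1e-6)
  expect_identical(rec$side[1], "left")
})

test_that("infeasible parameter combinations raise explicit errors, not clipping", {
  expect_error(generate_phantom(phantom_preset("male", tfo_true_mm = 18),
                                voxelize = FALSE, detail = 0.3),
               "infeasible")
  expect_error(phantom_preset("male", ifd_true_mm = 1), "ifd_true_mm")
  expect_error(phantom_preset("male", debris_volume_mm3 = 600), "debris")
  expect_error(phantom_preset("male", ifh_true_mm = 14), "ifh_true_mm")
  expect_error(phantom_preset("male", bone_hu = 120), "bone_hu")
})

test_that("rater-table simulation realizes its variance components and is reproducible", {
  rs <- rater_sim_spec(500, 3, subject_sd = 1, rater_sd = 0.3, error_sd = 0.4,
                       seed = 5)
  tab <- simulate_rater_table(rs)
  r <- attr(tab, "rater_effects")
  expect_equal(stats::sd(r), 0.3, tolerance = 1e-10)
  expect_equal(stats::sd(attr(tab, "mu")), 1, tolerance = 1e-10)
  m <- rater_matrix(tab)
  # moment recovery on the realized table
  expect_lt(abs(stats::sd(rowMeans(m)) - 1) / 1, 0.15)
  resid <- m - rowMeans(m)[row(m)] - rep(colMeans(m), each = nrow(m)) + mean(m)
  expect_lt(abs(sqrt(sum(resid^2) / ((nrow(m) - 1) * (ncol(m) - 1))) - 0.4) / 0.4, 0.15)
  expect_identical(simulate_rater_table(rs), tab)

  exact <- simulate_rater_table(rater_sim_spec(20, 3, subject_sd = 1,
                                               rater_sd = 0, error_sd = 0,
                                               seed = 2))
  em <- rater_matrix(exact)
  expect_equal(em[, 1], em[, 2], tolerance = 1e-12)
  expect_equal(icc_2_1(em)$icc, 1)
})
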