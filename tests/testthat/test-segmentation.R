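test_that("threshold is >= with exact boundary inclusion and warns on empty masks", {
  v <- vox_vol(array(40, c(4, 4, 4)), c(1, 1, 1))
  expect_warning(m <- threshold_bone(v), "empty mask")
  expect_false(any(m))

  vb <- vox_vol(array(c(149.999, 150, 150.001, 40), c(4, 1, 1)), c(1, 1, 1))
  mb <- threshold_bone(vb)
  expect_identical(as.vector(mb), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("male phantom mask volume matches the analytic bone volumes within 5%", {
  ph <- male_vox()
  mask <- threshold_bone(ph$volume)
  mask <- remove_small_components(mask)
  vox_mm3 <- sum(mask) * prod(ph$volume$spacing)
  true_mm3 <- sum(vapply(ph$surfaces, mesh_volume, 0))
  expect_lt(abs(vox_mm3 / true_mm3 - 1), 0.05)
})

test_that("small-component removal removes exactly the debris, strictly below 500 mm^3", {
  ph <- male_vox()                       # 10 debris x 100 mm^3
  mask <- threshold_bone(ph$volume)
  lab_before <- syndesmo3d:::label_components_26(mask)
  cleaned <- remove_small_components(mask)
  lab_after <- syndesmo3d:::label_components_26(cleaned)
  expect_identical(max(lab_before), 13L)
  expect_identical(max(lab_after), 3L)
  # bone voxels untouched: every removed voxel belonged to a small component
  sizes <- tabulate(lab_before[lab_before > 0])
  big <- which(sizes * prod(ph$volume$spacing) >= 500)
  expect_identical(sum(cleaned), sum(sizes[big]))
  # idempotence
  expect_identical(remove_small_components(cleaned), cleaned)
  # volume conservation: never increases the voxel count
  expect_lte(sum(cleaned), sum(mask))
})

test_that("removal threshold conventions: identity at 0, strict < at the limit", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:11, 2:11, 2:6] <- TRUE             # 500 voxels at 1 mm^3 each
  attr(m, "spacing") <- c(1, 1, 1)
  expect_identical(remove_small_components(m, 0), m)
  expect_identical(sum(remove_small_components(m, 500)), 500L)  # 500 not < 500
  m499 <- m
  m499[2, 2, 2] <- FALSE                 # 499 mm^3
  expect_identical(sum(remove_small_components(m499, 500)), 0L)
})

test_that("isosurface extraction is sub-voxel accurate and closed", {
  vol <- graded_sphere_volume(10)
  surfs <- extract_surfaces(threshold_bone(vol), vol = vol)
  expect_length(surfs, 1)
  expect_true(surfs[[1]]$closed)
  expect_lt(abs(mesh_area(surfs[[1]]) / (4 * pi * 100) - 1), 0.03)
  expect_lt(abs(mesh_volume(surfs[[1]]) / (4 / 3 * pi * 1000) - 1), 0.03)

  m1 <- array(FALSE, c(3, 3, 3))
  m1[2, 2, 2] <- TRUE
  attr(m1, "spacing") <- c(1, 1, 1)
  attr(m1, "origin") <- c(0, 0, 0)
  s1 <- extract_surfaces(m1)
  expect_length(s1, 1)
  expect_gt(nrow(s1[[1]]$faces), 0)
  expect_true(s1[[1]]$closed)

  expect_error(extract_surfaces(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("the phantom yields three surfaces after debris removal, labeled by seeds", {
  ph <- male_vox()
  seeds <- phantom_seeds(ph)
  mask <- remove_small_components(threshold_bone(ph$volume))
  surfs <- extract_surfaces(mask, vol = ph$volume)
  expect_length(surfs, 3)
  labeled <- label_bones(surfs, seeds$interior)
  expect_setequal(vapply(labeled, function(s) s$label, ""),
                  c("tibia", "fibula", "talus"))
  # the operation trusts the seeds: swapping seeds swaps labels
  sw <- seeds$interior
  names(sw)[1:2] <- names(sw)[2:1]
  swapped <- label_bones(surfs, sw)
  i_tib <- which(vapply(labeled, function(s) s$label, "") == "tibia")
  expect_identical(swapped[[i_tib]]$label, "fibula")

  expect_error(label_bones(surfs, list(tibia = c(500, 500, 500))), "no surface")
  expect_error(label_bones(surfs, list(a = seeds$interior$tibia,
                                       b = seeds$interior$tibia)),
               "same surface")
})

test_that("end-to-end segmentation reproduces the generator tibia within one voxel", {
  ph <- male_vox()
  seeds <- phantom_seeds(ph)
  bones <- segment_volume(ph$volume, seeds$interior)
  ext <- bones$tibia
  gen <- ph$surfaces$tibia
  sample_dist <- function(from, to, n = 120) {
    set.seed(4)
    v <- from$vertices
    v <- v[v[, 3] > 2 & v[, 3] < 34, , drop = FALSE]   # away from the caps
    v <- v[sample(nrow(v), n), , drop = FALSE]
    vapply(seq_len(n), function(i) {
      ct <- syndesmo3d:::mesh_slice_3d(to, anatomic_plane(c(0, 0, v[i, 3]),
                                                          c(0, 0, 1)))
      min(vapply(ct, function(p)
        syndesmo3d:::nearest_on_polyline(p[, 1:2], v[i, 1:2])$dist, 0))
    }, 0)
  }
  expect_lt(max(sample_dist(ext, gen)), 0.625)
  expect_lt(max(sample_dist(gen, ext)), 0.625)
})
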