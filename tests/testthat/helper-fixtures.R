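# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# Reference phantoms whose truth is set to the published male / female group
# means (mesh path, full detail).
male_mesh <- function() fixture("male_mesh", function()
  generate_phantom(phantom_preset("male", seed = 1), voxelize = FALSE))
female_mesh <- function() fixture("female_mesh", function()
  generate_phantom(phantom_preset("female", seed = 2), voxelize = FALSE))

male_mesh_rec <- function() fixture("male_mesh_rec", function()
  measure_surfaces(male_mesh()$surfaces, c(0, 0, 0), subject = "male_ref"))
female_mesh_rec <- function() fixture("female_mesh_rec", function()
  measure_surfaces(female_mesh()$surfaces, c(0, 0, 0), subject = "female_ref"))

# The same phantoms voxelized at 0.625 mm with 10 debris blobs of 100 mm^3.
male_vox <- function() fixture("male_vox", function()
  generate_phantom(phantom_preset("male", seed = 1, n_debris = 10,
                                  debris_volume_mm3 = 100)))
female_vox <- function() fixture("female_vox", function()
  generate_phantom(phantom_preset("female", seed = 2, n_debris = 10,
                                  debris_volume_mm3 = 100)))

vox_rec <- function(ph, subject) {
  seeds <- phantom_seeds(ph)
  measure_volume(ph$volume, seeds$interior, seeds$articular, subject = subject)
}
male_vox_rec <- function() fixture("male_vox_rec", function()
  vox_rec(male_vox(), "male_vox"))
female_vox_rec <- function() fixture("female_vox_rec", function()
  vox_rec(female_vox(), "female_vox"))

# Per-modality parameter errors of a measurement record against truth.
recovery_errors <- function(rec, truth) {
  r3 <- rec[rec$modality == "3-D", ]
  rx <- rec[rec$modality == "radiograph", ]
  out <- c(XY = r3$XY - truth$xy, TCS_A = r3$TCS_A - truth$tcsa,
           TCS_P = r3$TCS_P - truth$tcsp, IFD = r3$IFD - truth$ifd,
           IFH = r3$IFH - truth$ifh)
  if (nrow(rx)) out <- c(out, TFO = rx$TFO - truth$tfo)
  out
}

# Planar contour from a raw polygon in the canonical axial frame.
axial_contour <- function(uv, label = "") {
  frame <- syndesmo3d:::plane_frame(anatomic_plane(c(0, 0, 0), c(0, 0, 1)))
  syndesmo3d:::new_contour(uv, frame, label = label)
}

# Rectangle with a rectangular notch cut into its +v edge.
notched_rectangle <- function() {
  rbind(c(0, 0), c(10, 0), c(10, 4), c(7, 4), c(7, 2), c(3, 2), c(3, 4), c(0, 4))
}

sphere_mesh <- function(r = 10, n_u = 96, n_v = 48)
  syndesmo3d:::ellipsoid_surface(c(0, 0, 0), c(r, r, r), n_u, n_v, label = "sphere")

# CT-like volume of a sphere with a graded (partial-volume-like) edge whose
# 150 HU level sits exactly at radius r.
graded_sphere_volume <- function(r = 10, spacing = 0.625) {
  xs <- seq(-r - 3, r + 3, by = spacing)
  g <- expand.grid(x = xs, y = xs, z = xs)
  d <- sqrt(g$x^2 + g$y^2 + g$z^2)
  vox_vol(array(150 - 300 * (d - r), rep(length(xs), 3)), rep(spacing, 3),
          origin = rep(-r - 3, 3))
}
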