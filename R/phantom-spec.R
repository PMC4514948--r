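#' Phantom specification
#'
#' Parameters of the distal tibia / fibula / talus phantom. Every morphometric
#' truth value (`*_true_mm`) is realized exactly by the generated geometry, so
#' the phantom serves as analytic ground truth for the measurement pipeline.
#' Defaults are the male-group 3-D reference values; [phantom_preset()] gives
#' both sexes.
#'
#' @param side "right" or "left". Left phantoms are exact sagittal mirrors.
#' @param voxel_spacing_mm positive length-3 voxel spacing; default 0.625 mm
#'   isotropic, matching a thin-slice CT protocol.
#' @param plafond_tilt_deg two angles (about +x and +y, degrees) tilting the
#'   plafond plane relative to the grid axial plane.
#' @param xy_true_mm height of point A (hence plane Y) above the plafond.
#' @param tcsa_true_mm,tcsp_true_mm anterior / posterior tibiofibular clear
#'   space in plane Y.
#' @param ifd_true_mm incisura depth in plane Y.
#' @param ifh_true_mm height of the incisura's proximal tip above the plafond;
#'   must exceed `xy_true_mm + 5`.
#' @param tfo_true_mm tibiofibular overlap in the AP projection at plane-Y
#'   level.
#' @param bone_hu,soft_tissue_hu density levels (HU); bone must be above and
#'   soft tissue below the 150 HU segmentation threshold.
#' @param noise_sd_hu SD of additive Gaussian noise (HU), clipped at -1000.
#' @param n_debris number of spurious small components.
#' @param debris_volume_mm3 per-component debris volume; must be < 500.
#' @param seed integer RNG seed for noise and debris jitter.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_preset("male")
#' spec$xy_true_mm
#' @export
phantom_spec <- function(side = "right",
                         voxel_spacing_mm = c(0.625, 0.625, 0.625),
                         plafond_tilt_deg = c(0, 0),
                         xy_true_mm = 12.1,
                         tcsa_true_mm = 2.8,
                         tcsp_true_mm = 3.6,
                         ifd_true_mm = 5.1,
                         ifh_true_mm = 35.1,
                         tfo_true_mm = 5.5,
                         bone_hu = 700,
                         soft_tissue_hu = 40,
                         noise_sd_hu = 0,
                         n_debris = 0,
                         debris_volume_mm3 = 100,
                         seed = 1L) {
  spec <- list(side = side, voxel_spacing_mm = as.numeric(voxel_spacing_mm),
               plafond_tilt_deg = as.numeric(plafond_tilt_deg),
               xy_true_mm = xy_true_mm, tcsa_true_mm = tcsa_true_mm,
               tcsp_true_mm = tcsp_true_mm, ifd_true_mm = ifd_true_mm,
               ifh_true_mm = ifh_true_mm, tfo_true_mm = tfo_true_mm,
               bone_hu = bone_hu, soft_tissue_hu = soft_tissue_hu,
               noise_sd_hu = noise_sd_hu, n_debris = as.integer(n_debris),
               debris_volume_mm3 = debris_volume_mm3, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (!spec$side %in% c("right", "left"))
    stop("phantom_spec: side must be 'right' or 'left'")
  if (length(spec$voxel_spacing_mm) != 3 || any(spec$voxel_spacing_mm <= 0))
    stop("phantom_spec: voxel_spacing_mm must be a positive triple")
  truths <- c(xy = spec$xy_true_mm, tcsa = spec$tcsa_true_mm,
              tcsp = spec$tcsp_true_mm, ifd = spec$ifd_true_mm,
              ifh = spec$ifh_true_mm, tfo = spec$tfo_true_mm)
  if (any(!is.finite(truths)) || any(truths <= 0))
    stop("phantom_spec: all *_true_mm must be positive")
  if (spec$ifh_true_mm <= spec$xy_true_mm + 8)
    stop("phantom_spec: ifh_true_mm must exceed xy_true_mm + 8 ",
         "(the incisura tip lies well above plane Y)")
  if (!(spec$bone_hu > 150 && 150 > spec$soft_tissue_hu))
    stop("phantom_spec: need bone_hu > 150 > soft_tissue_hu")
  if (spec$debris_volume_mm3 >= 500)
    stop("phantom_spec: debris_volume_mm3 must be < 500")
  if (spec$n_debris < 0) stop("phantom_spec: n_debris must be >= 0")
  if (spec$noise_sd_hu < 0) stop("phantom_spec: noise_sd_hu must be >= 0")
  if (spec$ifd_true_mm <= 3)
    stop("phantom_spec: ifd_true_mm must exceed 3 mm (the peaked depth ",
         "profile needs headroom above its closure run)")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %s side, spacing %.3f mm\n",
                     "  XY %.2f  TCS-A %.2f  TCS-P %.2f  IFD %.2f  IFH %.2f  TFO %.2f (mm)\n",
                     "  HU bone/soft %g/%g, noise sd %g, debris %d x %g mm^3, seed %d\n"),
              x$side, x$voxel_spacing_mm[1], x$xy_true_mm, x$tcsa_true_mm,
              x$tcsp_true_mm, x$ifd_true_mm, x$ifh_true_mm, x$tfo_true_mm,
              x$bone_hu, x$soft_tissue_hu, x$noise_sd_hu, x$n_debris,
              x$debris_volume_mm3, x$seed))
  invisible(x)
}

#' Reference phantom presets
#'
#' Sex-specific reference phantoms whose ground truth is set to the published
#' group means for the normal distal tibiofibular syndesmosis: male XY 12.1,
#' TCS-A 2.8, TCS-P 3.6, IFD 5.1, IFH 35.1, TFO 5.5 mm; female XY 7.8,
#' TCS-A 1.8, TCS-P 2.9, IFD 4.2, IFH 33.7, TFO 3.8 mm.
#'
#' @param preset "male" or "female".
#' @param ... overrides passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("male", "female"), ...) {
  preset <- match.arg(preset)
  args <- if (preset == "male") {
    list(xy_true_mm = 12.1, tcsa_true_mm = 2.8, tcsp_true_mm = 3.6,
         ifd_true_mm = 5.1, ifh_true_mm = 35.1, tfo_true_mm = 5.5)
  } else {
    list(xy_true_mm = 7.8, tcsa_true_mm = 1.8, tcsp_true_mm = 2.9,
         ifd_true_mm = 4.2, ifh_true_mm = 33.7, tfo_true_mm = 3.8)
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}

#' Draw a random feasible phantom specification
#'
#' Samples each morphometric parameter uniformly inside the published normal
#' ranges (male and female pooled) and rejection-samples into the feasible
#' region of the anatomy family (placement and clearance constraints), for
#' property sweeps. Within the ranges the draws are independent; normal
#' anatomical covariance between parameters is not documented, so none is
#' imposed beyond feasibility.
#'
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget.
#' @param ... overrides passed to [phantom_spec()].
#' @return a [phantom_spec()].
#' @export
phantom_random <- function(seed, max_tries = 25, ...) {
  over <- list(...)
  for (try_i in seq_len(max_tries)) {
    r <- withr_seed_runif(seed + 100003L * (try_i - 1L))
    args <- list(
      xy_true_mm = r(6.5, 15),
      tcsa_true_mm = r(1.5, 3.5),
      tcsp_true_mm = r(2.3, 4.3),
      ifd_true_mm = r(3.2, 6.3),
      ifh_true_mm = NA,
      tfo_true_mm = r(2.5, 7.5),
      seed = as.integer(seed))
    args$ifh_true_mm <- args$xy_true_mm + r(16, 26)
    args[names(over)] <- over
    spec <- try(do.call(phantom_spec, args), silent = TRUE)
    if (inherits(spec, "try-error")) next
    ok <- try(generate_phantom(spec, voxelize = FALSE, detail = 0.25),
              silent = TRUE)
    if (!inherits(ok, "try-error")) return(spec)
  }
  stop("phantom_random: no feasible draw within max_tries")
}

# Local uniform sampler that does not disturb the global RNG stream.
withr_seed_runif <- function(seed) {
  state <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  draws <- stats::runif(64)
  if (is.null(state)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", state, envir = globalenv())
  i <- 0
  function(lo, hi) {
    i <<- i + 1
    lo + (hi - lo) * draws[i]
  }
}
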