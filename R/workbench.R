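# End-to-end orchestration: configuration, the voxel-path per-subject
# pipeline, and phantom-cohort runs that regenerate a reference-style report.

#' Pipeline run configuration
#'
#' All tunable constants of the pipeline in one validated object. Defaults
#' equal the protocol constants: 0.625 mm reconstruction interval, 150 HU
#' density threshold, 500 mm^3 small-component removal.
#'
#' @param n_per_sex subjects per sex in a phantom-cohort run.
#' @param path "mesh" (analytic surfaces) or "voxel" (voxelize + segment).
#' @param voxel_spacing_mm voxel spacing for the voxel path.
#' @param threshold_hu density threshold.
#' @param min_volume_mm3 small-component removal threshold.
#' @param noise_sd_hu volume noise (voxel path).
#' @param seed base seed; each subject derives `seed + index`.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param verbose logical; per-subject progress on stderr.
#' @return a `run_config` list.
#' @export
run_config <- function(n_per_sex = 10, path = c("mesh", "voxel"),
                       voxel_spacing_mm = c(0.625, 0.625, 0.625),
                       threshold_hu = 150, min_volume_mm3 = 500,
                       noise_sd_hu = 0, seed = 1L, out_dir = NULL,
                       verbose = FALSE) {
  path <- match.arg(path)
  cfg <- list(n_per_sex = as.integer(n_per_sex), path = path,
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              threshold_hu = threshold_hu, min_volume_mm3 = min_volume_mm3,
              noise_sd_hu = noise_sd_hu, seed = as.integer(seed),
              out_dir = out_dir, verbose = isTRUE(verbose))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$n_per_sex >= 1, cfg$path %in% c("mesh", "voxel"),
            length(cfg$voxel_spacing_mm) == 3, all(cfg$voxel_spacing_mm > 0),
            cfg$threshold_hu > 0, cfg$min_volume_mm3 >= 0,
            cfg$noise_sd_hu >= 0)
  invisible(cfg)
}

#' Write / read a run configuration (YAML)
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `path` / the [run_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$out_dir <- raw$out_dir %||% NULL
  do.call(run_config, raw)
}

# Published normal ranges drive the per-subject jitter SDs (range/6).
.cohort_sd <- list(
  male = c(xy = 6.8, tcsa = 1.3, tcsp = 1.4, ifd = 2.3, ifh = 11.2, tfo = 5.1) / 6,
  female = c(xy = 2.8, tcsa = 1.1, tcsp = 1.4, ifd = 2.0, ifh = 7.3, tfo = 3.8) / 6)
.height_m <- list(male = c(mean = 1.73, sd = 0.032),
                  female = c(mean = 1.61, sd = 0.025))

# One jittered subject spec around a sex preset; resamples on infeasibility.
cohort_subject_spec <- function(sex, seed, noise_sd_hu = 0,
                                voxel_spacing_mm = c(0.625, 0.625, 0.625)) {
  base <- phantom_preset(sex)
  sds <- .cohort_sd[[sex]]
  for (try in 0:4) {
    set.seed(seed + 7919L * try)
    tr <- stats::rnorm(6)
    args <- list(
      xy_true_mm = base$xy_true_mm + sds["xy"] * tr[1],
      tcsa_true_mm = max(0.8, base$tcsa_true_mm + sds["tcsa"] * tr[2]),
      tcsp_true_mm = max(1.2, base$tcsp_true_mm + sds["tcsp"] * tr[3]),
      ifd_true_mm = max(3.1, base$ifd_true_mm + sds["ifd"] * tr[4]),
      tfo_true_mm = max(1.0, base$tfo_true_mm + sds["tfo"] * tr[6]),
      noise_sd_hu = noise_sd_hu, voxel_spacing_mm = voxel_spacing_mm,
      seed = as.integer(seed))
    args$ifh_true_mm <- max(args$xy_true_mm + 8.5,
                            base$ifh_true_mm + sds["ifh"] * tr[5])
    spec <- try(do.call(phantom_spec, args), silent = TRUE)
    if (!inherits(spec, "try-error")) {
      # full feasibility probe (placement + clearance) on a coarse build
      feas <- try(generate_phantom(spec, voxelize = FALSE, detail = 0.3),
                  silent = TRUE)
      if (!inherits(feas, "try-error")) return(spec)
    }
  }
  stop("cohort_subject_spec: no feasible phantom after 5 draws (seed ", seed, ")")
}

#' Voxel-path measurement of one subject volume
#'
#' Segments the volume (threshold, small-component removal, sub-voxel
#' surfaces, seeded labels) and runs the full measurement battery: 3-D, 2-D
#' axial, and simulated radiograph.
#'
#' @param vol a [vox_vol()].
#' @param seeds named list of interior seed points (tibia, fibula, talus).
#' @param articular_seed point on the distal tibial articular surface.
#' @param threshold_hu,min_volume_mm3 segmentation constants.
#' @param subject identifier.
#' @param ... passed to [measure_surfaces()].
#' @return tibble of measurement records (one row per modality).
#' @export
measure_volume <- function(vol, seeds, articular_seed, threshold_hu = 150,
                           min_volume_mm3 = 500, subject = NA_character_, ...) {
  side <- vol$side
  if (side == "left") {
    # mirror the whole scene into the right-side canonical frame
    vol <- vox_vol(vol$values[rev(seq_len(dim(vol$values)[1])), , ],
                   vol$spacing,
                   origin = c(-(vol$origin[1] + (dim(vol$values)[1] - 1) * vol$spacing[1]),
                              vol$origin[2:3]),
                   side = "right")
    seeds <- lapply(seeds, function(p) p * c(-1, 1, 1))
    articular_seed <- articular_seed * c(-1, 1, 1)
  }
  bones <- segment_volume(vol, seeds, threshold_hu = threshold_hu,
                          min_volume_mm3 = min_volume_mm3)
  rec3 <- measure_surfaces(bones, articular_seed, side = "right",
                           subject = subject, ...)
  plane_y <- attr(rec3, "plane_y")
  rec2 <- measure_axial_2d(vol, plane_y, seeds, threshold_hu = threshold_hu,
                           subject = subject, side = "right")
  out <- dplyr::bind_rows(rec3, rec2)
  out$side <- side
  attr(out, "landmarks") <- attr(rec3, "landmarks")
  attr(out, "plane_x") <- attr(rec3, "plane_x")
  attr(out, "plane_y") <- plane_y
  out
}

#' Run a phantom-cohort pipeline
#'
#' Generates jittered male and female phantom cohorts, measures every subject
#' (mesh or voxel path), and assembles a reference-style report: per-subject
#' measurements, sex comparison by ANCOVA with body height as covariate, and
#' modality comparisons by paired t tests. Deterministic given the config
#' seed; per-subject failures are recorded and do not abort the cohort.
#'
#' @param config a [run_config()].
#' @return a `syndesmo_run`: list with `measurements` (tibble),
#'   `cohort` (per-subject 3-D values with sex and height), `sex_tests`
#'   (ANCOVA per parameter), `modality_tests`, `errors` (tibble), `config`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  subjects <- tidyr::expand_grid(sex = c("male", "female"),
                                 idx = seq_len(config$n_per_sex))
  subjects$subject <- sprintf("%s%03d", substr(subjects$sex, 1, 1), subjects$idx)
  subjects$seed <- config$seed + 1000L * (seq_len(nrow(subjects)) - 1L)

  meas <- list()
  errs <- list()
  cohort <- list()
  for (r in seq_len(nrow(subjects))) {
    sx <- subjects$sex[r]
    sid <- subjects$subject[r]
    res <- try({
      spec <- cohort_subject_spec(sx, subjects$seed[r],
                                  noise_sd_hu = config$noise_sd_hu,
                                  voxel_spacing_mm = config$voxel_spacing_mm)
      ph <- generate_phantom(spec, voxelize = config$path == "voxel",
                             detail = if (config$path == "mesh") 0.5 else 1)
      seeds <- phantom_seeds(ph)
      rec <- if (config$path == "voxel") {
        measure_volume(ph$volume, seeds$interior, seeds$articular,
                       threshold_hu = config$threshold_hu,
                       min_volume_mm3 = config$min_volume_mm3, subject = sid)
      } else {
        measure_surfaces(ph$surfaces, seeds$articular, side = spec$side,
                         subject = sid)
      }
      set.seed(subjects$seed[r] + 17L)
      rec$sex <- sx
      rec$height <- stats::rnorm(1, .height_m[[sx]]["mean"], .height_m[[sx]]["sd"])
      rec
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        subject = sid, error = conditionMessage(attr(res, "condition")))
      if (config$verbose) message("  subject ", sid, " FAILED")
      next
    }
    if (config$verbose) message("  subject ", sid, " ok")
    meas[[length(meas) + 1L]] <- res
  }
  measurements <- dplyr::bind_rows(meas)
  errors <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(subject = character(), error = character())

  cohort <- measurements[measurements$modality == "3-D",
                         c("subject", "sex", "height", "XY", "TCS_A", "TCS_P",
                           "IFD", "IFH")]
  sex_tests <- dplyr::bind_rows(lapply(c("XY", "TCS_A", "TCS_P", "IFD", "IFH"),
    function(pm) {
      ft <- ancova_sex(cohort, parameter = pm)
      tibble::tibble(parameter = pm, F = ft$F, p = ft$p,
                     male_adj = ft$adjusted_means$adjusted_mean[ft$adjusted_means$sex == "male"],
                     female_adj = ft$adjusted_means$adjusted_mean[ft$adjusted_means$sex == "female"])
    }))
  modality_tests <- dplyr::bind_rows(
    compare_modalities(measurements, "TCS_A"),
    compare_modalities(measurements, "TCS_P"),
    compare_modalities(measurements, "IFD"),
    compare_modalities(measurements, "TCS_P", c("3-D", "radiograph"),
                       parameter_y = "TCS"),
    compare_modalities(measurements, "IFH", c("3-D", "radiograph")))

  out <- structure(list(measurements = measurements, cohort = cohort,
                        sex_tests = sex_tests, modality_tests = modality_tests,
                        errors = errors, config = config),
                   class = "syndesmo_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' @export
print.syndesmo_run <- function(x, ...) {
  cat(sprintf("<syndesmo_run> %d records, %d subjects, %d failures (%s path)\n",
              nrow(x$measurements), length(unique(x$measurements$subject)),
              nrow(x$errors), x$config$path))
  cat("\nSex comparison (ANCOVA, height-adjusted):\n")
  print(x$sex_tests)
  cat("\nModality comparison (paired t):\n")
  print(x$modality_tests)
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(sex_tests = run$sex_tests, modality_tests = run$modality_tests,
         errors = run$errors),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Seed points of a generated phantom
#'
#' Interior seed points for bone labeling and the articular seed for the
#' plafond fit, derived from the phantom truth (stands in for the operator's
#' clicks).
#'
#' @param ph result of [generate_phantom()].
#' @return list with `interior` (named list tibia/fibula/talus) and
#'   `articular` (length-3 point).
#' @export
phantom_seeds <- function(ph) {
  tr <- ph$truth
  Trf <- phantom_transform(tr$spec)
  tp <- function(p) as.numeric(Trf %*% p)
  an <- phantom_anatomy()
  list(interior = list(tibia = tp(c(0, 0, 10)),
                       fibula = tp(c(tr$fibula_centre, tr$xy)),
                       talus = tp(an$talus_centre)),
       articular = tp(c(0, 0, 0)))
}
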