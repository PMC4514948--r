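#' CT-like voxel volume
#'
#' A 3-D scalar grid in Hounsfield-like units with voxel spacing and origin.
#' Axes follow the canonical frame (+x lateral, +y anterior, +z proximal for a
#' right ankle); `origin` is the world coordinate (mm) of the centre of voxel
#' `[1, 1, 1]`.
#'
#' @param values 3-D numeric array (HU).
#' @param spacing positive length-3 voxel spacing (mm).
#' @param origin length-3 world position of the first voxel centre (mm).
#' @param side "right" or "left" (metadata only).
#' @return An object of class `vox_vol`.
#' @export
vox_vol <- function(values, spacing, origin = c(0, 0, 0), side = "right") {
  stopifnot(length(dim(values)) == 3, length(spacing) == 3, all(spacing > 0),
            length(origin) == 3, side %in% c("right", "left"))
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), side = side),
            class = "vox_vol")
}

#' @export
print.vox_vol <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vox_vol> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm, %s side\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$side))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%.2f, %.2f, %.2f) mm\n",
              min(x$values), max(x$values), x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# World coordinates of voxel centres along each axis.
vox_axis <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

vox_voxel_volume <- function(vol) prod(vol$spacing)

#' Write a volume as NIfTI
#' @param vol a [vox_vol()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::asNifti(img)
  RNifti::writeNifti(img, path)
  # sidecar with origin/side: NIfTI sform handling kept out of scope
  jsonlite::write_json(list(origin = vol$origin, side = vol$side),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file path.
#' @return a [vox_vol()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(origin = c(0, 0, 0), side = "right")
  vox_vol(array(as.numeric(img), dim = dim(img)[1:3]), sp,
          origin = as.numeric(meta$origin), side = meta$side)
}

#' Write a volume as MetaImage (.mha)
#'
#' Single-file MetaImage with a local raw float32 block, little-endian.
#'
#' @param vol a [vox_vol()].
#' @param path output path ending in `.mha`.
#' @return `path`, invisibly.
#' @export
write_volume_mha <- function(vol, path) {
  d <- dim(vol$values)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.9g %.9g %.9g",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           sprintf("Offset = %.9g %.9g %.9g",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           sprintf("AnatomicalOrientation = %s", vol$side),
           "ElementType = MET_FLOAT", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a MetaImage (.mha) volume written by [write_volume_mha()]
#' @param path file path.
#' @return a [vox_vol()].
#' @export
read_volume_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1)
    hdr <- c(hdr, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  gv <- function(key) sub(paste0("^", key, " = "), "", grep(paste0("^", key), hdr, value = TRUE)[1])
  d <- as.integer(strsplit(gv("DimSize"), " ")[[1]])
  sp <- as.numeric(strsplit(gv("ElementSpacing"), " ")[[1]])
  org <- as.numeric(strsplit(gv("Offset"), " ")[[1]])
  side <- gv("AnatomicalOrientation")
  if (is.na(side) || !side %in% c("left", "right")) side <- "right"
  vals <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  vox_vol(array(vals, dim = d), sp, origin = org, side = side)
}
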