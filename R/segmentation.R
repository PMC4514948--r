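# Image post-processing chain: density threshold at 150 HU, removal of
# connected components smaller than 500 mm^3 (26-connectivity), sub-voxel
# isosurface extraction, and seeded bone labeling.

#' Threshold bone from a CT-like volume
#'
#' @param vol a [vox_vol()].
#' @param threshold_hu density threshold; voxels with values `>=` the
#'   threshold are bone (default 150 HU).
#' @return logical 3-D array (the binary mask), with the volume's spacing and
#'   origin attached as attributes `spacing` and `origin`.
#' @examples
#' v <- vox_vol(array(40, c(4, 4, 4)), c(1, 1, 1))
#' sum(threshold_bone(v))  # empty mask, with a warning
#' @export
threshold_bone <- function(vol, threshold_hu = 150) {
  stopifnot(inherits(vol, "vox_vol"))
  mask <- vol$values >= threshold_hu
  if (!any(mask)) warning("threshold_bone: empty mask (no voxel >= ",
                          threshold_hu, " HU)")
  attr(mask, "spacing") <- vol$spacing
  attr(mask, "origin") <- vol$origin
  mask
}

# 26-connected component labels of a logical mask; 0 = background.
label_components_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, d))
  n1 <- d[1]; n12 <- d[1] * d[2]
  # voxel -> compact id
  id <- integer(prod(d))
  id[idx] <- seq_along(idx)
  k <- (idx - 1L) %/% n12
  r <- (idx - 1L) %% n12
  j <- r %/% n1
  i <- r %% n1
  # half of the 26 neighbourhood (the other half follows by symmetry)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
                (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- vector("list", nrow(offs))
  for (q in seq_len(nrow(offs))) {
    di <- offs[q, 1]; dj <- offs[q, 2]; dk <- offs[q, 3]
    ii <- i + di; jj <- j + dj; kk <- k + dk
    ok <- ii >= 0L & ii < d[1] & jj >= 0L & jj < d[2] & kk >= 0L & kk < d[3]
    nb <- ii[ok] + jj[ok] * n1 + kk[ok] * n12 + 1L
    nbid <- id[nb]
    hit <- nbid > 0L
    edges[[q]] <- cbind(id[idx[ok]][hit], nbid[hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[idx] <- as.integer(memb)
  lab
}

#' Remove small connected components from a bone mask
#'
#' Components are 26-connected; a component is removed when its physical
#' volume is strictly less than `min_volume_mm3` (default 500 mm^3).
#'
#' @param mask logical array from [threshold_bone()] (spacing metadata
#'   attached), or any logical array plus explicit `spacing`.
#' @param min_volume_mm3 removal threshold (strict `<`).
#' @param spacing voxel spacing; defaults to the mask's attached metadata.
#' @return the cleaned mask (same attributes).
#' @export
remove_small_components <- function(mask, min_volume_mm3 = 500,
                                    spacing = attr(mask, "spacing")) {
  if (is.null(spacing)) stop("remove_small_components: no spacing metadata")
  if (min_volume_mm3 <= 0 || !any(mask)) return(mask)
  lab <- label_components_26(mask)
  sizes <- tabulate(lab[lab > 0L])
  vol_mm3 <- sizes * prod(spacing)
  drop <- which(vol_mm3 < min_volume_mm3)
  if (length(drop)) {
    out <- mask & !(array(lab %in% drop, dim(mask)))
    attributes(out) <- attributes(mask)
    return(out)
  }
  mask
}

#' Extract bone surfaces from a cleaned mask
#'
#' Isosurface at the threshold level with linear interpolation, using the
#' original HU values where available (sub-voxel accuracy); falls back to the
#' binary mask. One closed surface per connected component.
#'
#' @param mask logical array (with spacing/origin attributes) selecting the
#'   retained voxels.
#' @param vol optional source [vox_vol()]; when given, voxels outside `mask`
#'   are reset below the level so removed components leave no surface.
#' @param level iso level in HU (only used with `vol`).
#' @param spacing,origin grid metadata; default from the mask attributes.
#' @return list of unlabeled [bone_surface()], largest first. Surfaces open at
#'   the volume boundary keep `closed = FALSE`.
#' @export
extract_surfaces <- function(mask, vol = NULL, level = 150,
                             spacing = attr(mask, "spacing"),
                             origin = attr(mask, "origin")) {
  if (!any(mask)) stop("extract_surfaces: empty mask")
  if (is.null(spacing)) stop("extract_surfaces: no spacing metadata")
  if (is.null(origin)) origin <- c(0, 0, 0)
  if (is.null(vol)) {
    vals <- array(-1, dim(mask))
    vals[mask] <- 1
    lv <- 0
    side <- "right"
  } else {
    vals <- vol$values
    # flatten only removed foreground voxels, so debris leaves no surface but
    # the graded edge profile of the kept bones stays intact (sub-voxel)
    vals[(vals >= level) & !mask] <- level - 1000
    spacing <- vol$spacing
    origin <- vol$origin
    side <- vol$side
    lv <- level
  }
  # pad one background layer so masks touching the grid boundary still close
  d <- dim(vals)
  padded <- array(lv - 1000, d + 2L)
  padded[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- vals
  src <- vox_vol(padded, spacing, origin - spacing, side = side)
  soup <- marching_tetrahedra(src, level = lv)
  if (is.null(soup)) stop("extract_surfaces: level set empty")
  split_surface_components(soup)
}

#' Label bone surfaces from seed points
#'
#' Assigns anatomical labels by point-in-surface tests: each seed must lie
#' inside exactly one surface; surfaces containing no seed are labeled
#' "other". The operation trusts the seeds (swapped seeds give swapped
#' labels).
#'
#' @param surfaces list of closed [bone_surface()].
#' @param seed_points named list of length-3 points (mm), e.g.
#'   `list(tibia = c(...), fibula = c(...), talus = c(...))`.
#' @return the surfaces, labeled, in the input order.
#' @export
label_bones <- function(surfaces, seed_points) {
  stopifnot(length(names(seed_points)) == length(seed_points))
  owner <- integer(length(seed_points))
  for (s in seq_along(seed_points)) {
    p <- as.numeric(seed_points[[s]])
    inside <- vapply(surfaces, function(srf) point_in_surface(srf, p), TRUE)
    if (sum(inside) == 0)
      stop("label_bones: seed '", names(seed_points)[s],
           "' lies inside no surface")
    if (sum(inside) > 1)
      stop("label_bones: seed '", names(seed_points)[s],
           "' lies inside several surfaces")
    owner[s] <- which(inside)
  }
  if (anyDuplicated(owner))
    stop("label_bones: two seeds fall in the same surface ('",
         paste(names(seed_points)[duplicated(owner) | duplicated(owner, fromLast = TRUE)],
               collapse = "', '"), "')")
  out <- lapply(surfaces, function(s) { s$label <- "other"; s })
  for (s in seq_along(seed_points)) out[[owner[s]]]$label <- names(seed_points)[s]
  out
}

# Point-in-mesh by slicing at the point's z and testing the 2-D polygons.
point_in_surface <- function(surface, p) {
  zr <- range(surface$vertices[, 3])
  if (p[3] <= zr[1] || p[3] >= zr[2]) return(FALSE)
  polys <- mesh_slice_3d(surface, anatomic_plane(c(0, 0, p[3]), c(0, 0, 1)))
  if (length(polys) == 0) return(FALSE)
  inside <- FALSE
  for (poly in polys) {
    if (points_in_polygon(matrix(p[1:2], ncol = 2), poly[, 1:2, drop = FALSE]))
      inside <- !inside               # nested shells toggle
  }
  inside
}

#' Run the full segmentation chain on a volume
#'
#' Threshold at `threshold_hu`, remove components under `min_volume_mm3`,
#' extract sub-voxel surfaces, label them from seeds.
#'
#' @param vol a [vox_vol()].
#' @param seed_points named list of interior points per bone.
#' @param threshold_hu density threshold (default 150 HU).
#' @param min_volume_mm3 small-component threshold (default 500 mm^3).
#' @return named list of labeled [bone_surface()] (named by label).
#' @export
segment_volume <- function(vol, seed_points, threshold_hu = 150,
                           min_volume_mm3 = 500) {
  mask <- threshold_bone(vol, threshold_hu)
  mask <- remove_small_components(mask, min_volume_mm3)
  surfaces <- extract_surfaces(mask, vol = vol, level = threshold_hu)
  labeled <- label_bones(surfaces, seed_points)
  names(labeled) <- vapply(labeled, function(s) s$label, "")
  labeled
}
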