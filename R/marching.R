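# Marching tetrahedra isosurface extraction.
#
# Each grid cube is split into six tetrahedra around the main diagonal and the
# level set is linearly interpolated along crossed edges, giving sub-voxel
# placement of the surface at the Hounsfield threshold. Triangle orientation
# is normalized per tetrahedron (outward = from values above the level toward
# values below), and shared edge vertices are merged exactly so the result is
# watertight away from the volume boundary.

# 6-tet decomposition of the cube around diagonal c1-c7; corners numbered
# c1=(0,0,0) c2=(1,0,0) c3=(1,1,0) c4=(0,1,0) c5=(0,0,1) c6=(1,0,1)
# c7=(1,1,1) c8=(0,1,1).
.tet_table <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                    c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
.cube_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                   c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

#' Extract an isosurface from a voxel volume
#'
#' @param vol a [vox_vol()].
#' @param level iso level (HU); voxels with values exactly at the level count
#'   as inside.
#' @return a single [bone_surface()] containing all surface sheets (split with
#'   [split_surface_components()]), or `NULL` if the level set is empty.
#' @export
marching_tetrahedra <- function(vol, level = 150) {
  v <- vol$values - level
  v[v == 0] <- 1e-9                     # values at the level count as inside
  d <- dim(v)
  if (any(d < 2)) return(NULL)
  inside <- v > 0

  # active cubes: corners on both sides of the level
  S <- array(0L, d - 1L)
  for (c in seq_len(8)) {
    o <- .cube_off[c, ]
    S <- S + inside[o[1] + seq_len(d[1] - 1L),
                    o[2] + seq_len(d[2] - 1L),
                    o[3] + seq_len(d[3] - 1L)]
  }
  act <- which(S > 0L & S < 8L, arr.ind = TRUE)
  if (nrow(act) == 0) return(NULL)

  # linear indices of the 8 corners of each active cube
  lin <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  corner_idx <- sapply(seq_len(8), function(c) {
    o <- .cube_off[c, ]
    lin(act[, 1] + o[1], act[, 2] + o[2], act[, 3] + o[3])
  })
  corner_idx <- matrix(corner_idx, nrow = nrow(act))

  # all tets of all active cubes: N x 4 corner linear indices
  tets <- do.call(rbind, lapply(seq_len(6), function(t)
    corner_idx[, .tet_table[t, ], drop = FALSE]))
  sv <- matrix(v[tets], nrow = nrow(tets))
  msk <- sv > 0
  nin <- rowSums(msk)
  keep <- nin > 0 & nin < 4
  tets <- tets[keep, , drop = FALSE]
  sv <- sv[keep, , drop = FALSE]
  msk <- msk[keep, , drop = FALSE]
  nin <- nin[keep]
  if (nrow(tets) == 0) return(NULL)

  # reorder each tet's columns as (inside..., outside...) via the mask code
  code <- msk[, 1] + 2L * msk[, 2] + 4L * msk[, 3] + 8L * msk[, 4]
  perm <- list(`1` = c(1, 2, 3, 4), `2` = c(2, 1, 3, 4), `4` = c(3, 1, 2, 4),
               `8` = c(4, 1, 2, 3), `14` = c(2, 3, 4, 1), `13` = c(1, 3, 4, 2),
               `11` = c(1, 2, 4, 3), `7` = c(1, 2, 3, 4),
               `3` = c(1, 2, 3, 4), `5` = c(1, 3, 2, 4), `9` = c(1, 4, 2, 3),
               `6` = c(2, 3, 1, 4), `10` = c(2, 4, 1, 3), `12` = c(3, 4, 1, 2))
  o1 <- o2 <- o3 <- o4 <- integer(nrow(tets))
  for (cd in unique(code)) {
    p <- perm[[as.character(cd)]]
    r <- code == cd
    o1[r] <- p[1]; o2[r] <- p[2]; o3[r] <- p[3]; o4[r] <- p[4]
  }
  n <- nrow(tets)
  gi <- function(o) tets[cbind(seq_len(n), o)]
  q1 <- gi(o1); q2 <- gi(o2); q3 <- gi(o3); q4 <- gi(o4)

  # emit crossed edges per case; each row: (inside corner, outside corner)
  e <- vector("list", 10)
  one <- nin == 1
  if (any(one)) {
    e[[1]] <- cbind(q1[one], q2[one]); e[[2]] <- cbind(q1[one], q3[one])
    e[[3]] <- cbind(q1[one], q4[one])
  }
  three <- nin == 3
  if (any(three)) {
    # q4 is the lone outside vertex; triangle on edges (q1,q4),(q2,q4),(q3,q4)
    e[[4]] <- cbind(q1[three], q4[three]); e[[5]] <- cbind(q2[three], q4[three])
    e[[6]] <- cbind(q3[three], q4[three])
  }
  two <- nin == 2
  if (any(two)) {
    # inside q1,q2; outside q3,q4; quad cycle e13-e14-e24-e23
    e[[7]] <- cbind(q1[two], q3[two]); e[[8]] <- cbind(q1[two], q4[two])
    e[[9]] <- cbind(q2[two], q4[two]); e[[10]] <- cbind(q2[two], q3[two])
  }

  xs <- vox_axis(vol, 1); ys <- vox_axis(vol, 2); zs <- vox_axis(vol, 3)
  coord <- function(idx) {
    k <- (idx - 1L) %/% (d[1] * d[2])
    r <- (idx - 1L) %% (d[1] * d[2])
    j <- r %/% d[1]
    i <- r %% d[1]
    cbind(xs[i + 1L], ys[j + 1L], zs[k + 1L])
  }
  all_e <- do.call(rbind, e[!vapply(e, is.null, TRUE)])
  ekey <- paste(pmin(all_e[, 1], all_e[, 2]), pmax(all_e[, 1], all_e[, 2]))
  uk <- unique(ekey)
  vid <- match(ekey, uk)
  first <- match(uk, ekey)
  ea <- all_e[first, 1]; eb <- all_e[first, 2]
  t <- v[ea] / (v[ea] - v[eb])
  pa <- coord(ea); pb <- coord(eb)
  verts <- pa + t * (pb - pa)

  # assemble triangles from per-case edge blocks
  offs <- cumsum(c(0, vapply(e, function(x) if (is.null(x)) 0L else nrow(x), 0L)))
  blk <- function(i) if (offs[i + 1] > offs[i]) vid[(offs[i] + 1):offs[i + 1]] else integer(0)
  tris <- rbind(
    if (any(one)) cbind(blk(1), blk(2), blk(3)),
    if (any(three)) cbind(blk(4), blk(5), blk(6)),
    if (any(two)) rbind(cbind(blk(7), blk(8), blk(9)),
                        cbind(blk(7), blk(9), blk(10))))
  tri_src <- c(if (any(one)) which(one), if (any(three)) which(three),
               if (any(two)) rep(which(two), 2))

  # orient: normal must point from inside (above level) to outside
  a <- verts[tris[, 1], , drop = FALSE]
  bb <- verts[tris[, 2], , drop = FALSE]
  cc <- verts[tris[, 3], , drop = FALSE]
  nrm <- cbind((bb[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) - (bb[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
               (bb[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) - (bb[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
               (bb[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (bb[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  cin <- coord(q1)
  cin[two, ] <- (coord(q1)[two, , drop = FALSE] + coord(q2)[two, , drop = FALSE]) / 2
  cin[three, ] <- (coord(q1)[three, , drop = FALSE] + coord(q2)[three, , drop = FALSE] +
                     coord(q3)[three, , drop = FALSE]) / 3
  cout <- coord(q4)
  cout[one, ] <- (coord(q2)[one, , drop = FALSE] + coord(q3)[one, , drop = FALSE] +
                    coord(q4)[one, , drop = FALSE]) / 3
  cout[two, ] <- (coord(q3)[two, , drop = FALSE] + coord(q4)[two, , drop = FALSE]) / 2
  outdir <- cout[tri_src, , drop = FALSE] - cin[tri_src, , drop = FALSE]
  flip <- rowSums(nrm * outdir) < 0
  tmp <- tris[flip, 2]
  tris[flip, 2] <- tris[flip, 3]
  tris[flip, 3] <- tmp

  # drop degenerate triangles (duplicate vertices)
  ok <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] & tris[, 1] != tris[, 3]
  tris <- tris[ok, , drop = FALSE]
  bone_surface(verts, tris, closed = NA)
}

#' Split a triangle soup into connected surfaces
#'
#' @param surface a [bone_surface()] possibly holding several disconnected
#'   sheets.
#' @return a list of [bone_surface()], one per connected component, largest
#'   first.
#' @export
split_surface_components <- function(surface) {
  f <- surface$faces
  if (nrow(f) == 0) return(list())
  g <- igraph::graph_from_edgelist(
    rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(surface$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  fcomp <- comp[f[, 1]]
  out <- lapply(sort(unique(fcomp)), function(ci) {
    fs <- f[fcomp == ci, , drop = FALSE]
    used <- sort(unique(as.vector(fs)))
    remap <- integer(nrow(surface$vertices))
    remap[used] <- seq_along(used)
    bone_surface(surface$vertices[used, , drop = FALSE],
                 matrix(remap[fs], ncol = 3), label = surface$label)
  })
  out[order(-vapply(out, function(s) nrow(s$faces), 1L))]
}
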