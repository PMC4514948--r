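# Minimal ASCII PLY / STL readers and writers. Only the subset of the formats
# needed to exchange triangle meshes (float vertices, triangular faces).

#' Write a surface as ASCII PLY
#' @param surface a [bone_surface()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment label %s", surface$label),
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY surface
#' @param path file path.
#' @return a [bone_surface()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(lines == "end_header")[1]
  if (is.na(hdr_end)) stop("not a PLY file: ", path)
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)[1]))
  lab <- sub("comment label ", "", grep("^comment label", hdr, value = TRUE)[1])
  if (is.na(lab)) lab <- ""
  vl <- lines[hdr_end + seq_len(nv)]
  fl <- lines[hdr_end + nv + seq_len(nf)]
  v <- matrix(scan(text = vl, quiet = TRUE), ncol = 3, byrow = TRUE)
  fr <- matrix(scan(text = fl, quiet = TRUE), ncol = 4, byrow = TRUE)
  bone_surface(v, fr[, 2:4, drop = FALSE] + 1L, label = lab)
}

#' Write a surface as ASCII STL
#' @param surface a [bone_surface()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(surface, path) {
  fn <- mesh_face_normals(surface)$normals
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  name <- if (nzchar(surface$label)) surface$label else "surface"
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Vertices are merged exactly (by coordinate string), so a watertight solid
#' round-trips as a closed mesh.
#'
#' @param path file path.
#' @return a [bone_surface()] (label taken from the solid name).
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  name <- sub("^solid\\s*", "", lines[1])
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- matrix(scan(text = gsub("vertex", "", vl), quiet = TRUE),
                   ncol = 3, byrow = TRUE)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- unique(key)
  idx <- match(key, uk)
  v <- coords[match(uk, key), , drop = FALSE]
  f <- matrix(idx, ncol = 3, byrow = TRUE)
  bone_surface(v, f, label = if (nzchar(name)) name else "")
}

#' Write a set of labeled surfaces plus a JSON manifest
#'
#' One PLY per bone plus `manifest.json` mapping labels to files.
#'
#' @param surfaces list of [bone_surface()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_surface_set <- function(surfaces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(surfaces), function(i) {
    s <- surfaces[[i]]
    lab <- if (nzchar(s$label)) s$label else sprintf("surface%02d", i)
    fn <- sprintf("%s.ply", lab)
    write_ply(s, file.path(dir, fn))
    list(label = lab, file = fn, closed = isTRUE(s$closed))
  })
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Read a surface set written by [write_surface_set()]
#' @param dir directory containing `manifest.json`.
#' @return named list of [bone_surface()].
#' @export
read_surface_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- lapply(man, function(e) {
    s <- read_ply(file.path(dir, e$file))
    s$label <- e$label
    s
  })
  names(out) <- vapply(man, function(e) e$label, "")
  out
}
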