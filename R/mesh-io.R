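#' @useDynLib fvstent, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv
NULL

# Vertex welding tolerance applied when reading STL soup (mm).
STL_MERGE_TOL <- 1e-6

#' Triangulated surface mesh
#'
#' A minimal container for a triangulated surface: an `n x 3` numeric matrix
#' of vertex coordinates in millimetres and an `m x 3` integer matrix of
#' 1-based vertex indices per triangle.  The coordinate system is
#' right-handed and faces are wound counter-clockwise seen from outside.
#'
#' @param vertices numeric matrix, one vertex per row (mm).
#' @param faces integer matrix, one triangle per row, 1-based indices.
#' @param provenance free-text tag recording where the mesh came from.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, provenance = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(faces) > 0L && ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces,
                 provenance = as.character(provenance)[1]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces [%s]\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  invisible(x)
}

# Weld vertices closer than `tol` by snapping to a tolerance grid.
merge_duplicate_vertices <- function(vertices, faces, tol = STL_MERGE_TOL) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  vertices <- vertices[first, , drop = FALSE]
  faces[] <- remap[faces]
  list(vertices = vertices, faces = faces)
}

#' Read a surface mesh from an STL file
#'
#' Reads ASCII or binary stereolithography files.  STL stores a triangle
#' soup; vertices closer than 1e-6 mm are merged on read so downstream
#' stages see true connectivity.  The face count of the file is preserved.
#'
#' @param path file to read.
#' @param dialect one of `"auto"`, `"stl_ascii"`, `"stl_binary"`.
#' @return A [surface_mesh()].
#' @export
read_surface_mesh <- function(path, dialect = c("auto", "stl_ascii",
                                                "stl_binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read mesh file: ", path)
  if (dialect == "auto") {
    head <- readBin(path, "raw", n = 5L)
    dialect <- if (identical(rawToChar(head), "solid") &&
                   is_ascii_stl(path)) "stl_ascii" else "stl_binary"
  }
  res <- if (dialect == "stl_ascii") read_stl_ascii(path)
         else read_stl_binary(path)
  if (nrow(res$faces) == 0L)
    stop("STL format error: file contains no facets: ", path)
  m <- merge_duplicate_vertices(res$vertices, res$faces)
  surface_mesh(m$vertices, m$faces, provenance = basename(path))
}

# A file starting with "solid" can still be binary; check the body parses.
is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 30L, warn = FALSE))
  any(grepl("facet|endsolid", txt))
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  parts <- strsplit(trimws(vl), "\\s+")
  coords <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
  if (anyNA(coords)) stop("STL format error: non-numeric vertex in ", path)
  v <- t(coords)
  nf <- nrow(v) / 3L
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80L))
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L || 84 + 50 * as.numeric(nf) > sz)
    stop("STL format error: bad binary facet count in ", path)
  if (nf == 0L)
    return(list(vertices = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))
  raw <- readBin(con, "raw", n = 50L * nf)
  rec <- matrix(raw, nrow = 50L)
  # bytes 13..48 of each record are the three vertices (skip normal)
  vb <- as.vector(rec[13:48, , drop = FALSE])
  v <- matrix(readBin(vb, "numeric", n = 9L * nf, size = 4L,
                      endian = "little"),
              ncol = 3L, byrow = TRUE)
  f <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

#' Write a surface mesh to an STL file
#'
#' @param mesh a [surface_mesh()]; must contain at least one face.
#' @param path output file.
#' @param dialect `"stl_binary"` (default, 32-bit float, standard 80-byte
#'   header + uint32 count) or `"stl_ascii"`.
#' @return `path`, invisibly.
#' @export
write_surface_mesh <- function(mesh, path,
                               dialect = c("stl_binary", "stl_ascii")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh (no faces)")
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  if (dialect == "stl_ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid fvstent", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid fvstent", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(formatC("fvstent binary STL", width = -80))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    # assemble per-facet records: normal, v1, v2, v3 as float32 + uint16
    tri <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                 v[f[, 3], , drop = FALSE])
    fl <- writeBin(as.numeric(t(tri)), raw(), size = 4L, endian = "little")
    recs <- matrix(as.raw(0), nrow = 50L, ncol = nrow(f))
    recs[1:48, ] <- matrix(fl, nrow = 48L)
    writeBin(as.vector(recs), con)
  }
  invisible(path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(n^2))
}

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem volume; positive when faces are wound outward.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in mm^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Validate a surface mesh
#'
#' Pure report of mesh integrity: edge-manifoldness, degenerate faces,
#' winding consistency, and the bounding box.  A mesh is watertight when
#' every edge is shared by exactly two consistently wound faces, no face is
#' degenerate, and the signed volume is positive.
#'
#' @param mesh a [surface_mesh()].
#' @return A list of class `validation_report` with fields `watertight`,
#'   `n_nonmanifold_edges`, `n_degenerate_faces`, `bbox`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  f <- mesh$faces
  v <- mesh$vertices
  if (nrow(f) == 0L) {
    rep <- list(watertight = FALSE, n_nonmanifold_edges = 0L,
                n_degenerate_faces = 0L,
                bbox = list(min = rep(NA_real_, 3), max = rep(NA_real_, 3)))
    class(rep) <- "validation_report"
    return(rep)
  }
  nv <- nrow(v)
  ea <- c(f[, 1], f[, 2], f[, 3])
  eb <- c(f[, 2], f[, 3], f[, 1])
  undirected <- pmin(ea, eb) * (nv + 1) + pmax(ea, eb)
  cnt <- table(undirected)
  n_nonmanifold <- sum(cnt != 2L)
  directed <- ea * (nv + 1) + eb
  inconsistent <- anyDuplicated(directed) > 0L
  degen <- (f[, 1] == f[, 2]) | (f[, 2] == f[, 3]) | (f[, 1] == f[, 3]) |
    (face_areas(mesh) < 1e-12)
  n_degen <- sum(degen)
  watertight <- n_nonmanifold == 0L && n_degen == 0L && !inconsistent &&
    mesh_volume(mesh) > 0
  rep <- list(watertight = watertight,
              n_nonmanifold_edges = as.integer(n_nonmanifold),
              n_degenerate_faces = as.integer(n_degen),
              bbox = list(min = apply(v, 2, min), max = apply(v, 2, max)))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation_report: watertight=%s nonmanifold_edges=%d degenerate=%d\n",
    x$watertight, x$n_nonmanifold_edges, x$n_degenerate_faces))
  invisible(x)
}

#' Split a mesh into connected components
#'
#' Faces are connected when they share a vertex.  Used to count the wires
#' of an exported braided stent after a round trip through STL.
#'
#' @param mesh a [surface_mesh()].
#' @return A list of `surface_mesh` objects, one per component.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(f))) {
    a <- find(f[i, 1]); b <- find(f[i, 2]); c3 <- find(f[i, 3])
    parent[b] <- a
    parent[c3] <- a
  }
  root <- vapply(seq_len(nv), find, integer(1))
  comp_of_face <- root[f[, 1]]
  comps <- unique(comp_of_face)
  lapply(comps, function(cid) {
    keep <- comp_of_face == cid
    fsub <- f[keep, , drop = FALSE]
    used <- sort(unique(as.vector(fsub)))
    remap <- integer(nv)
    remap[used] <- seq_along(used)
    surface_mesh(mesh$vertices[used, , drop = FALSE],
                 matrix(remap[fsub], ncol = 3L),
                 provenance = paste0(mesh$provenance, "#component"))
  })
}

#' Read a centerline polyline from CSV
#'
#' Expects a header `x,y,z` with an optional `radius` column, coordinates in
#' millimetres, one ordered point per row.
#'
#' @param path CSV file.
#' @return A [centerline()] object; when a radius column is present it is
#'   carried over and `radius_source` is set to `"from file"`.
#' @export
read_polyline <- function(path) {
  if (!file.exists(path)) stop("cannot read polyline file: ", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop("polyline format error: ", conditionMessage(e)))
  if (!all(c("x", "y", "z") %in% names(df)))
    stop("polyline format error: need columns x,y,z")
  pts <- as.matrix(df[, c("x", "y", "z")])
  if (!is.numeric(pts) || anyNA(pts))
    stop("polyline format error: non-numeric coordinate")
  if (nrow(pts) < 2L) stop("polyline format error: need at least 2 points")
  radius <- NULL
  if ("radius" %in% names(df)) {
    radius <- as.numeric(df$radius)
    if (anyNA(radius)) stop("polyline format error: non-numeric radius")
  }
  cl <- centerline(pts, radius = radius)
  cl$radius_source <- if (is.null(radius)) "none" else "from file"
  cl
}

#' Write a centerline polyline to CSV
#'
#' Coordinates are written as decimal text with 17 significant digits so a
#' round trip reproduces them exactly.
#'
#' @param cl a [centerline()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_polyline <- function(cl, path) {
  stopifnot(inherits(cl, "centerline"))
  p <- cl$points
  has_r <- !is.null(cl$radius) && !anyNA(cl$radius)
  header <- if (has_r) "x,y,z,radius" else "x,y,z"
  rows <- if (has_r)
    sprintf("%.17g,%.17g,%.17g,%.17g", p[, 1], p[, 2], p[, 3], cl$radius)
  else sprintf("%.17g,%.17g,%.17g", p[, 1], p[, 2], p[, 3])
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report` from [validate_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
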