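#' Triangle mesh
#'
#' A closed (watertight) triangle surface in micrometer coordinates,
#' tagged with the structure class it bounds (1 = shaft, 2 = spine).
#'
#' @param vertices numeric matrix (n x 3) of vertex positions in um.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param structure_class 1 (shaft) or 2 (spine).
#' @param check if `TRUE` (default), reject meshes that are not closed.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, structure_class = 2L,
                          check = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!structure_class %in% c(1L, 2L))
    stop("structure_class must be 1 (shaft) or 2 (spine)")
  m <- structure(list(vertices = vertices, faces = faces,
                      structure_class = as.integer(structure_class)),
                 class = "triangle_mesh")
  if (check && !is_watertight(m))
    stop("closed surface required: the mesh has boundary or non-manifold edges (hole filling is out of scope)")
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, class %d, %s\n",
              nrow(x$vertices), nrow(x$faces), x$structure_class,
              if (is_watertight(x)) "watertight" else "open"))
  invisible(x)
}

#' Watertightness test
#'
#' A mesh is watertight when every undirected edge is shared by exactly
#' two faces.
#'
#' @param mesh a [triangle_mesh()] (or a list with `vertices`/`faces`).
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F
#'
#' Equals 2 for a closed surface of sphere topology.
#'
#' @param mesh a [triangle_mesh()].
#' @return integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  length(unique(as.vector(f))) - length(key) + nrow(f)
}

#' Signed mesh volume by the divergence theorem
#'
#' Sum of signed tetrahedron volumes against the origin. The absolute
#' value is the enclosed volume for a consistently oriented closed mesh.
#'
#' @param mesh a [triangle_mesh()].
#' @return numeric volume in um^3 (signed).
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

#' Read a triangle mesh from OBJ or PLY (ASCII)
#'
#' Watertightness is checked on read; an open mesh raises an error
#' rather than being silently repaired.
#'
#' @param path path ending in `.obj` or `.ply`.
#' @param structure_class class tag to attach (1 shaft, 2 spine).
#' @param check reject non-watertight meshes (default `TRUE`).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, structure_class = 2L, check = TRUE) {
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    obj = parse_obj(path),
    ply = parse_ply(path),
    stop("unsupported mesh format '", ext, "' (OBJ or ASCII PLY expected)"))
  triangle_mesh(parsed$vertices, parsed$faces, structure_class, check = check)
}

#' Write a triangle mesh to OBJ or PLY (ASCII)
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path ending in `.obj` or `.ply`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$faces
  if (ext == "obj") {
    lines <- c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
    writeLines(lines, path)
  } else if (ext == "ply") {
    header <- c("ply", "format ascii 1.0",
                paste("element vertex", nrow(v)),
                "property float x", "property float y", "property float z",
                paste("element face", nrow(f)),
                "property list uchar int vertex_indices", "end_header")
    body <- c(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
              sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L))
    writeLines(c(header, body), path)
  } else {
    stop("unsupported mesh format '", ext, "'")
  }
  invisible(path)
}

parse_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vlines)), "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", flines)), "\\s+"),
                                 function(p) {
    idx <- as.integer(sub("/.*", "", p))
    if (length(idx) != 3) stop("only triangle faces are supported")
    idx
  }))
  list(vertices = verts, faces = faces)
}

parse_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("not an ASCII PLY file")
  header <- lines[seq_len(end)]
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", header, value = TRUE)[1]))
  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- do.call(rbind, lapply(vparts, function(p) as.numeric(p[1:3])))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- do.call(rbind, lapply(fparts, function(p) {
    n <- as.integer(p[1])
    if (n != 3) stop("only triangle faces are supported")
    as.integer(p[2:4]) + 1L
  }))
  list(vertices = verts, faces = faces)
}
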