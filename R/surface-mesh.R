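# Triangulated boundary surfaces: construction, validity checks, and
# plain-text STL / PLY readers and writers.

#' Construct a triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices with
#'   consistent (outward) winding.
#' @param labels Optional per-triangle region tags (length m).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, labels = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  if (nrow(triangles) > 0L) {
    rng <- range(triangles)
    if (rng[1L] < 1L || rng[2L] > nrow(vertices))
      stop("triangle indices out of range")
    key <- apply(triangles, 1L, function(t) paste(sort(t), collapse = "-"))
    if (anyDuplicated(key))
      stop("duplicate triangles in surface mesh")
    if (any(triangles[, 1L] == triangles[, 2L] |
            triangles[, 1L] == triangles[, 3L] |
            triangles[, 2L] == triangles[, 3L]))
      stop("degenerate triangle (repeated vertex index)")
  }
  if (!is.null(labels) && length(labels) != nrow(triangles))
    stop("labels must have one entry per triangle")
  structure(list(vertices = vertices, triangles = triangles, labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles%s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

directed_edges <- function(triangles) {
  rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
}

#' Test whether a surface is a closed, consistently oriented 2-manifold
#'
#' Every undirected edge must be shared by exactly two triangles with opposite
#' directions (so each directed edge occurs exactly once).
#'
#' @param mesh A `surface_mesh`.
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  tr <- mesh$triangles
  if (nrow(tr) == 0L) return(FALSE)
  de <- directed_edges(tr)
  dk <- paste(de[, 1L], de[, 2L])
  if (anyDuplicated(dk)) return(FALSE)     # non-manifold or inconsistent winding
  uk <- paste(pmin(de[, 1L], de[, 2L]), pmax(de[, 1L], de[, 2L]))
  all(table(uk) == 2L)
}

#' Surface area of a triangulated mesh
#' @param mesh A `surface_mesh`.
#' @return Total area (mm^2).
#' @export
surface_area <- function(mesh) {
  tr <- mesh$triangles; v <- mesh$vertices
  sum(vapply(seq_len(nrow(tr)),
             function(i) triangle_area(v[tr[i, ], , drop = FALSE]), 0))
}

#' Volume enclosed by a closed surface
#'
#' Divergence-theorem volume; positive when triangles are wound outward.
#'
#' @param mesh A watertight `surface_mesh`.
#' @return Enclosed volume (mm^3).
#' @export
enclosed_volume <- function(mesh) {
  tr <- mesh$triangles; v <- mesh$vertices
  vol <- 0
  for (i in seq_len(nrow(tr))) {
    p <- v[tr[i, ], , drop = FALSE]
    vol <- vol + sum(cross3(p[1L, ], p[2L, ]) * p[3L, ]) / 6
  }
  vol
}

bbox_diagonal <- function(mesh) {
  r <- apply(mesh$vertices, 2L, range)
  norm3(r[2L, ] - r[1L, ])
}

#' Write a surface mesh as ASCII STL
#' @param mesh A `surface_mesh`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_stl <- function(mesh, file) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  for (i in seq_len(nrow(tr))) {
    p <- v[tr[i, ], , drop = FALSE]
    n <- cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])
    nn <- norm3(n); if (nn > 0) n <- n / nn
    writeLines(c(
      sprintf("  facet normal %.17g %.17g %.17g", n[1L], n[2L], n[3L]),
      "    outer loop",
      sprintf("      vertex %.17g %.17g %.17g", p[, 1L], p[, 2L], p[, 3L]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid surface", con)
  invisible(file)
}

#' Read an ASCII STL file
#'
#' Vertices are de-duplicated exactly (by coordinate triple) in order of first
#' appearance.
#'
#' @param file Path to an ASCII STL file.
#' @return A `surface_mesh`.
#' @export
read_stl <- function(file) {
  lines <- readLines(file)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(f) as.numeric(f[2:4]), numeric(3L)))
  key <- apply(coords, 1L, paste, collapse = ",")
  uidx <- !duplicated(key)
  verts <- coords[uidx, , drop = FALSE]
  map <- match(key, key[uidx])
  tris <- matrix(map, ncol = 3L, byrow = TRUE)
  surface_mesh(verts, tris)
}

#' Write a surface mesh as ASCII PLY
#' @param mesh A `surface_mesh`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_ply <- function(mesh, file) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1L] - 1L, tr[, 2L] - 1L, tr[, 3L] - 1L), con)
  invisible(file)
}

#' Read an ASCII PLY surface file
#' @param file Path to an ASCII PLY file written by [write_ply()].
#' @return A `surface_mesh`.
#' @export
read_ply <- function(file) {
  lines <- readLines(file)
  hdr_end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)))
  vlines <- lines[hdr_end + seq_len(nv)]
  flines <- lines[hdr_end + nv + seq_len(nf)]
  verts <- t(vapply(strsplit(vlines, "\\s+"), function(f) as.numeric(f[1:3]), numeric(3L)))
  tris <- t(vapply(strsplit(flines, "\\s+"), function(f) as.integer(f[2:4]), integer(3L))) + 1L
  surface_mesh(verts, tris)
}

# Rigid-transform / scale helper used across modules.
transform_surface <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                              scale = 1) {
  v <- scale * (mesh$vertices %*% t(rotation))
  v <- sweep(v, 2L, translation, "+")
  surface_mesh(v, mesh$triangles, mesh$labels)
}
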