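# tet4 volume meshes: construction with automatic orientation repair,
# boundary extraction, part handling, quality reports and VTK output.

#' Construct a tet4 volume mesh
#'
#' Node ordering of each tetrahedron follows the positive-signed-volume
#' convention; elements violating it are repaired by swapping two vertices
#' rather than rejected.
#'
#' @param nodes n x 3 numeric matrix of node coordinates (mm).
#' @param tets m x 4 integer matrix of 1-based node indices.
#' @param part Per-element part tag (character, length m or 1).
#' @param region Optional per-element region tag.
#' @return An object of class `volume_mesh`.
#' @export
volume_mesh <- function(nodes, tets, part = "solid", region = NULL) {
  nodes <- matrix(as.numeric(nodes), ncol = 3L,
                  dimnames = list(NULL, c("x", "y", "z")))
  tets <- matrix(as.integer(tets), ncol = 4L)
  if (nrow(tets) > 0L) {
    rng <- range(tets)
    if (rng[1L] < 1L || rng[2L] > nrow(nodes)) stop("tet indices out of range")
  }
  vols <- tet_volumes(nodes, tets)
  neg <- which(vols < 0)
  if (length(neg)) {                       # orientation repair by vertex swap
    tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
    vols[neg] <- -vols[neg]
  }
  if (any(vols <= 0))
    stop("degenerate tetrahedron (zero volume) at element ",
         which(vols <= 0)[1L])
  part <- rep_len(as.character(part), nrow(tets))
  if (!is.null(region)) region <- rep_len(as.character(region), nrow(tets))
  structure(list(nodes = nodes, tets = tets, part = part, region = region,
                 volumes = vols),
            class = "volume_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("volume_mesh: %d nodes, %d tet4 elements, parts: %s\n",
              nrow(x$nodes), nrow(x$tets),
              paste(unique(x$part), collapse = ", ")))
  invisible(x)
}

tet_volumes <- function(nodes, tets) {
  if (nrow(tets) == 0L) return(numeric(0))
  a <- nodes[tets[, 2L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 3L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  d <- nodes[tets[, 4L], , drop = FALSE] - nodes[tets[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  (cx * d[, 1L] + cy * d[, 2L] + cz * d[, 3L]) / 6
}

# Outward-oriented faces of each tet under the positive-volume convention.
tet_face_table <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 4L, 3L))

#' Extract the boundary surface of a volume mesh
#'
#' Faces belonging to exactly one tetrahedron, oriented outward; the part tag
#' of the owning element is carried as the triangle label.
#'
#' @param mesh A `volume_mesh`.
#' @param parts Optional character vector restricting to elements of these parts.
#' @return A `surface_mesh` whose vertex indices refer to `mesh$nodes`.
#' @export
boundary_faces <- function(mesh, parts = NULL) {
  sel <- if (is.null(parts)) seq_len(nrow(mesh$tets)) else which(mesh$part %in% parts)
  tt <- mesh$tets[sel, , drop = FALSE]
  nf <- 4L * nrow(tt)
  faces <- matrix(0L, nf, 3L)
  owner <- integer(nf)
  for (k in 1:4) {
    rows <- seq_len(nrow(tt)) + (k - 1L) * nrow(tt)
    faces[rows, ] <- tt[, tet_face_table[k, ], drop = FALSE]
    owner[rows] <- sel
  }
  key <- paste(pmin(faces[, 1L], pmin(faces[, 2L], faces[, 3L])),
               faces[, 1L] + faces[, 2L] + faces[, 3L],
               pmax(faces[, 1L], pmax(faces[, 2L], faces[, 3L])))
  tab <- table(key)
  bnd <- key %in% names(tab)[tab == 1L]
  structure(list(vertices = mesh$nodes,
                 triangles = faces[bnd, , drop = FALSE],
                 labels = mesh$part[owner[bnd]]),
            class = "surface_mesh")
}

#' Nodes used by the elements of one part
#' @param mesh A `volume_mesh`.
#' @param part Part tag.
#' @return Sorted integer vector of node indices.
#' @export
part_nodes <- function(mesh, part) {
  sel <- mesh$part %in% part
  if (!any(sel)) stop("no elements with part tag '", part, "'")
  sort(unique(as.vector(mesh$tets[sel, , drop = FALSE])))
}

#' Remove a part from a volume mesh
#'
#' Drops the part's elements together with nodes used by no remaining element
#' (indices are remapped).  Springs or boundary conditions referring to node
#' indices must be rebuilt against the reduced mesh.
#'
#' @param mesh A `volume_mesh`.
#' @param part Part tag(s) to remove.
#' @return A `volume_mesh` plus attribute `node_map` (old index -> new or NA).
#' @export
remove_part <- function(mesh, part) {
  keep <- !(mesh$part %in% part)
  if (!any(keep)) stop("removing '", part, "' would empty the mesh")
  tets <- mesh$tets[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tets)))
  map <- rep(NA_integer_, nrow(mesh$nodes))
  map[used] <- seq_along(used)
  out <- volume_mesh(mesh$nodes[used, , drop = FALSE],
                     matrix(map[tets], ncol = 4L),
                     part = mesh$part[keep],
                     region = if (is.null(mesh$region)) NULL else mesh$region[keep])
  attr(out, "node_map") <- map
  out
}

#' Mesh quality report
#'
#' Applies the meshing rules: no slender elements (edge-length ratio), no
#' low-quality elements (insphere/circumsphere metric), and gradual size
#' transitions between face-adjacent elements.
#'
#' @param mesh A `volume_mesh`.
#' @param rules List with `quality_min` (default 0.1), `slenderness_max`
#'   (default 10) and `gradation_max` (default 2, max allowed ratio of
#'   adjacent element sizes measured as longest edge).
#' @return A `quality_report`: per-element metrics, violation counts, and the
#'   worst adjacent-size ratio.
#' @export
validate_mesh <- function(mesh, rules = list()) {
  rules <- utils::modifyList(
    list(quality_min = 0.1, slenderness_max = 10, gradation_max = 2), rules)
  m <- nrow(mesh$tets)
  quality <- numeric(m)
  slender <- numeric(m)
  longest <- numeric(m)
  for (i in seq_len(m)) {
    p <- mesh$nodes[mesh$tets[i, ], , drop = FALSE]
    quality[i] <- tet_quality(p)
    el <- tet_edge_lengths(p)
    slender[i] <- max(el) / min(el)
    longest[i] <- max(el)
  }
  # face adjacency for the gradation rule
  nf <- 4L * m
  faces <- matrix(0L, nf, 3L); owner <- integer(nf)
  for (k in 1:4) {
    rows <- seq_len(m) + (k - 1L) * m
    faces[rows, ] <- mesh$tets[, tet_face_table[k, ], drop = FALSE]
    owner[rows] <- seq_len(m)
  }
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  ord <- order(key)
  key <- key[ord]; owner <- owner[ord]
  shared <- which(key[-1L] == key[-length(key)])
  grad <- if (length(shared)) {
    a <- owner[shared]; b <- owner[shared + 1L]
    pmax(longest[a], longest[b]) / pmin(longest[a], longest[b])
  } else numeric(0)
  report <- list(
    n_elements = m,
    quality = quality,
    slenderness = slender,
    max_adjacent_ratio = if (length(grad)) max(grad) else 1,
    counts = c(low_quality = sum(quality < rules$quality_min),
               slender = sum(slender > rules$slenderness_max),
               gradation = sum(grad > rules$gradation_max)),
    rules = rules)
  class(report) <- "quality_report"
  report
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0("quality_report: %d elements | low quality (<%g): %d | ",
                     "slender (>%g): %d | gradation pairs (>%g): %d\n"),
              x$n_elements, x$rules$quality_min, x$counts["low_quality"],
              x$rules$slenderness_max, x$counts["slender"],
              x$rules$gradation_max, x$counts["gradation"]))
  invisible(x)
}

#' Write a volume mesh as legacy ASCII VTK
#' @param mesh A `volume_mesh`.
#' @param file Output path.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node numeric vectors or n x 3 matrices.
#' @return Invisibly, the path.
#' @export
write_vtk <- function(mesh, file, cell_data = NULL, point_data = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "carpalfem mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1L] - 1L, mesh$tets[, 2L] - 1L,
                     mesh$tets[, 3L] - 1L, mesh$tets[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  cd <- c(list(part_id = as.numeric(factor(mesh$part))), cell_data)
  writeLines(sprintf("CELL_DATA %d", m), con)
  for (nm in names(cd)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", cd[[nm]]), con)
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.17g", v), con)
      }
    }
  }
  invisible(file)
}

#' Read a legacy ASCII VTK unstructured grid (tet4 only)
#' @param file Path to a file written by [write_vtk()].
#' @return A `volume_mesh`.
#' @export
read_vtk <- function(file) {
  lines <- readLines(file)
  ip <- grep("^POINTS", lines)[1L]
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1L]][2L])
  nodes <- t(vapply(strsplit(lines[ip + seq_len(n)], "\\s+"),
                    function(f) as.numeric(f[1:3]), numeric(3L)))
  ic <- grep("^CELLS", lines)[1L]
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1L]][2L])
  tets <- t(vapply(strsplit(lines[ic + seq_len(m)], "\\s+"),
                   function(f) as.integer(f[2:5]), integer(4L))) + 1L
  volume_mesh(nodes, tets)
}

#' Write a volume mesh (with fields) as ASCII VTU
#'
#' XML VTK UnstructuredGrid, one file per time step; suitable for ParaView.
#'
#' @param mesh A `volume_mesh`.
#' @param file Output path.
#' @param cell_data Named list of per-element numeric vectors.
#' @param point_data Named list of per-node vectors or n x 3 matrices.
#' @return Invisibly, the path.
#' @export
write_vtu <- function(mesh, file, cell_data = NULL, point_data = NULL) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  da <- function(name, values, ncomp = 1L) {
    c(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
              name, ncomp),
      paste(sprintf("%.17g", t(values)), collapse = " "),
      "</DataArray>")
  }
  out <- c('<?xml version="1.0"?>',
           '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
           "<UnstructuredGrid>",
           sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
           "<Points>", da("Points", mesh$nodes, 3L), "</Points>",
           "<Cells>",
           '<DataArray type="Int32" Name="connectivity" format="ascii">',
           paste(t(mesh$tets) - 1L, collapse = " "), "</DataArray>",
           '<DataArray type="Int32" Name="offsets" format="ascii">',
           paste(4L * seq_len(m), collapse = " "), "</DataArray>",
           '<DataArray type="UInt8" Name="types" format="ascii">',
           paste(rep(10L, m), collapse = " "), "</DataArray>",
           "</Cells>")
  cd <- c(list(part_id = as.numeric(factor(mesh$part))), cell_data)
  out <- c(out, "<CellData>",
           unlist(lapply(names(cd), function(nm) da(nm, cd[[nm]]))),
           "</CellData>")
  if (!is.null(point_data)) {
    out <- c(out, "<PointData>",
             unlist(lapply(names(point_data), function(nm) {
               v <- point_data[[nm]]
               da(nm, v, if (is.matrix(v)) ncol(v) else 1L)
             })),
             "</PointData>")
  }
  out <- c(out, "</Piece>", "</UnstructuredGrid>", "</VTKFile>")
  writeLines(out, file)
  invisible(file)
}
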