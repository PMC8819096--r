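# Surface-to-volume conversion.  The converter fills a watertight,
# star-shaped surface by stacking scaled copies of the boundary toward an
# interior kernel point ("onion" layers): each surface triangle spawns a
# column of prisms, each split into three tetrahedra, plus one apex
# tetrahedron at the centre.  The outermost layer *is* the input surface, so
# the boundary is reproduced exactly.  Diagonal choices on the vertical quad
# faces depend only on surface vertex indices, which makes neighbouring
# prism columns conforming.

# Split one prism (bottom b[1:3], top t[1:3], both above surface vertex ids
# sid[1:3]) into three tets.  Indexing rule of Dompierre et al.: rotate the
# smallest surface id first; the remaining quad diagonal follows the smaller
# of the two other ids.
prism_to_tets <- function(b, t, sid) {
  r <- which.min(sid)
  ord <- ((r - 1L) + 0:2) %% 3L + 1L
  b <- b[ord]; t <- t[ord]; sid <- sid[ord]
  if (sid[2L] < sid[3L]) {
    rbind(c(b[1L], b[2L], b[3L], t[3L]),
          c(b[1L], b[2L], t[3L], t[2L]),
          c(b[1L], t[2L], t[3L], t[1L]))
  } else {
    rbind(c(b[1L], b[2L], b[3L], t[2L]),
          c(b[1L], t[2L], b[3L], t[3L]),
          c(b[1L], t[2L], t[3L], t[1L]))
  }
}

#' Convert a watertight surface into a tet4 volume mesh
#'
#' Radial-layer construction valid for surfaces that are star-shaped with
#' respect to `center` (all generated parts are; so are convex test shapes).
#' The boundary of the result coincides exactly with the input surface.
#' The construction is fully deterministic.
#'
#' @param surface A watertight `surface_mesh` with outward winding.
#' @param target_edge Target edge length (mm) controlling the number of
#'   radial layers.
#' @param center Optional interior kernel point; defaults to the vertex
#'   centroid.
#' @param part Part tag for the elements.
#' @return A `volume_mesh`.  The attribute `layer` stores each node's radial
#'   layer (0 = centre, max = boundary) and `surface_vertex` maps boundary
#'   nodes back to input vertex indices.
#' @export
tetrahedralize <- function(surface, target_edge, center = NULL, part = "solid") {
  if (!inherits(surface, "surface_mesh")) stop("surface must be a surface_mesh")
  if (!is_watertight(surface))
    stop("input surface is not watertight (open or inconsistently oriented); ",
         "cannot tetrahedralize")
  if (!is.numeric(target_edge) || target_edge <= 0)
    stop("target_edge must be positive")
  v <- surface$vertices
  if (is.null(center)) center <- colMeans(v)
  radii <- sqrt(rowSums(sweep(v, 2L, center, "-")^2))
  n_layers <- max(1L, as.integer(round(mean(radii) / target_edge)))
  nv <- nrow(v)
  # node table: centre, then layers 1..n_layers (outermost = surface vertices)
  nodes <- matrix(0, 1L + n_layers * nv, 3L)
  nodes[1L, ] <- center
  layer_of <- integer(nrow(nodes))
  for (l in seq_len(n_layers)) {
    f <- l / n_layers
    rows <- 1L + (l - 1L) * nv + seq_len(nv)
    nodes[rows, ] <- sweep(f * sweep(v, 2L, center, "-"), 2L, center, "+")
    layer_of[rows] <- l
  }
  id_at <- function(l, i) 1L + (l - 1L) * nv + i   # node id of vertex i at layer l
  tr <- surface$triangles
  tet_list <- vector("list", n_layers)
  # innermost: apex tets centre -> layer 1
  tet_list[[1L]] <- cbind(1L, id_at(1L, tr[, 1L]), id_at(1L, tr[, 2L]),
                          id_at(1L, tr[, 3L]))
  if (n_layers > 1L) {
    for (l in seq_len(n_layers - 1L)) {
      shell <- vector("list", nrow(tr))
      for (i in seq_len(nrow(tr))) {
        s <- tr[i, ]
        shell[[i]] <- prism_to_tets(id_at(l, s), id_at(l + 1L, s), s)
      }
      tet_list[[l + 1L]] <- do.call(rbind, shell)
    }
  }
  tets <- do.call(rbind, tet_list)
  mesh <- volume_mesh(nodes, tets, part = part)
  attr(mesh, "layer") <- layer_of
  sv <- rep(NA_integer_, nrow(nodes))
  sv[id_at(n_layers, seq_len(nv))] <- seq_len(nv)
  attr(mesh, "surface_vertex") <- sv
  mesh
}
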