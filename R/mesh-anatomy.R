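# Assembled multi-part volume meshing of an anatomy model.  Bone volumes
# come from the radial-layer tetrahedralizer; cartilage layers and the SLIL
# block are built conforming (shared interface nodes with their bones), so
# bone-cartilage and bone-SLIL junctions need no contact search.

#' Mesh an anatomy model into one multi-part tet4 volume mesh
#'
#' Bones are tetrahedralized about their own centres; the radius is split
#' into a cancellous core and cortical shell by radial layer (interface at
#' the layer fraction nearest `cancellous_scale`); cartilage layers are
#' prism-extrusions of the articular caps sharing base nodes with the bone;
#' the SLIL block lattice shares its end-face nodes with scaphoid and lunate.
#'
#' @param model An `anatomy_model` from [generate_reduced_wrist()].
#' @param target_edge Target element edge length (mm) for the bone volumes.
#' @param parts_only Optional character vector of bone parts to mesh
#'   (default: full carpus).  `"radius"` alone gives the reduced
#'   radius-only model.
#' @return A `volume_mesh` with parts `radius` (regions
#'   `cortical`/`cancellous`), `scaphoid`, `lunate`, `capitate`,
#'   `*_cartilage`, `slil`.  Attribute `surface_node` maps
#'   `part -> surface vertex id -> global node id` for landmark resolution.
#' @export
mesh_anatomy <- function(model, target_edge = 3,
                         parts_only = c("radius", "scaphoid", "lunate",
                                        "capitate")) {
  cfg <- model$config
  nodes <- NULL
  tets <- NULL
  part <- character(0)
  region <- character(0)
  surface_node <- list()

  add_nodes <- function(x) {
    off <- if (is.null(nodes)) 0L else nrow(nodes)
    nodes <<- rbind(nodes, x)
    off
  }
  add_elems <- function(t4, p, r = p) {
    tets <<- rbind(tets, t4)
    part <<- c(part, rep(p, nrow(t4)))
    region <<- c(region, rep(r, nrow(t4)))
  }

  for (nm in parts_only) {
    surf <- model$bones[[nm]]
    ctr <- attr(surf, "center")
    vm <- tetrahedralize(surf, target_edge, center = ctr, part = nm)
    off <- add_nodes(vm$nodes)
    layer <- attr(vm, "layer")
    sv <- attr(vm, "surface_vertex")
    n_layers <- max(layer)
    if (nm == "radius") {
      # element layer = max node layer; inner layers are cancellous core
      elem_layer <- apply(matrix(layer[vm$tets], ncol = 4L), 1L, max)
      cutoff <- max(1L, as.integer(round(cfg$cancellous_scale * n_layers)))
      if (cutoff >= n_layers) cutoff <- n_layers - 1L
      reg <- ifelse(elem_layer <= cutoff & n_layers > 1L, "cancellous",
                    "cortical")
      add_elems(vm$tets + off, "radius", reg)
    } else {
      add_elems(vm$tets + off, nm)
    }
    map <- rep(NA_integer_, nrow(surf$vertices))
    map[sv[!is.na(sv)]] <- which(!is.na(sv)) + off
    surface_node[[nm]] <- map
  }

  thick <- cfg$cartilage_thickness * cfg$scale
  for (nm in intersect(parts_only, names(model$cart_pieces))) {
    piece <- model$cart_pieces[[nm]]
    surf <- model$bones[[nm]]
    ext <- extrude_cap(surf, piece$cap_tris, surface_node[[nm]],
                       nrow(nodes), thick)
    add_nodes(ext$nodes_new)
    add_elems(ext$tets, paste0(nm, "_cartilage"))
  }

  if (all(c("scaphoid", "lunate") %in% parts_only)) {
    idA_global <- matrix(surface_node$scaphoid[model$slil_patches$scaphoid],
                         nrow = nrow(model$slil_patches$scaphoid))
    idB_global <- matrix(surface_node$lunate[model$slil_patches$lunate],
                         nrow = nrow(model$slil_patches$lunate))
    lat <- slil_lattice(nodes, idA_global, idB_global, cfg$slil_layers,
                        nrow(nodes))
    if (!is.null(lat$nodes_new)) add_nodes(lat$nodes_new)
    add_elems(lat$tets, "slil")
  }

  mesh <- volume_mesh(nodes, tets, part = part, region = region)
  attr(mesh, "surface_node") <- surface_node
  attr(mesh, "target_edge") <- target_edge
  mesh
}

# Nearest boundary node of a named mesh part to a point; parts named in the
# landmark table map onto mesh parts (the radius shell is part "radius").
landmark_part_to_mesh_part <- function(p) {
  if (p == "radius_cortical") "radius" else p
}

nearest_part_node <- function(mesh, part, point, tol = Inf) {
  mp <- landmark_part_to_mesh_part(part)
  if (!mp %in% mesh$part)
    stop("mesh has no part named '", mp, "'")
  bnd <- boundary_faces(mesh, parts = mp)
  ids <- sort(unique(as.vector(bnd$triangles)))
  d2 <- rowSums(sweep(mesh$nodes[ids, , drop = FALSE], 2L, point, "-")^2)
  i <- which.min(d2)
  if (sqrt(d2[i]) > tol)
    stop("landmark is ", sprintf("%.3g", sqrt(d2[i])),
         " mm from the nearest boundary node of part '", mp,
         "' (tolerance ", tol, " mm)")
  ids[i]
}
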