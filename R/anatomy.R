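# Parametric surrogate anatomy for the reduced wrist.  Bones are
# superellipsoid-based convex solids on a structured latitude/longitude grid
# (optionally perturbed by a smooth seeded radial deformation); cartilage
# layers are radial extrusions of polar caps, sharing their base vertices
# with the bone; the SLIL is a 3D block lattice bridging the facing surfaces
# of scaphoid and lunate.
#
# Model frame: x = radial(-)/ulnar(+), y = dorsal(-)/volar(+),
# z = proximal(-)/distal(+).  All lengths in mm.

#' Default surrogate shape configuration
#'
#' Characteristic dimensions (mm) of the surrogate bones.  `scale` multiplies
#' every length; `slil_gap` is the nominal scaphoid-lunate clearance bridged
#' by the SLIL block; `n_theta`/`n_phi` set the surface grid resolution;
#' `perturb` is the amplitude (mm) of the smooth seeded radial deformation.
#'
#' @param ... Overrides for any default entry.
#' @return Named list.
#' @export
default_shape_config <- function(...) {
  cfg <- list(
    scale = 1,
    radius_semi = c(11, 10, 11), radius_center_z = -14,
    cancellous_scale = 0.6,
    scaphoid_semi = c(4.5, 3.5, 3.5), scaphoid_center_z = 3,
    lunate_semi = c(3.5, 3.5, 3.5), lunate_center_z = 3,
    capitate_semi = c(5.5, 4.5, 4.5), capitate_center_z = 12.5,
    slil_gap = 2,
    cartilage_thickness = 0.8,
    exponent_bone = 2.4, exponent_radius = 3,
    n_theta = 8L, n_phi = 12L,
    cap_rows = 2L, slil_rows = 1L, slil_layers = 2L,
    perturb = 0.05,
    lever_arm_r = 19.40)
  utils::modifyList(cfg, list(...))
}

# Superellipsoid radius along unit direction u for semi-axes a, exponent p.
superellipsoid_radius <- function(u, a, p) {
  (sum(abs(u / a)^p))^(-1 / p)
}

# Smooth seeded radial modulation, returns a function of unit directions.
make_perturbation <- function(amplitude, rng_draw) {
  if (amplitude <= 0) return(function(u) 0)
  d <- matrix(rng_draw(9), 3L, 3L)
  d <- sweep(d, 1L, sqrt(rowSums(d^2)), "/")
  coef <- rng_draw(3)
  function(u) amplitude * sum(coef * as.vector(d %*% u)^2)
}

# Structured superellipsoid surface.  Returns a surface_mesh with attributes:
# grid (pole/ring vertex ids), dirs (outward unit direction per vertex),
# center.
superellipsoid_surface <- function(semi, center, exponent, n_theta, n_phi,
                                   perturb_fn = function(u) 0) {
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  stopifnot(n_theta >= 3L, n_phi >= 6L)
  nv <- 2L + (n_theta - 1L) * n_phi
  verts <- matrix(0, nv, 3L)
  dirs <- matrix(0, nv, 3L)
  ring <- matrix(0L, n_theta - 1L, n_phi)
  pole_top <- 1L
  pole_bottom <- nv
  place <- function(id, u) {
    t <- superellipsoid_radius(u, semi, exponent) + perturb_fn(u)
    verts[id, ] <<- center + t * u
    dirs[id, ] <<- u
  }
  place(pole_top, c(0, 0, 1))
  for (i in seq_len(n_theta - 1L)) {
    th <- pi * i / n_theta
    for (j in seq_len(n_phi)) {
      ph <- 2 * pi * (j - 1L) / n_phi
      id <- 1L + (i - 1L) * n_phi + j
      ring[i, j] <- id
      place(id, c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
    }
  }
  place(pole_bottom, c(0, 0, -1))
  wrap <- function(j) (j - 1L) %% n_phi + 1L
  tris <- vector("list", n_theta)
  tris[[1L]] <- do.call(rbind, lapply(seq_len(n_phi), function(j)
    c(pole_top, ring[1L, j], ring[1L, wrap(j + 1L)])))
  if (n_theta > 2L) {
    for (i in seq_len(n_theta - 2L)) {
      quads <- do.call(rbind, lapply(seq_len(n_phi), function(j) {
        a <- ring[i, j]; b <- ring[i + 1L, j]
        cc <- ring[i + 1L, wrap(j + 1L)]; d <- ring[i, wrap(j + 1L)]
        split_quad(a, b, cc, d)
      }))
      tris[[i + 1L]] <- quads
    }
  }
  tris[[n_theta]] <- do.call(rbind, lapply(seq_len(n_phi), function(j)
    c(ring[n_theta - 1L, j], pole_bottom, ring[n_theta - 1L, wrap(j + 1L)])))
  out <- surface_mesh(verts, do.call(rbind, tris))
  attr(out, "grid") <- list(n_theta = n_theta, n_phi = n_phi, ring = ring,
                            pole_top = pole_top, pole_bottom = pole_bottom)
  attr(out, "dirs") <- dirs
  attr(out, "center") <- center
  out
}

# Split oriented quad a->b->c->d into two triangles; the diagonal takes the
# smallest vertex id so the choice is reproducible from connectivity alone.
split_quad <- function(a, b, cc, d) {
  if (min(a, cc) <= min(b, d))
    rbind(c(a, b, cc), c(a, cc, d))
  else
    rbind(c(a, b, d), c(b, cc, d))
}

# Vertex ids of a polar cap: pole plus the first/last `rows` rings.
cap_vertices <- function(surface, side = c("top", "bottom"), rows) {
  side <- match.arg(side)
  g <- attr(surface, "grid")
  if (side == "top") c(g$pole_top, as.vector(t(g$ring[seq_len(rows), , drop = FALSE])))
  else c(as.vector(t(g$ring[g$n_theta - 1L - seq_len(rows) + 1L, , drop = FALSE])),
         g$pole_bottom)
}

# Triangles of the surface entirely inside a vertex set.
cap_triangles <- function(surface, vset) {
  tr <- surface$triangles
  keep <- tr[, 1L] %in% vset & tr[, 2L] %in% vset & tr[, 3L] %in% vset
  tr[keep, , drop = FALSE]
}

# Prism-extruded volume over a set of surface triangles: base vertices are
# `base_ids` (global node ids), top vertices are freshly appended.  Returns
# list(nodes_new, tets, top_of) where top_of maps surface vertex id -> new
# global id of the offset vertex.
extrude_cap <- function(surface, cap_tris, global_of, next_id, thickness) {
  dirs <- attr(surface, "dirs")
  vset <- sort(unique(as.vector(cap_tris)))
  top_of <- integer(nrow(surface$vertices))
  nodes_new <- matrix(0, length(vset), 3L)
  for (k in seq_along(vset)) {
    v <- vset[k]
    top_of[v] <- next_id + k
    nodes_new[k, ] <- surface$vertices[v, ] + thickness * dirs[v, ]
  }
  tets <- do.call(rbind, lapply(seq_len(nrow(cap_tris)), function(i) {
    s <- cap_tris[i, ]
    prism_to_tets(global_of[s], top_of[s], s)
  }))
  list(nodes_new = nodes_new, tets = tets, top_of = top_of, vset = vset)
}

# Facing-patch vertex id matrix (rows x cols) for the SLIL attachment.
# side = "ulnar": window around phi = 0 (+x); side = "radial": around phi = pi
# (-x), with column order reversed so (row, col) pairs of the two patches
# face each other with matching y and z.
slil_patch <- function(surface, side = c("ulnar", "radial"), rows_half = 1L) {
  side <- match.arg(side)
  g <- attr(surface, "grid")
  mid <- as.integer(round(g$n_theta / 2))      # equatorial ring block
  ri <- (mid - rows_half):(mid + rows_half)
  ri <- ri[ri >= 1L & ri <= g$n_theta - 1L]
  wrap <- function(j) (j - 1L) %% g$n_phi + 1L
  if (side == "ulnar") {
    cj <- wrap(c(g$n_phi, 1L, 2L))
  } else {
    jm <- g$n_phi %/% 2L + 1L                  # phi = pi for even n_phi
    cj <- wrap(c(jm + 1L, jm, jm - 1L))
  }
  g$ring[ri, cj, drop = FALSE]
}

# Tet lattice interpolating patch A (node ids idA, coords from `nodes`) to
# patch B, with n_layers element layers.  Interior nodes appended from
# next_id.  Patch matrices must be the same dimension.
slil_lattice <- function(nodes, idA, idB, n_layers, next_id) {
  stopifnot(all(dim(idA) == dim(idB)), n_layers >= 1L)
  nu <- nrow(idA); nv <- ncol(idA)
  local <- matrix(seq_len(nu * nv), nu, nv)    # layer-local ids, row-major by column
  # triangulated patch in local ids
  tris <- do.call(rbind, lapply(seq_len(nu - 1L), function(r)
    do.call(rbind, lapply(seq_len(nv - 1L), function(s)
      split_quad(local[r, s], local[r + 1L, s],
                 local[r + 1L, s + 1L], local[r, s + 1L])))))
  A <- nodes[as.vector(idA), , drop = FALSE]
  B <- nodes[as.vector(idB), , drop = FALSE]
  layer_ids <- vector("list", n_layers + 1L)
  layer_ids[[1L]] <- as.vector(idA)
  layer_ids[[n_layers + 1L]] <- as.vector(idB)
  nodes_new <- NULL
  for (k in seq_len(n_layers - 1L)) {
    f <- k / n_layers
    coords <- (1 - f) * A + f * B
    ids <- next_id + (k - 1L) * nu * nv + seq_len(nu * nv)
    layer_ids[[k + 1L]] <- ids
    nodes_new <- rbind(nodes_new, coords)
  }
  tets <- do.call(rbind, lapply(seq_len(n_layers), function(k) {
    bot <- layer_ids[[k]]; top <- layer_ids[[k + 1L]]
    do.call(rbind, lapply(seq_len(nrow(tris)), function(i) {
      s <- tris[i, ]
      prism_to_tets(bot[s], top[s], s)
    }))
  }))
  list(nodes_new = nodes_new, tets = tets)
}

# Closed surface of an extruded/lattice piece built from its own local tet
# mesh (boundary extraction guarantees watertightness and orientation).
piece_surface <- function(nodes, tets) {
  vm <- volume_mesh(nodes, tets)
  b <- boundary_faces(vm)
  used <- sort(unique(as.vector(b$triangles)))
  map <- match(seq_len(nrow(nodes)), used)
  surface_mesh(nodes[used, , drop = FALSE],
               matrix(map[b$triangles], ncol = 3L))
}

#' Generate the surrogate reduced-wrist anatomy
#'
#' Builds parametric surrogate surfaces for the ten model parts
#' (radius cortical shell, cancellous core, radius cartilage, scaphoid,
#' lunate, capitate, three carpal cartilage layers, and the SLIL block) with
#' deterministic seeded shape perturbation, and places the ligament
#' attachment landmarks.
#'
#' @param shape_config Configuration from [default_shape_config()].
#' @param seed Integer seed for the shape perturbation.
#' @return An `anatomy_model`: list with `parts` (named `surface_mesh` list),
#'   `landmarks` (from [place_ligament_landmarks()]), `frame` (axis
#'   convention descriptor), `lever_arm_r` (mm), `config`, and internal
#'   builders reused by the mesher.
#' @export
generate_reduced_wrist <- function(shape_config = default_shape_config(),
                                   seed = 1L) {
  cfg <- shape_config
  dims <- c("radius_semi", "scaphoid_semi", "lunate_semi", "capitate_semi",
            "slil_gap", "cartilage_thickness")
  for (d in dims)
    if (any(cfg[[d]] <= 0)) stop("non-positive dimension in shape_config: ", d)
  if (cfg$cartilage_thickness >= min(cfg$scaphoid_semi, cfg$lunate_semi,
                                     cfg$capitate_semi))
    stop("cartilage thickness must be below the bone radii")
  if (cfg$lever_arm_r <= 0) stop("lever_arm_r must be positive")
  s <- cfg$scale
  if (s <= 0) stop("scale must be positive")

  # private deterministic RNG stream (leaves the global RNG untouched)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  rng_draw <- function(n) stats::runif(n, -1, 1)

  sc_cx <- -(cfg$scaphoid_semi[1L] + cfg$slil_gap / 2)
  lu_cx <- cfg$lunate_semi[1L] + cfg$slil_gap / 2
  spec <- list(
    radius = list(semi = cfg$radius_semi, center = c(0, 0, cfg$radius_center_z),
                  p = cfg$exponent_radius),
    scaphoid = list(semi = cfg$scaphoid_semi,
                    center = c(sc_cx, 0, cfg$scaphoid_center_z),
                    p = cfg$exponent_bone),
    lunate = list(semi = cfg$lunate_semi,
                  center = c(lu_cx, 0, cfg$lunate_center_z),
                  p = cfg$exponent_bone),
    capitate = list(semi = cfg$capitate_semi,
                    center = c(0, 0, cfg$capitate_center_z),
                    p = cfg$exponent_bone))
  bones <- list()
  for (nm in names(spec)) {
    sp <- spec[[nm]]
    pert <- make_perturbation(cfg$perturb * s, rng_draw)
    bones[[nm]] <- superellipsoid_surface(sp$semi * s, sp$center * s, sp$p,
                                          cfg$n_theta, cfg$n_phi, pert)
  }

  thick <- cfg$cartilage_thickness * s
  cart_side <- c(radius = "top", scaphoid = "bottom", lunate = "bottom",
                 capitate = "bottom")
  cart_pieces <- list()
  for (nm in names(cart_side)) {
    surf <- bones[[nm]]
    vset <- cap_vertices(surf, cart_side[[nm]], cfg$cap_rows)
    ctris <- cap_triangles(surf, vset)
    ext <- extrude_cap(surf, ctris, seq_len(nrow(surf$vertices)),
                       nrow(surf$vertices), thick)
    nodes <- rbind(surf$vertices, ext$nodes_new)
    cart_pieces[[nm]] <- list(surface = piece_surface(nodes, ext$tets),
                              cap_tris = ctris, side = cart_side[[nm]])
  }

  idA <- slil_patch(bones$scaphoid, "ulnar", cfg$slil_rows)
  idB <- slil_patch(bones$lunate, "radial", cfg$slil_rows)
  nsc <- nrow(bones$scaphoid$vertices)
  # local frame for the standalone SLIL surface: scaphoid verts + lunate verts
  nodes_sl <- rbind(bones$scaphoid$vertices, bones$lunate$vertices)
  lat <- slil_lattice(nodes_sl, idA, idB + nsc, cfg$slil_layers,
                      nrow(nodes_sl))
  slil_surface <- piece_surface(rbind(nodes_sl, lat$nodes_new), lat$tets)

  cancellous <- transform_surface(bones$radius, scale = cfg$cancellous_scale)
  # rescale about the radius centre, not the origin
  ctr <- attr(bones$radius, "center")
  cancellous$vertices <- sweep(cancellous$vertices, 2L,
                               (1 - cfg$cancellous_scale) * ctr, "+")

  parts <- list(
    radius_cortical = bones$radius,
    radius_cancellous = cancellous,
    radius_cartilage = cart_pieces$radius$surface,
    scaphoid = bones$scaphoid,
    lunate = bones$lunate,
    capitate = bones$capitate,
    scaphoid_cartilage = cart_pieces$scaphoid$surface,
    lunate_cartilage = cart_pieces$lunate$surface,
    capitate_cartilage = cart_pieces$capitate$surface,
    slil = slil_surface)

  model <- structure(list(
    parts = parts,
    frame = paste("x: radial(-)/ulnar(+); y: dorsal(-)/volar(+);",
                  "z: proximal(-)/distal(+); units mm"),
    lever_arm_r = cfg$lever_arm_r,
    config = cfg, seed = as.integer(seed),
    bones = bones, cart_pieces = cart_pieces,
    slil_patches = list(scaphoid = idA, lunate = idB)),
    class = "anatomy_model")
  model$landmarks <- place_ligament_landmarks(model)
  model
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat(sprintf("anatomy_model: %d parts, %d ligament landmarks, lever arm r = %g mm\n",
              length(x$parts), nrow(x$landmarks), x$lever_arm_r))
  cat(" frame:", x$frame, "\n")
  invisible(x)
}

# Ligament table: name, parts, anatomical placement tag.
ligament_rows <- function() {
  data.frame(
    name = c("Dorsal intercarpal (capitate-lunate)",
             "Dorsal intercarpal (capitate-scaphoid)",
             "Dorsal scapholunate",
             "Long radiolunate",
             "Radial arcuate",
             "Radial collateral carpal",
             "Radioscaphocapitate",
             "Short radiolunate",
             "Volar radioscapholunate (scaphoid)",
             "Volar radioscapholunate (lunate)"),
    part_a = c("capitate", "capitate", "scaphoid", "lunate", "capitate",
               "radius_cortical", "radius_cortical", "radius_cortical",
               "radius_cortical", "radius_cortical"),
    part_b = c("lunate", "scaphoid", "lunate", "radius_cortical", "scaphoid",
               "scaphoid", "capitate", "scaphoid", "scaphoid", "lunate"),
    tag = c("dorsal", "dorsal", "dorsal", "volar", "volar", "radial",
            "volar", "volar", "volar", "volar"),
    k = c(150, 150, 230, 75, 40, 10, 50, 75, 50.75, 50.75),
    stringsAsFactors = FALSE)
}

pick_attachment <- function(model, part, tag, toward) {
  if (!part %in% names(model$parts))
    stop("anatomy model has no part named '", part, "'")
  v <- model$parts[[part]]$vertices
  ctr <- colMeans(v)
  # candidates must sit clearly on the named half (20% of the half-extent
  # beyond the centroid), so "dorsal" landmarks are strictly dorsal
  ext <- apply(v, 2L, function(x) (max(x) - min(x)) / 2)
  cand <- switch(tag,
                 dorsal = which(v[, 2L] < ctr[2L] - 0.2 * ext[2L]),
                 volar = which(v[, 2L] > ctr[2L] + 0.2 * ext[2L]),
                 radial = which(v[, 1L] < ctr[1L] - 0.2 * ext[1L]),
                 ulnar = which(v[, 1L] > ctr[1L] + 0.2 * ext[1L]),
                 seq_len(nrow(v)))
  if (!length(cand)) cand <- seq_len(nrow(v))
  d2 <- rowSums(sweep(v[cand, , drop = FALSE], 2L, toward, "-")^2)
  v[cand[which.min(d2)], ]
}

#' Place ligament attachment landmarks
#'
#' One landmark pair per ligament row; the combined
#' radius-to-scaphoid-and-lunate volar row expands to two entries.  Each
#' landmark is a surface vertex of the named part, chosen on the
#' dorsal/volar/radial half-space indicated by the ligament's anatomical name
#' and pointing toward the partner bone.
#'
#' @param model An `anatomy_model`.
#' @return Data frame: name, part_a, ax, ay, az, part_b, bx, by, bz, k
#'   (stiffness, N/mm).
#' @export
place_ligament_landmarks <- function(model) {
  rows <- ligament_rows()
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    for (p in c(r$part_a, r$part_b))
      if (!p %in% names(model$parts))
        stop("anatomy model has no part named '", p, "'")
    ca <- colMeans(model$parts[[r$part_a]]$vertices)
    cb <- colMeans(model$parts[[r$part_b]]$vertices)
    pa <- pick_attachment(model, r$part_a, r$tag, cb)
    pb <- pick_attachment(model, r$part_b, r$tag, ca)
    data.frame(name = r$name, part_a = r$part_a,
               ax = pa[1L], ay = pa[2L], az = pa[3L],
               part_b = r$part_b, bx = pb[1L], by = pb[2L], bz = pb[3L],
               k = r$k, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write anatomy parts and landmarks to disk
#'
#' Each part is written as ASCII STL and PLY; the landmark set as
#' tab-delimited text (mm).
#'
#' @param model An `anatomy_model`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_anatomy <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(model$parts)) {
    write_stl(model$parts[[nm]], file.path(dir, paste0(nm, ".stl")))
    write_ply(model$parts[[nm]], file.path(dir, paste0(nm, ".ply")))
  }
  utils::write.table(model$landmarks, file.path(dir, "landmarks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
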