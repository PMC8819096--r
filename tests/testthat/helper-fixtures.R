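# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Closed unit cube surface with outward winding.
cube_surface <- function(side = 1) {
  v <- side * as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  tris <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, tris)
}

sphere_surface <- function(radius = 5, n_theta = 16, n_phi = 24) {
  carpalfem:::superellipsoid_surface(rep(radius, 3), c(0, 0, 0), 2,
                                     n_theta, n_phi)
}

# Coarse surrogate anatomy + meshes shared across tests.
coarse_config <- function(...) {
  default_shape_config(n_theta = 6L, n_phi = 8L, ...)
}

coarse_model <- function() cached("coarse_model",
  generate_reduced_wrist(coarse_config(), seed = 1L))

coarse_mesh <- function() cached("coarse_mesh",
  mesh_anatomy(coarse_model(), target_edge = 4))

default_model <- function() cached("default_model",
  generate_reduced_wrist(default_shape_config(), seed = 1L))

# Unit-cube tet mesh for FEM unit tests.
cube_mesh <- function(target_edge = 2) tetrahedralize(cube_surface(), target_edge)

# Uniaxial-stretch rig on the unit cube: symmetry planes on x=0/y=0/z=0,
# prescribed z-displacement on z=1, lateral faces free.
uniaxial_case <- function(mat, stretch, steps = 5) {
  cube <- cube_mesh()
  xs <- cube$nodes
  dof <- function(i, c) 3 * (i - 1) + c
  bcs <- list(
    fixed = integer(0), prescribed = integer(0), target = numeric(3),
    ramp = seq_len(steps) / steps,
    fixed_dofs = c(dof(which(abs(xs[, 1]) < 1e-9), 1),
                   dof(which(abs(xs[, 2]) < 1e-9), 2),
                   dof(which(abs(xs[, 3]) < 1e-9), 3)),
    prescribed_dofs = dof(which(abs(xs[, 3] - 1) < 1e-9), 3))
  bcs$prescribed_values <- rep(stretch - 1, length(bcs$prescribed_dofs))
  simulation_case(cube, list(solid = mat), bcs = bcs)
}

random_deformation_gradient <- function(max_dev = 0.3) {
  repeat {
    F <- diag(3) + matrix(stats::runif(9, -max_dev, max_dev), 3, 3)
    if (det(F) > 0.2) return(F)
  }
}
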