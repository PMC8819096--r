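# Implicit nonlinear solution: Newton-Raphson with load stepping and step
# bisection, mechanism (under-constraint) detection by tangent
# eigen-analysis, and the reduced radius-only load study.

# Constrained-dof bookkeeping.  Beyond whole-node sets (`fixed`,
# `prescribed` + `target` translation), a bc list may carry per-dof
# constraints: `fixed_dofs` (held at zero) and `prescribed_dofs` with
# `prescribed_values` (ramped), enabling symmetry planes and uniaxial rigs.
constraint_dofs <- function(bcs) {
  fixed <- c(node_dofs(bcs$fixed),
             if (!is.null(bcs$fixed_dofs)) as.integer(bcs$fixed_dofs))
  pres <- c(node_dofs(bcs$prescribed),
            if (!is.null(bcs$prescribed_dofs)) as.integer(bcs$prescribed_dofs))
  target <- c(rep(as.numeric(bcs$target), length(bcs$prescribed)),
              if (!is.null(bcs$prescribed_values))
                as.numeric(bcs$prescribed_values))
  if (length(intersect(fixed, pres)))
    stop("fixed and prescribed dof sets must be disjoint")
  list(fixed = fixed, prescribed = pres, target = target)
}

# Backtracking line search on the Newton increment: halve the step while it
# inverts an element or increases the free residual norm.  Full steps are
# taken near the solution, preserving Newton's local convergence rate.
newton_backtrack <- function(case, u, free, du, rn_current, max_halving = 5L) {
  alpha <- 1
  for (k in seq_len(max_halving + 1L)) {
    u_trial <- u
    u_trial[free] <- u_trial[free] + alpha * du
    asm <- assemble(case, u_trial, want_tangent = FALSE)
    if (asm$inverted == 0) {
      rn <- sqrt(sum(asm$residual[free]^2))
      if (rn <= rn_current * (1 + 1e-8) || k > max_halving) return(alpha * du)
    }
    alpha <- alpha / 2
  }
  alpha * du
}

#' Solve a simulation case by load-stepped Newton-Raphson
#'
#' Prescribed displacements are ramped by the BC schedule; each step is
#' solved to a relative residual below `rel_tol` (absolute fallback
#' `abs_tol`).  A non-converged or element-inverting step is retried with up
#' to `max_bisect` bisections; persistent failure terminates the run with a
#' structured divergence record (this is an observable result, not an
#' error).
#'
#' @param case A `simulation_case`.
#' @return A `field_result`: per-step displacements `u` (list of 3n
#'   vectors), per-step element Cauchy stresses (Voigt n_el x 6, MPa),
#'   `convergence` log (step, iterations, residual norms), `diverged` flag
#'   with `divergence` record, `reactions` at fixed nodes for the last
#'   converged step, and the originating `case`.
#' @export
newton_solve <- function(case) {
  mesh <- case$mesh
  st <- case$settings
  n <- nrow(mesh$nodes)
  bcs <- case$bcs
  cd <- constraint_dofs(bcs)
  fixed_dofs <- cd$fixed
  pres_dofs <- cd$prescribed
  target <- cd$target
  free <- setdiff(seq_len(3L * n), c(fixed_dofs, pres_dofs))
  u <- numeric(3L * n)
  ramp <- bcs$ramp
  results_u <- list()
  results_sig <- list()
  log_rows <- list()
  diverged <- FALSE
  divergence <- NULL

  solve_to <- function(u_start, frac_from, frac_to, depth) {
    # returns list(u=, ok=, log=) solving one increment, recursing on bisection
    u_try <- u_start
    u_try[pres_dofs] <- frac_to * target
    ok <- FALSE
    norms <- numeric(0)
    r0 <- NA_real_
    for (it in seq_len(st$max_iter)) {
      asm <- assemble(case, u_try)
      if (asm$inverted > 0) {
        norms <- c(norms, Inf)
        break
      }
      r_free <- asm$residual[free]
      rn <- sqrt(sum(r_free^2))
      norms <- c(norms, rn)
      if (it == 1L) r0 <- max(rn, st$abs_tol)
      if (rn <= st$rel_tol * r0 || rn <= st$abs_tol) { ok <- TRUE; break }
      Kff <- asm$tangent[free, free, drop = FALSE]
      du <- tryCatch(
        as.numeric(Matrix::solve(Kff, -r_free)),
        error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      u_try[free] <- u_try[free] + newton_backtrack(case, u_try, free, du, rn)
    }
    if (ok)
      return(list(u = u_try, ok = TRUE,
                  log = data.frame(from = frac_from, to = frac_to,
                                   iterations = length(norms),
                                   residual = norms[length(norms)],
                                   first_residual = norms[1L])))
    if (depth >= st$max_bisect)
      return(list(u = u_start, ok = FALSE,
                  log = data.frame(from = frac_from, to = frac_to,
                                   iterations = length(norms),
                                   residual = norms[length(norms)],
                                   first_residual = norms[1L])))
    mid <- (frac_from + frac_to) / 2
    first <- solve_to(u_start, frac_from, mid, depth + 1L)
    if (!first$ok) return(first)
    second <- solve_to(first$u, mid, frac_to, depth + 1L)
    second$log <- rbind(first$log, second$log)
    second
  }

  frac_prev <- 0
  for (s in seq_along(ramp)) {
    res <- solve_to(u, frac_prev, ramp[s], 0L)
    log_rows[[s]] <- cbind(step = s, res$log)
    if (!res$ok) {
      diverged <- TRUE
      divergence <- list(step = s, fraction = ramp[s],
                         log = do.call(rbind, log_rows))
      break
    }
    u <- res$u
    frac_prev <- ramp[s]
    results_u[[length(results_u) + 1L]] <- u
    results_sig[[length(results_sig) + 1L]] <-
      .tet4_stress_cpp(mesh$nodes, mesh$tets, u, case$matcode, case$matpar)
  }
  reactions <- NULL
  if (length(results_u)) {
    asm <- assemble(case, results_u[[length(results_u)]], want_tangent = FALSE)
    reactions <- matrix(asm$residual[node_dofs(bcs$fixed)], ncol = 3L,
                        byrow = TRUE)
  }
  structure(list(u = results_u, stress = results_sig,
                 convergence = do.call(rbind, log_rows),
                 diverged = diverged, divergence = divergence,
                 reactions = reactions, case = case,
                 steps_completed = length(results_u)),
            class = "field_result")
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf("field_result: %d/%d steps converged%s\n",
              x$steps_completed, length(x$case$bcs$ramp),
              if (x$diverged) sprintf(" (DIVERGED at step %d)",
                                      x$divergence$step) else ""))
  invisible(x)
}

#' Count near-zero-energy modes of the constrained tangent
#'
#' Assembles the tangent at the reference configuration with the boundary
#' conditions applied (fixed and prescribed dofs eliminated) and counts
#' eigenvalues below `tol` times the largest one.  Zero means the structure
#' is fully constrained; each counted mode is an unresisted (mechanism)
#' freedom.
#'
#' @param case A `simulation_case`.
#' @param tol Relative eigenvalue threshold (default 1e-11; rigid mechanism modes sit at the numerical-zero floor of order 1e-15 of the largest eigenvalue, while the softest genuine elastic modes of the default model are above 1e-9 of it).
#' @return Integer mode count, with attribute `eigenvalues` (the smallest
#'   twelve).
#' @export
detect_mechanism <- function(case, tol = 1e-11) {
  n <- nrow(case$mesh$nodes)
  asm <- assemble(case, numeric(3L * n))
  cd <- constraint_dofs(case$bcs)
  free <- setdiff(seq_len(3L * n), c(cd$fixed, cd$prescribed))
  if (!length(free)) {
    count <- 0L
    attr(count, "eigenvalues") <- numeric(0)
    return(count)
  }
  Kff <- as.matrix(asm$tangent[free, free, drop = FALSE])
  Kff <- (Kff + t(Kff)) / 2
  ev <- eigen(Kff, symmetric = TRUE, only.values = TRUE)$values
  emax <- max(abs(ev))
  count <- sum(ev < tol * emax)
  attr(count, "eigenvalues") <- sort(ev)[seq_len(min(12L, length(ev)))]
  count
}

# External nodal force vector from unit outward pressure on labelled
# boundary faces: each face contributes -p * area * normal / 3 per node
# (pressure pushes against the outward normal).
pressure_load <- function(mesh, faces, pressure) {
  f <- numeric(3L * nrow(mesh$nodes))
  for (i in seq_len(nrow(faces))) {
    tv <- faces[i, ]
    p <- mesh$nodes[tv, , drop = FALSE]
    nrm <- cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ]) / 2  # area-weighted
    for (a in 1:3) {
      dofs <- 3L * (tv[a] - 1L) + 1:3
      f[dofs] <- f[dofs] - pressure * nrm / 3
    }
  }
  f
}

#' Reduced radius-only load study
#'
#' Meshes the radius alone (cortical shell, cancellous core, distal
#' cartilage), fixes its proximal face, applies unit pressure patches on the
#' two articular fossa regions of the cartilage (scaphoid side x < 0, lunate
#' side x > 0), solves, and partitions the elastic strain energy by region.
#'
#' @param model An `anatomy_model`.
#' @param target_edge Mesh edge length (mm).
#' @param pressure Patch pressure magnitude (MPa); unit by default.
#' @param materials Material library; the cortical shell uses the
#'   `cortical_literature` entry by default (the tabulated 18 MPa cortical
#'   modulus is softer than cancellous bone and cannot separate the shell
#'   from the core; see the package vignette).
#' @param cortical_entry Library entry name for the cortical shell.
#' @param steps Load steps.
#' @return List: `result` (a `field_result`), `energy_fraction` (named,
#'   cortical/cancellous/cartilage), `max_disp_node`, `loaded_nodes`,
#'   `case`.
#' @export
run_reduced_radius_study <- function(model, target_edge = 3, pressure = 1,
                                     materials = material_library(),
                                     cortical_entry = "cortical_literature",
                                     steps = 2L) {
  mesh <- mesh_anatomy(model, target_edge, parts_only = "radius")
  bnd <- boundary_faces(mesh, "radius_cartilage")
  # outer articular faces: all three vertices on the extruded (offset) layer
  top_nodes <- setdiff(part_nodes(mesh, "radius_cartilage"),
                       part_nodes(mesh, "radius"))
  outer_f <- bnd$triangles[, 1L] %in% top_nodes &
    bnd$triangles[, 2L] %in% top_nodes &
    bnd$triangles[, 3L] %in% top_nodes
  tri_cent <- (mesh$nodes[bnd$triangles[, 1L], , drop = FALSE] +
               mesh$nodes[bnd$triangles[, 2L], , drop = FALSE] +
               mesh$nodes[bnd$triangles[, 3L], , drop = FALSE]) / 3
  margin <- 0.5 * model$config$scale
  scaph_f <- outer_f & tri_cent[, 1L] < -margin
  lun_f <- outer_f & tri_cent[, 1L] > margin
  if (!any(scaph_f) || !any(lun_f))
    stop("could not identify the two fossa load patches")
  fext <- pressure_load(mesh, bnd$triangles[scaph_f, , drop = FALSE], pressure) +
    pressure_load(mesh, bnd$triangles[lun_f, , drop = FALSE], pressure)
  rad_nodes <- part_nodes(mesh, "radius")
  zmin <- min(mesh$nodes[rad_nodes, 3L])
  fixed <- rad_nodes[mesh$nodes[rad_nodes, 3L] <= zmin + 1.0]
  bcs <- list(fixed = fixed, prescribed = integer(0), target = numeric(3),
              ramp = seq_len(steps) / steps)
  mats <- list(cortical = materials[[cortical_entry]],
               cancellous = materials$cancellous,
               radius_cartilage = materials$cartilage)
  case <- simulation_case(mesh, mats, springs = NULL, bcs = bcs,
                          external_force = fext)
  # external load ramps with the schedule
  res <- newton_solve_scaled_load(case)
  if (res$diverged) return(list(result = res, case = case))
  en <- assemble(case, res$u[[res$steps_completed]],
                 want_tangent = FALSE)$elem_energy
  key <- ifelse(mesh$part == "radius", mesh$region, mesh$part)
  efrac <- tapply(en, key, sum) / sum(en)
  names(efrac)[names(efrac) == "radius_cartilage"] <- "cartilage"
  umat <- matrix(res$u[[res$steps_completed]], ncol = 3L, byrow = TRUE)
  umag <- sqrt(rowSums(umat^2))
  loaded_nodes <- sort(unique(as.vector(
    bnd$triangles[scaph_f | lun_f, , drop = FALSE])))
  list(result = res, energy_fraction = efrac,
       max_disp_node = which.max(umag), disp_magnitude = umag,
       loaded_nodes = loaded_nodes, case = case)
}

# Newton solve where the constant external force, not a prescribed
# displacement, is ramped by the schedule.
newton_solve_scaled_load <- function(case) {
  full_ext <- case$external_force
  bcs <- case$bcs
  ramp <- bcs$ramp
  sub <- case
  results_u <- list(); results_sig <- list(); log_rows <- list()
  u <- numeric(3L * nrow(case$mesh$nodes))
  diverged <- FALSE; divergence <- NULL
  for (s in seq_along(ramp)) {
    sub$external_force <- ramp[s] * full_ext
    sub$bcs$ramp <- 1
    one <- newton_solve_from(sub, u)
    log_rows[[s]] <- cbind(step = s, one$log)
    if (!one$ok) {
      diverged <- TRUE
      divergence <- list(step = s, fraction = ramp[s],
                         log = do.call(rbind, log_rows))
      break
    }
    u <- one$u
    results_u[[length(results_u) + 1L]] <- u
    results_sig[[length(results_sig) + 1L]] <-
      .tet4_stress_cpp(case$mesh$nodes, case$mesh$tets, u, case$matcode,
                       case$matpar)
  }
  structure(list(u = results_u, stress = results_sig,
                 convergence = do.call(rbind, log_rows),
                 diverged = diverged, divergence = divergence,
                 reactions = NULL, case = case,
                 steps_completed = length(results_u)),
            class = "field_result")
}

# Single Newton solve from a warm start (helper for load-ramped cases).
newton_solve_from <- function(case, u_start) {
  st <- case$settings
  n <- nrow(case$mesh$nodes)
  cd <- constraint_dofs(case$bcs)
  free <- setdiff(seq_len(3L * n), c(cd$fixed, cd$prescribed))
  u <- u_start
  norms <- numeric(0)
  ok <- FALSE
  r0 <- NA_real_
  for (it in seq_len(st$max_iter)) {
    asm <- assemble(case, u)
    if (asm$inverted > 0) { norms <- c(norms, Inf); break }
    r_free <- asm$residual[free]
    rn <- sqrt(sum(r_free^2))
    norms <- c(norms, rn)
    if (it == 1L) r0 <- max(rn, st$abs_tol)
    if (rn <= st$rel_tol * r0 || rn <= st$abs_tol) { ok <- TRUE; break }
    du <- tryCatch(as.numeric(Matrix::solve(asm$tangent[free, free],
                                            -r_free)),
                   error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) break
    u[free] <- u[free] + newton_backtrack(case, u, free, du, rn)
  }
  list(u = u, ok = ok,
       log = data.frame(iterations = length(norms),
                        residual = norms[length(norms)],
                        first_residual = norms[1L]))
}

#' SLIL stabilizing-role study
#'
#' Builds the default carpus twice -- with and without the SLIL block -- and
#' compares (i) the mechanism mode count of the constrained reference
#' tangent and (ii) Newton convergence under a small probe fraction of the
#' extension motion.  A mechanism fails at any load level, so the probe load
#' separates a stabilized complex (converges, zero modes) from an
#' under-constrained one (near-zero-energy modes and/or divergence) without
#' entangling the diagnosis with large-displacement attachment overload.
#'
#' @param model An `anatomy_model`.
#' @param target_edge Mesh edge length (mm).
#' @param probe_fraction Fraction of the full extension displacement used as
#'   the probe load (default 0.01).
#' @param materials Material library (printed bone moduli by default).
#' @param motion Probe motion (default "extension").
#' @param mode_tol Eigenvalue threshold for [detect_mechanism()].
#' @return List with `with_slil` and `without_slil`, each carrying
#'   `mechanism_modes`, `converged`, `result`; plus the meshes.
#' @export
slil_stability_study <- function(model, target_edge = 3,
                                 probe_fraction = 0.01,
                                 materials = material_library(),
                                 motion = "extension", mode_tol = 1e-11) {
  full <- mesh_anatomy(model, target_edge)
  run_one <- function(mesh) {
    bcs <- build_bc_set(mesh, motion, steps = 4L, r_mm = model$lever_arm_r)
    bcs$target <- probe_fraction * bcs$target
    springs <- build_spring_set(model$landmarks, mesh)
    mats <- list(cortical = materials$cortical,
                 cancellous = materials$cancellous,
                 scaphoid = materials$cortical,
                 lunate = materials$cortical,
                 capitate = materials$cortical,
                 radius_cartilage = materials$cartilage,
                 scaphoid_cartilage = materials$cartilage,
                 lunate_cartilage = materials$cartilage,
                 capitate_cartilage = materials$cartilage,
                 slil = materials$slil)
    mats <- mats[intersect(names(mats),
                           unique(c(mesh$part, mesh$region)))]
    case <- simulation_case(mesh, mats, springs = springs, bcs = bcs)
    modes <- detect_mechanism(case, tol = mode_tol)
    res <- newton_solve(case)
    list(mechanism_modes = as.integer(modes),
         eigenvalues = attr(modes, "eigenvalues"),
         converged = !res$diverged, result = res, case = case)
  }
  no_slil <- remove_part(full, "slil")
  attr(no_slil, "surface_node") <- NULL
  attr(no_slil, "target_edge") <- attr(full, "target_edge")
  list(with_slil = run_one(full),
       without_slil = run_one(no_slil),
       mesh = full, mesh_no_slil = no_slil)
}
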