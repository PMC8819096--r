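# Simulation case assembly: meshes + materials + springs + boundary
# conditions + optional penalty contact, and the global residual/tangent.

#' Default solver settings
#' @param ... Overrides: `rel_tol` (relative residual, default 1e-6),
#'   `abs_tol` (absolute fallback, N, default 1e-9), `max_iter` (per step,
#'   default 25), `max_bisect` (step bisections on divergence, default 3),
#'   `fd_rel` (element finite-difference tangent scale, default 1e-6).
#' @return Named list.
#' @export
solver_settings <- function(...) {
  utils::modifyList(list(rel_tol = 1e-6, abs_tol = 1e-9, max_iter = 25L,
                         max_bisect = 3L, fd_rel = 1e-6), list(...))
}

#' Frictionless node-to-triangle penalty contact pair
#' @param slave_part Part whose boundary nodes are checked for penetration.
#' @param master_part Part whose boundary triangles resist it.
#' @param penalty Penalty stiffness (N/mm per node), positive.
#' @param search_radius Max node-triangle distance considered (mm).
#' @return A `contact_pair`.
#' @export
contact_pair <- function(slave_part, master_part, penalty, search_radius = 5) {
  if (penalty <= 0) stop("contact penalty must be positive")
  structure(list(slave_part = slave_part, master_part = master_part,
                 penalty = penalty, search_radius = search_radius),
            class = "contact_pair")
}

#' Assemble a simulation case
#'
#' @param mesh A `volume_mesh`.
#' @param materials Named list of `material` objects, one per part tag (for
#'   the radius, per region tag `cortical`/`cancellous`).
#' @param springs Optional `spring_set`.
#' @param bcs A `bc_set`, or a list with `fixed`, `prescribed`, `target`,
#'   `ramp` for non-motion cases.
#' @param contacts List of `contact_pair`s (default none).
#' @param external_force Optional 3n vector of constant external nodal
#'   forces (N), e.g. from pressure patches.
#' @param settings From [solver_settings()].
#' @return A `simulation_case`.
#' @export
simulation_case <- function(mesh, materials, springs = NULL, bcs,
                            contacts = list(), external_force = NULL,
                            settings = solver_settings()) {
  key <- if (is.null(mesh$region)) mesh$part
         else ifelse(mesh$part == "radius", mesh$region, mesh$part)
  missing <- setdiff(unique(key), names(materials))
  if (length(missing))
    stop("no material for part/region: ", paste(missing, collapse = ", "))
  n <- nrow(mesh$nodes)
  for (nm in c("fixed", "prescribed"))
    if (length(bcs[[nm]]) && (min(bcs[[nm]]) < 1L || max(bcs[[nm]]) > n))
      stop("BC node set '", nm, "' references nodes outside the mesh")
  if (length(intersect(bcs$fixed, bcs$prescribed)))
    stop("fixed and prescribed node sets must be disjoint")
  if (is.null(external_force)) external_force <- numeric(3L * n)
  # per-element material code/parameter table for the kernels
  matcode <- integer(nrow(mesh$tets))
  matpar <- matrix(0, nrow(mesh$tets), 3L)
  for (k in unique(key)) {
    m <- materials[[k]]
    sel <- key == k
    if (m$kind == "linear") {
      matcode[sel] <- 0L
      matpar[sel, 1L] <- m$lambda
      matpar[sel, 2L] <- m$mu
    } else {
      matcode[sel] <- 1L
      matpar[sel, ] <- matrix(c(m$C1, m$C2, m$K), sum(sel), 3L, byrow = TRUE)
    }
  }
  structure(list(mesh = mesh, materials = materials, springs = springs,
                 bcs = bcs, contacts = contacts,
                 external_force = external_force,
                 settings = settings,
                 matcode = matcode, matpar = matpar),
            class = "simulation_case")
}

#' @export
print.simulation_case <- function(x, ...) {
  cat(sprintf("simulation_case: %d nodes, %d elements, %d springs, %d contact pairs\n",
              nrow(x$mesh$nodes), nrow(x$mesh$tets),
              if (is.null(x$springs)) 0L else length(x$springs$springs),
              length(x$contacts)))
  invisible(x)
}

# Contact forces/tangent triplets (frictionless node-to-triangle penalty).
contact_assemble <- function(case, u, want_tangent = TRUE) {
  mesh <- case$mesh
  n <- nrow(mesh$nodes)
  f <- numeric(3L * n)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  cur <- mesh$nodes + matrix(u, ncol = 3L, byrow = TRUE)
  for (cp in case$contacts) {
    sb <- boundary_faces(mesh, cp$slave_part)
    mb <- boundary_faces(mesh, cp$master_part)
    snodes <- setdiff(sort(unique(as.vector(sb$triangles))),
                      sort(unique(as.vector(mb$triangles))))
    mtris <- mb$triangles
    mcent <- (cur[mtris[, 1L], , drop = FALSE] +
              cur[mtris[, 2L], , drop = FALSE] +
              cur[mtris[, 3L], , drop = FALSE]) / 3
    for (s in snodes) {
      xs <- cur[s, ]
      d2 <- rowSums(sweep(mcent, 2L, xs, "-")^2)
      cand <- which(d2 < cp$search_radius^2)
      if (!length(cand)) next
      tbest <- cand[which.min(d2[cand])]
      tv <- mtris[tbest, ]
      p1 <- cur[tv[1L], ]; p2 <- cur[tv[2L], ]; p3 <- cur[tv[3L], ]
      nrm <- cross3(p2 - p1, p3 - p1)
      nn <- norm3(nrm)
      if (nn <= 0) next
      nrm <- nrm / nn
      g <- sum((xs - p1) * nrm)          # signed gap along outward normal
      if (g >= 0) next
      # barycentric weights of the projection (clamped usage: forces only)
      A <- cbind(p2 - p1, p3 - p1)
      rhs <- (xs - g * nrm) - p1
      ab <- tryCatch(solve(crossprod(A), crossprod(A, rhs)),
                     error = function(e) c(1 / 3, 1 / 3))
      w <- c(1 - sum(ab), ab)
      w <- pmax(pmin(w, 1), 0); w <- w / sum(w)
      fmag <- cp$penalty * (-g)
      sd <- 3L * (s - 1L) + 1:3
      f[sd] <- f[sd] - fmag * nrm        # internal force opposes push-out
      for (a in 1:3) {
        md <- 3L * (tv[a] - 1L) + 1:3
        f[md] <- f[md] + w[a] * fmag * nrm
      }
      if (want_tangent) {
        # Gauss-Newton penalty tangent: kp * (n n^T) on the gap dofs
        kp <- cp$penalty * outer(nrm, nrm)
        dofs <- c(sd, 3L * (tv[1L] - 1L) + 1:3, 3L * (tv[2L] - 1L) + 1:3,
                  3L * (tv[3L] - 1L) + 1:3)
        wts <- c(1, -w)
        for (a in 1:4) for (b in 1:4) {
          blk <- wts[a] * wts[b] * kp
          ti <- c(ti, rep(dofs[3L * (a - 1L) + 1:3], each = 3L))
          tj <- c(tj, rep(dofs[3L * (b - 1L) + 1:3], times = 3L))
          tx <- c(tx, as.vector(t(blk)))
        }
      }
    }
  }
  list(f = f, ti = ti, tj = tj, tx = tx)
}

#' Assemble the global residual and tangent
#'
#' Residual = internal forces (elements + springs + contact) minus external
#' forces; the tangent is the consistent linearization (symmetric for this
#' conservative, frictionless system).
#'
#' @param case A `simulation_case`.
#' @param u Current nodal displacement vector (3n, mm).
#' @param external External force vector (3n, N); defaults to the case's.
#' @param want_tangent Assemble the sparse tangent too?
#' @return List: `residual` (3n), `tangent` (sparse dsCMatrix or NULL),
#'   `energy` (total elastic strain energy, mJ), `elem_energy`,
#'   `inverted` (0 or the 1-based index of the first inverted element).
#' @export
assemble <- function(case, u, external = NULL, want_tangent = TRUE) {
  mesh <- case$mesh
  n <- nrow(mesh$nodes)
  if (length(u) != 3L * n) stop("u must have length 3 * n_nodes")
  if (is.null(external)) external <- case$external_force
  el <- .tet4_assemble_cpp(mesh$nodes, mesh$tets, u, case$matcode,
                           case$matpar, want_tangent, case$settings$fd_rel)
  if (el$inverted > 0)
    return(list(residual = NULL, tangent = NULL, energy = NA_real_,
                elem_energy = NULL, inverted = el$inverted))
  f <- el$f
  ti <- el$ti; tj <- el$tj; tx <- el$tx
  if (!is.null(case$springs)) {
    sa <- spring_assemble(case$springs, mesh$nodes, u, want_tangent)
    f <- f + sa$f
    ti <- c(ti, sa$ti); tj <- c(tj, sa$tj); tx <- c(tx, sa$tx)
  }
  if (length(case$contacts)) {
    ca <- contact_assemble(case, u, want_tangent)
    f <- f + ca$f
    ti <- c(ti, ca$ti); tj <- c(tj, ca$tj); tx <- c(tx, ca$tx)
  }
  K <- NULL
  if (want_tangent)
    K <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(3L * n, 3L * n),
                              symmetric = FALSE)
  list(residual = f - external, tangent = K, energy = sum(el$energy),
       elem_energy = el$energy, inverted = 0L)
}

# DOF indices (1-based into the 3n vector) of a node set.
node_dofs <- function(nodes_idx) {
  as.vector(t(outer(3L * (nodes_idx - 1L), 1:3, "+")))
}
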