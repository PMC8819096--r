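# Motion-derived boundary conditions: wrist range-of-motion table, the
# rotation-to-displacement conversion on the capitate lever arm, and the
# fixed/prescribed node-set construction.

#' Wrist range-of-motion table
#'
#' Average angular ranges (degrees) of the main wrist motions.  Pronation
#' and supination are stored for completeness but are not simulated (they do
#' not involve the scapholunate joint).
#'
#' @return Named list of `c(lower, upper)` ranges in degrees.
#' @export
rom_table <- function() {
  list(flexion = c(65, 80), extension = c(55, 75),
       radial = c(15, 25), ulnar = c(30, 45),
       pronation = c(60, 80), supination = c(60, 85))
}

#' Motion angle from the ROM table
#'
#' @param motion One of "flexion", "extension", "radial", "ulnar".
#' @param rom A ROM table from [rom_table()].
#' @param policy "midpoint" (default; the range midpoint), "lower", "upper",
#'   or "explicit" (returns `angle`).
#' @param angle Explicit angle (degrees) when `policy = "explicit"`.
#' @return Angle in degrees.
#' @export
#' @examples
#' motion_angle("extension")  # 65
motion_angle <- function(motion, rom = rom_table(),
                         policy = c("midpoint", "lower", "upper", "explicit"),
                         angle = NULL) {
  policy <- match.arg(policy)
  if (!motion %in% c("flexion", "extension", "radial", "ulnar"))
    stop("unknown motion '", motion, "' (pronation-supination is not simulated)")
  r <- rom[[motion]]
  if (is.null(r) || r[1L] >= r[2L] || any(r <= 0))
    stop("invalid ROM range for motion '", motion, "'")
  switch(policy,
         midpoint = mean(r),
         lower = r[1L],
         upper = r[2L],
         explicit = {
           if (is.null(angle)) stop("policy 'explicit' requires angle")
           angle
         })
}

#' Convert a wrist rotation into a prescribed cartesian displacement
#'
#' A rotation by theta about the wrist centre moves the capitate application
#' node (at lever arm r) along the chord: tangential component r sin(theta)
#' with a motion-dependent sign and axis (extension: -y dorsal; flexion: +y
#' volar; radial deviation: -x; ulnar deviation: +x) and axial component
#' -r (1 - cos(theta)) on z (toward the radius) for every motion.
#'
#' @param angle_deg Rotation angle in degrees, in (0, 180).
#' @param r_mm Lever arm (mm), positive; default 19.40 mm.
#' @param motion One of "flexion", "extension", "radial", "ulnar".
#' @return Displacement vector `c(x, y, z)` in mm.
#' @export
#' @examples
#' rotation_to_displacement(65, 19.40, "extension")  # c(0, -17.58, -11.20)
rotation_to_displacement <- function(angle_deg, r_mm = 19.40, motion) {
  if (!is.numeric(angle_deg) || angle_deg < 0 || angle_deg >= 180)
    stop("angle must lie in [0, 180) degrees")
  if (!is.numeric(r_mm) || r_mm <= 0) stop("lever arm r must be positive")
  th <- angle_deg * pi / 180
  tangential <- r_mm * sin(th)
  axial <- -r_mm * (1 - cos(th))
  d <- switch(motion,
              extension = c(0, -tangential, axial),
              flexion = c(0, tangential, axial),
              radial = c(-tangential, 0, axial),
              ulnar = c(tangential, 0, axial),
              stop("unknown motion '", motion, "'"))
  names(d) <- c("x", "y", "z")
  d
}

#' Reference displacement table for the four simulated motions
#'
#' The (tangential, axial) displacement pairs at the ROM midpoints with the
#' default lever arm, as applied to the capitate.
#'
#' @param r_mm Lever arm (mm).
#' @param rom ROM table.
#' @return Data frame: motion, angle_deg, x, y, z (mm).
#' @export
displacement_table <- function(r_mm = 19.40, rom = rom_table()) {
  motions <- c("extension", "flexion", "radial", "ulnar")
  do.call(rbind, lapply(motions, function(m) {
    a <- motion_angle(m, rom)
    d <- rotation_to_displacement(a, r_mm, m)
    data.frame(motion = m, angle_deg = a, x = d[1L], y = d[2L], z = d[3L],
               row.names = NULL)
  }))
}

#' Least-squares lever arm from a displacement table
#'
#' Recovers r from (tangential, axial) = (r sin(theta), -r (1 - cos(theta)))
#' over all table entries, in the least-squares sense.
#'
#' @param table Data frame with columns motion, angle_deg, x, y, z as from
#'   [displacement_table()].
#' @return Fitted r (mm).
#' @export
fit_lever_arm <- function(table) {
  basis <- c(); obs <- c()
  for (i in seq_len(nrow(table))) {
    th <- table$angle_deg[i] * pi / 180
    tang <- switch(table$motion[i],
                   extension = -table$y[i], flexion = table$y[i],
                   radial = -table$x[i], ulnar = table$x[i])
    basis <- c(basis, sin(th), 1 - cos(th))
    obs <- c(obs, tang, -table$z[i])
  }
  sum(obs * basis) / sum(basis^2)
}

#' Build the boundary-condition set for a motion case
#'
#' The proximal face of the radius is fully fixed (all translational degrees
#' of freedom zero; tet4 nodes carry no rotational ones).  All capitate
#' nodes receive a uniform prescribed translation equal to the
#' rotation-to-displacement conversion, linearly ramped over the load steps
#' (the distal carpal row is taken to move as a rigid solid with the
#' capitate).
#'
#' @param mesh A `volume_mesh` from [mesh_anatomy()] containing `radius` and
#'   `capitate` parts.
#' @param motion One of "flexion", "extension", "radial", "ulnar".
#' @param steps Number of load steps (>= 1).
#' @param r_mm Lever arm (mm).
#' @param rom ROM table.
#' @param policy Angle policy (see [motion_angle()]).
#' @param angle Explicit angle for `policy = "explicit"`.
#' @param plane_tol Thickness (mm) of the proximal-plane node selection.
#' @return A `bc_set`: `fixed` (node ids), `prescribed` (node ids), `target`
#'   (displacement vector, mm), `ramp` (step fractions ending at 1),
#'   `motion`, `angle_deg`.
#' @export
build_bc_set <- function(mesh, motion, steps = 10L, r_mm = 19.40,
                         rom = rom_table(), policy = "midpoint", angle = NULL,
                         plane_tol = 1.0) {
  for (p in c("radius", "capitate"))
    if (!p %in% mesh$part) stop("mesh has no part named '", p, "'")
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  a <- motion_angle(motion, rom, policy, angle)
  target <- rotation_to_displacement(a, r_mm, motion)
  rad_nodes <- part_nodes(mesh, "radius")
  zmin <- min(mesh$nodes[rad_nodes, 3L])
  fixed <- rad_nodes[mesh$nodes[rad_nodes, 3L] <= zmin + plane_tol]
  prescribed <- part_nodes(mesh, "capitate")
  prescribed <- setdiff(prescribed, fixed)
  if (!length(fixed) || !length(prescribed))
    stop("empty fixed or prescribed node selection")
  structure(list(fixed = fixed, prescribed = prescribed,
                 target = target, ramp = seq_len(steps) / steps,
                 motion = motion, angle_deg = a),
            class = "bc_set")
}

#' @export
print.bc_set <- function(x, ...) {
  cat(sprintf("bc_set: %s %.1f deg | %d fixed nodes | %d prescribed nodes | target (%.2f, %.2f, %.2f) mm | %d steps\n",
              x$motion, x$angle_deg, length(x$fixed), length(x$prescribed),
              x$target[1L], x$target[2L], x$target[3L], length(x$ramp)))
  invisible(x)
}
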