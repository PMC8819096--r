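# The ligament spring network: linear axial spring elements attached at
# single bone-surface nodes, with stiffnesses from the ligament table.

#' Ligament stiffness table
#'
#' The nine-row ligament table used for the spring network (stiffness in
#' N/mm); the combined volar radioscapholunate row is expanded into its
#' radius-scaphoid and radius-lunate branches, both carrying the row
#' stiffness 50.75 N/mm.  The short radiolunate row connects radius and
#' scaphoid as tabulated (the connection is kept as printed; override via
#' `stiffness_table` arguments where a corrected network is wanted).
#'
#' @return Data frame: name, part_a, part_b, tag, k.
#' @export
ligament_stiffness_table <- function() ligament_rows()

#' Construct a single spring element
#' @param name Ligament name.
#' @param node_a,node_b Distinct mesh node indices.
#' @param k Stiffness (N/mm), positive.
#' @param rest_length Rest length (mm), non-negative.
#' @param tension_only If TRUE the spring carries no force when shorter than
#'   its rest length (slack ligament); default FALSE (linear spring).
#' @return A `spring_element`.
#' @export
spring_element <- function(name, node_a, node_b, k, rest_length,
                           tension_only = FALSE) {
  if (!is.numeric(k) || k <= 0) stop("spring stiffness k must be positive")
  if (rest_length < 0) stop("rest_length must be non-negative")
  if (node_a == node_b) stop("spring endpoints must be distinct nodes")
  structure(list(name = name, node_a = as.integer(node_a),
                 node_b = as.integer(node_b), k = k,
                 rest_length = rest_length,
                 tension_only = isTRUE(tension_only)),
            class = "spring_element")
}

#' Build the ligament spring set on a meshed model
#'
#' Resolves each landmark pair to the nearest boundary node of the named
#' part and creates one spring per pair with the tabulated stiffness.  Rest
#' lengths are the as-built node distances, so all springs are unstressed in
#' the reference configuration (zero pre-strain).
#'
#' @param landmarks Landmark data frame from [place_ligament_landmarks()].
#' @param mesh A `volume_mesh` from [mesh_anatomy()].
#' @param stiffness_table Optional data frame with columns `name` and `k`
#'   overriding the tabulated stiffness values.
#' @param tolerance Max landmark-to-node snap distance (mm); defaults to the
#'   mesh target edge (or 5 mm).
#' @param tension_only Default tension flag for all springs.
#' @return A `spring_set`: list of `spring_element`s plus a provenance table.
#' @export
build_spring_set <- function(landmarks, mesh, stiffness_table = NULL,
                             tolerance = NULL, tension_only = FALSE) {
  if (is.null(tolerance)) {
    te <- attr(mesh, "target_edge")
    tolerance <- if (is.null(te)) 5 else 2 * te
  }
  k_of <- landmarks$k
  if (!is.null(stiffness_table)) {
    m <- match(landmarks$name, stiffness_table$name)
    k_of[!is.na(m)] <- stiffness_table$k[m[!is.na(m)]]
  }
  springs <- vector("list", nrow(landmarks))
  prov <- landmarks
  prov$node_a <- NA_integer_; prov$node_b <- NA_integer_
  prov$rest_length <- NA_real_
  for (i in seq_len(nrow(landmarks))) {
    lm <- landmarks[i, ]
    na <- nearest_part_node(mesh, lm$part_a, c(lm$ax, lm$ay, lm$az), tolerance)
    nb <- nearest_part_node(mesh, lm$part_b, c(lm$bx, lm$by, lm$bz), tolerance)
    L0 <- norm3(mesh$nodes[na, ] - mesh$nodes[nb, ])
    springs[[i]] <- spring_element(lm$name, na, nb, k_of[i], L0, tension_only)
    prov$node_a[i] <- na; prov$node_b[i] <- nb; prov$rest_length[i] <- L0
  }
  structure(list(springs = springs, provenance = prov), class = "spring_set")
}

#' @export
print.spring_set <- function(x, ...) {
  cat(sprintf("spring_set: %d springs, k in [%g, %g] N/mm\n",
              length(x$springs),
              min(vapply(x$springs, `[[`, 0, "k")),
              max(vapply(x$springs, `[[`, 0, "k"))))
  invisible(x)
}

#' Axial spring force pair
#'
#' Force magnitude k (L - L0) along the current axis, applied equal and
#' opposite; a tension-only spring shorter than its rest length carries zero.
#'
#' @param spring A `spring_element`.
#' @param xa,xb Current endpoint positions (length-3, mm).
#' @return List with `fa`, `fb` (forces on the two endpoints, N) and
#'   `tension` (axial force, N, positive in tension).
#' @export
spring_force <- function(spring, xa, xb) {
  d <- xb - xa
  L <- norm3(d)
  if (L <= .Machine$double.eps)
    stop("spring '", spring$name, "': coincident endpoints (zero length)")
  n <- d / L
  t <- spring$k * (L - spring$rest_length)
  if (spring$tension_only && t < 0) t <- 0
  list(fa = t * n, fb = -t * n, tension = t)
}

#' Consistent spring tangent stiffness
#'
#' Exact linearization of [spring_force()] with respect to the six endpoint
#' coordinates: material part k n n^T plus geometric part
#' (T/L)(I - n n^T), assembled in the (a, b) block pattern.  Symmetric.
#'
#' @param spring A `spring_element`.
#' @param xa,xb Current endpoint positions (mm).
#' @return 6 x 6 stiffness matrix (N/mm), ordered (ax, ay, az, bx, by, bz).
#' @export
spring_tangent <- function(spring, xa, xb) {
  d <- xb - xa
  L <- norm3(d)
  if (L <= .Machine$double.eps)
    stop("spring '", spring$name, "': coincident endpoints (zero length)")
  n <- d / L
  t <- spring$k * (L - spring$rest_length)
  slack <- spring$tension_only && t < 0
  kb <- if (slack) matrix(0, 3L, 3L)
        else spring$k * outer(n, n) + (t / L) * (diag(3) - outer(n, n))
  rbind(cbind(kb, -kb), cbind(-kb, kb))
}

# Residual contribution (internal forces, sign +internal) and sparse tangent
# triplets of a whole spring set at displacements u (3n vector).
spring_assemble <- function(spring_set, nodes, u, want_tangent = TRUE) {
  n <- nrow(nodes)
  f <- numeric(3L * n)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (sp in spring_set$springs) {
    ia <- sp$node_a; ib <- sp$node_b
    da <- 3L * (ia - 1L) + 1:3; db <- 3L * (ib - 1L) + 1:3
    xa <- nodes[ia, ] + u[da]; xb <- nodes[ib, ] + u[db]
    fr <- spring_force(sp, xa, xb)
    # internal force opposes the applied spring force
    f[da] <- f[da] - fr$fa
    f[db] <- f[db] - fr$fb
    if (want_tangent) {
      kt <- spring_tangent(sp, xa, xb)
      dofs <- c(da, db)
      ti <- c(ti, rep(dofs, each = 6L))
      tj <- c(tj, rep(dofs, times = 6L))
      tx <- c(tx, as.vector(t(kt)))
    }
  }
  list(f = f, ti = ti, tj = tj, tx = tx)
}

#' Write a spring set as delimited text
#' @param spring_set A `spring_set`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_spring_set <- function(spring_set, file) {
  utils::write.table(spring_set$provenance, file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
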