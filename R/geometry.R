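# Low-level vector/simplex geometry shared by the meshing and FEM code.
# All coordinates are millimetres; all meshes use 1-based vertex indices.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(a) sqrt(sum(a * a))

#' Signed volume of a tetrahedron
#'
#' Positive when the fourth vertex lies on the side of the oriented triangle
#' (v1, v2, v3) given by the right-hand rule.
#'
#' @param p 4 x 3 matrix of vertex coordinates (mm).
#' @return Signed volume in mm^3.
#' @export
tet_signed_volume <- function(p) {
  a <- p[2L, ] - p[1L, ]
  b <- p[3L, ] - p[1L, ]
  d <- p[4L, ] - p[1L, ]
  sum(cross3(a, b) * d) / 6
}

triangle_area <- function(p) {
  norm3(cross3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])) / 2
}

#' Triangle aspect ratio (inscribed/circumscribed circle metric)
#'
#' Computes 2 r_in / R_circ, where r_in and R_circ are the radii of the
#' inscribed and circumscribed circles.  The factor 2 normalizes the metric so
#' an equilateral triangle (for which R = 2 r) scores exactly 1; thin slivers
#' approach 0 and collinear points return 0 by definition.
#'
#' @param tri 3 x 3 matrix, one vertex per row (mm).
#' @return Quality value in [0, 1].
#' @export
#' @examples
#' triangle_aspect_ratio(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
triangle_aspect_ratio <- function(tri) {
  tri <- as.matrix(tri)
  stopifnot(nrow(tri) == 3L, ncol(tri) == 3L)
  a <- norm3(tri[2L, ] - tri[3L, ])
  b <- norm3(tri[1L, ] - tri[3L, ])
  cc <- norm3(tri[1L, ] - tri[2L, ])
  area <- triangle_area(tri)
  if (area <= 0 || a * b * cc == 0) return(0)
  s <- (a + b + cc) / 2
  r_in <- area / s
  r_circ <- a * b * cc / (4 * area)
  min(1, 2 * r_in / r_circ)
}

#' Tetrahedron quality (insphere/circumsphere metric)
#'
#' Computes 3 r_in / R_circ with r_in the insphere radius and R_circ the
#' circumsphere radius; a regular tetrahedron (R = 3 r) scores 1 and
#' degenerate (coplanar) tetrahedra score 0.
#'
#' @param tet 4 x 3 matrix, one vertex per row (mm).
#' @return Quality value in [0, 1].
#' @export
tet_quality <- function(tet) {
  tet <- as.matrix(tet)
  stopifnot(nrow(tet) == 4L, ncol(tet) == 3L)
  vol <- abs(tet_signed_volume(tet))
  faces <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  area_sum <- sum(vapply(faces, function(f) triangle_area(tet[f, ]), 0))
  if (vol <= 0 || area_sum <= 0) return(0)
  r_in <- 3 * vol / area_sum
  # circumcentre from |x - v1|^2 = |x - vi|^2, i = 2..4
  A <- 2 * (tet[2:4, , drop = FALSE] - matrix(tet[1L, ], 3L, 3L, byrow = TRUE))
  rhs <- rowSums(tet[2:4, , drop = FALSE]^2) - sum(tet[1L, ]^2)
  ctr <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(ctr)) return(0)
  r_circ <- norm3(ctr - tet[1L, ])
  min(1, 3 * r_in / r_circ)
}

tet_edge_lengths <- function(tet) {
  idx <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  apply(idx, 1L, function(ij) norm3(tet[ij[1L], ] - tet[ij[2L], ]))
}

# Uniformly distributed random rotation matrix (used by property tests and
# the lofted-perturbation generator).
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}
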