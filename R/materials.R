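# Constitutive models: linear-elastic bone, compressible two-parameter
# Mooney-Rivlin soft tissue, and the bulk-modulus/Poisson-ratio relations.
# Units are a consistent mm-N-MPa system.

#' Linear elastic material parameters
#' @param E Young's modulus (MPa), positive.
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return A `material` of kind `"linear"`.
#' @export
linear_elastic <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("E must be positive")
  if (!is.numeric(nu) || nu <= -1 || nu >= 0.5)
    stop("nu must lie in (-1, 0.5)")
  structure(list(kind = "linear", E = E, nu = nu,
                 lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
                 mu = E / (2 * (1 + nu))),
            class = "material")
}

#' Compressible Mooney-Rivlin material parameters
#'
#' Strain energy W = C1 (I1bar - 3) + C2 (I2bar - 3) + (K/2)(J - 1)^2, the
#' first-order polynomial hyperelastic model with deviatoric invariants
#' I1bar = J^(-2/3) I1, I2bar = J^(-4/3) I2 and a quadratic volumetric
#' penalty whose coefficient K/2 makes the small-strain bulk response equal K.
#'
#' @param C1 Distortional constant C10 (MPa).
#' @param C2 Distortional constant C01 (MPa).
#' @param K Bulk modulus (MPa), positive.
#' @return A `material` of kind `"mooney_rivlin"`.
#' @export
mooney_rivlin <- function(C1, C2, K) {
  if (!is.numeric(C1) || !is.numeric(C2) || C1 + C2 <= 0)
    stop("C1 + C2 must be positive")
  if (!is.numeric(K) || K <= 0) stop("K must be positive")
  structure(list(kind = "mooney_rivlin", C1 = C1, C2 = C2, K = K),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  if (x$kind == "linear")
    cat(sprintf("material: linear elastic, E = %g MPa, nu = %g\n", x$E, x$nu))
  else
    cat(sprintf("material: Mooney-Rivlin, C1 = %g, C2 = %g, K = %g MPa\n",
                x$C1, x$C2, x$K))
  invisible(x)
}

#' Bulk modulus from Young's modulus and Poisson's ratio
#'
#' K = E / (3 (1 - 2 nu)).
#'
#' @param E Young's modulus (MPa), positive.
#' @param nu Poisson's ratio, strictly below 0.5.
#' @return Bulk modulus (MPa).
#' @export
#' @examples
#' bulk_modulus(11.6, 0.4)  # articular cartilage, ~19.3 MPa
bulk_modulus <- function(E, nu) {
  if (!is.numeric(E) || E <= 0) stop("E must be positive")
  if (!is.numeric(nu) || nu >= 0.5)
    stop("nu must be below 0.5 (incompressible limit)")
  E / (3 * (1 - 2 * nu))
}

#' Poisson's ratio from Young's and bulk moduli
#'
#' Inverts K = E / (3 (1 - 2 nu)) as nu = (1 - E / (3 K)) / 2.
#'
#' @param E Young's modulus (MPa), positive.
#' @param K Bulk modulus (MPa), with K > E / 3.
#' @return Poisson's ratio.
#' @export
#' @examples
#' poisson_from_bulk(4.89, 9.19802)  # SLIL, ~0.41
poisson_from_bulk <- function(E, K) {
  if (!is.numeric(E) || E <= 0) stop("E must be positive")
  if (!is.numeric(K) || E >= 3 * K)
    stop("requires K > E/3 (otherwise nu <= 0)")
  (1 - E / (3 * K)) / 2
}

#' SLIL bulk modulus as printed in its source
#'
#' Returns the library constant 9.19802 MPa.  The value reproduces the
#' arithmetic chain 1000 x 832.4 x 11.05 x 1e-6 (the stated bulk/shear ratio
#' of 1000 applied to the product of the two distortional constants), but the
#' stated relation "mu = C1 * C2" is dimensionally inconsistent, so the
#' constant is stored as printed rather than derived.
#'
#' @return Bulk modulus (MPa).
#' @export
ligament_bulk_as_printed <- function() 9.19802

#' Default material library
#'
#' Named defaults: `cortical` (E = 18 MPa, nu = 0.2) and `cancellous`
#' (E = 100 MPa, nu = 0.25) linear-elastic bone as tabulated in the source
#' literature; `cortical_literature` (E = 18e3 MPa, nu = 0.2), the
#' literature-scale cortical modulus (the tabulated 18 MPa is three orders of
#' magnitude below reported cortical stiffness and makes cortical bone softer
#' than cancellous; both entries are provided and the choice is a
#' configuration decision); `cartilage` Mooney-Rivlin (C1 = 4.1,
#' C2 = 0.41, K = 19.3 MPa); `slil` Mooney-Rivlin (C1 = 832.4e-6,
#' C2 = 11.05e-6, K = 9.19802 MPa).
#'
#' @param overrides Named list of `material` objects replacing defaults.
#' @return Named list of `material` objects.
#' @export
material_library <- function(overrides = list()) {
  lib <- list(
    cortical = linear_elastic(18, 0.2),
    cancellous = linear_elastic(100, 0.25),
    cortical_literature = linear_elastic(18e3, 0.2),
    cartilage = mooney_rivlin(4.1, 0.41, 19.3),
    slil = mooney_rivlin(832.4e-6, 11.05e-6, ligament_bulk_as_printed()))
  for (nm in names(overrides)) {
    if (!inherits(overrides[[nm]], "material"))
      stop("override '", nm, "' is not a material")
    lib[[nm]] <- overrides[[nm]]
  }
  lib
}

mr_invariants <- function(F) {
  J <- det(F)
  C <- t(F) %*% F
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  list(J = J, I1 = I1, I2 = I2,
       I1b = J^(-2 / 3) * I1, I2b = J^(-4 / 3) * I2)
}

#' Mooney-Rivlin strain-energy density
#' @param F 3 x 3 deformation gradient with det(F) > 0.
#' @param p A `material` from [mooney_rivlin()].
#' @return Energy density (MPa = mJ/mm^3).
#' @export
mr_energy <- function(F, p) {
  F <- as.matrix(F)
  iv <- mr_invariants(F)
  if (iv$J <= 0) stop("element inversion: det(F) <= 0")
  p$C1 * (iv$I1b - 3) + p$C2 * (iv$I2b - 3) + (p$K / 2) * (iv$J - 1)^2
}

# First Piola-Kirchhoff stress, analytic derivative of mr_energy.
mr_pk1 <- function(F, p) {
  iv <- mr_invariants(F)
  if (iv$J <= 0) stop("element inversion: det(F) <= 0")
  Finvt <- t(solve(F))
  C <- t(F) %*% F
  dI1 <- 2 * F
  dI2 <- 2 * (iv$I1 * F - F %*% C)
  dJ <- iv$J * Finvt
  dI1b <- iv$J^(-2 / 3) * dI1 - (2 / 3) * iv$I1b / iv$J * dJ
  dI2b <- iv$J^(-4 / 3) * dI2 - (4 / 3) * iv$I2b / iv$J * dJ
  p$C1 * dI1b + p$C2 * dI2b + p$K * (iv$J - 1) * dJ
}

#' Mooney-Rivlin Cauchy stress
#'
#' Analytic derivative of [mr_energy()]: sigma = J^-1 P F^T with P the first
#' Piola-Kirchhoff stress.
#'
#' @param F 3 x 3 deformation gradient with det(F) > 0.
#' @param p A `material` from [mooney_rivlin()].
#' @return Symmetric 3 x 3 Cauchy stress (MPa).
#' @export
mr_stress <- function(F, p) {
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  sig <- mr_pk1(F, p) %*% t(F) / J
  (sig + t(sig)) / 2
}

#' Isotropic linear-elastic (Hooke) stress
#'
#' sigma = lambda tr(eps) I + 2 mu eps.
#'
#' @param strain Symmetric 3 x 3 small-strain tensor.
#' @param p A `material` from [linear_elastic()].
#' @return Symmetric 3 x 3 stress tensor (MPa).
#' @export
linear_stress <- function(strain, p) {
  strain <- as.matrix(strain)
  p$lambda * sum(diag(strain)) * diag(3) + 2 * p$mu * strain
}

#' Serialize a material library to a config file
#' @param lib Named list of `material` objects.
#' @param file Output path (delimited text).
#' @return Invisibly, the path.
#' @export
write_material_library <- function(lib, file) {
  rows <- lapply(names(lib), function(nm) {
    m <- lib[[nm]]
    if (m$kind == "linear")
      sprintf("%s\tlinear\tE=%.10g\tnu=%.10g\tMPa", nm, m$E, m$nu)
    else
      sprintf("%s\tmooney_rivlin\tC1=%.10g\tC2=%.10g\tK=%.10g\tMPa",
              nm, m$C1, m$C2, m$K)
  })
  writeLines(c("# name\tkind\tparameters\tunits", unlist(rows)), file)
  invisible(file)
}
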