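# Constitutive models and modulus conversions.

test_that("bulk modulus relation reproduces the cartilage constant", {
  expect_equal(bulk_modulus(11.6, 0.4), 19.333, tolerance = 1e-3)
  expect_equal(round(bulk_modulus(11.6, 0.4), 1), 19.3)
  expect_equal(bulk_modulus(3.0, 0.0), 1.0)
  expect_error(bulk_modulus(10, 0.5), "0.5")
  expect_error(bulk_modulus(-1, 0.3), "positive")
})

test_that("Poisson inversion reproduces the ligament constant", {
  expect_equal(poisson_from_bulk(4.89, 9.19802), 0.4114, tolerance = 5e-5)
  expect_equal(round(poisson_from_bulk(4.89, 9.19802), 2), 0.41)
  # limit K -> E/3 gives nu -> 0
  expect_equal(poisson_from_bulk(3, 1 + 1e-12), 0, tolerance = 1e-9)
  expect_error(poisson_from_bulk(3, 0.9), "K > E/3")
})

test_that("bulk_modulus and poisson_from_bulk are mutual inverses", {
  set.seed(5)
  for (rep in 1:25) {
    E <- stats::runif(1, 0.1, 1000)
    nu <- stats::runif(1, 0.01, 0.49)
    expect_equal(poisson_from_bulk(E, bulk_modulus(E, nu)), nu,
                 tolerance = 1e-10)
  }
})

test_that("printed ligament bulk modulus and its arithmetic chain agree", {
  expect_identical(ligament_bulk_as_printed(), 9.19802)
  expect_equal(1000 * 832.4e-6 * 11.05e-6 * 1e6, 9.19802, tolerance = 1e-10)
  lib <- material_library()
  expect_identical(lib$slil$K, ligament_bulk_as_printed())
})

test_that("material library holds the tabulated defaults and validates", {
  lib <- material_library()
  expect_equal(c(lib$cortical$E, lib$cortical$nu), c(18, 0.2))
  expect_equal(c(lib$cancellous$E, lib$cancellous$nu), c(100, 0.25))
  expect_equal(c(lib$cartilage$C1, lib$cartilage$C2, lib$cartilage$K),
               c(4.1, 0.41, 19.3))
  expect_equal(c(lib$slil$C1, lib$slil$C2), c(832.4e-6, 11.05e-6))
  expect_error(linear_elastic(10, 0.6), "nu")
  expect_error(mooney_rivlin(-1, -1, 10), "C1")
  ovr <- material_library(list(cortical = linear_elastic(18e3, 0.2)))
  expect_equal(ovr$cortical$E, 18e3)
})

test_that("Mooney-Rivlin energy matches closed forms", {
  cart <- material_library()$cartilage
  expect_equal(mr_energy(diag(3), cart), 0)
  # pure dilatation: isochoric invariants stay 3, only the volumetric term
  J <- 1.1
  expect_equal(mr_energy(J^(1 / 3) * diag(3), cart), (19.3 / 2) * 0.1^2,
               tolerance = 1e-10)
  # isochoric uniaxial with C2 = 0: W = C1 (lam^2 + 2/lam - 3)
  p <- mooney_rivlin(4.1, 0, 19.3)
  lam <- 1.2
  F <- diag(c(1 / sqrt(lam), 1 / sqrt(lam), lam))
  expect_equal(mr_energy(F, p), 4.1 * (lam^2 + 2 / lam - 3), tolerance = 1e-10)
  expect_error(mr_energy(diag(c(-1, 1, 1)), p), "inversion")
})

test_that("Mooney-Rivlin stress is the exact gradient of the energy", {
  set.seed(7)
  p <- material_library()$cartilage
  h <- 1e-6
  for (rep in 1:20) {
    F <- random_deformation_gradient()
    sig <- mr_stress(F, p)
    expect_equal(sig, t(sig), tolerance = 1e-12)
    # first-Piola finite differences
    P_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P_fd[i, j] <- (mr_energy(Fp, p) - mr_energy(Fm, p)) / (2 * h)
    }
    sig_fd <- P_fd %*% t(F) / det(F)
    sig_fd <- (sig_fd + t(sig_fd)) / 2
    expect_equal(sig, sig_fd, tolerance = 1e-5)
  }
})

test_that("stress vanishes at identity and at pure rotations (objectivity)", {
  p <- material_library()$slil
  expect_equal(mr_stress(diag(3), p), matrix(0, 3, 3), tolerance = 1e-14)
  set.seed(8)
  for (rep in 1:10) {
    R <- carpalfem:::random_rotation()
    expect_equal(max(abs(mr_stress(R, p))), 0, tolerance = 1e-12)
    expect_equal(mr_energy(R, p), 0, tolerance = 1e-12)
  }
})

test_that("energy is non-negative near the reference for valid parameters", {
  set.seed(9)
  p <- material_library()$cartilage
  for (rep in 1:50) {
    F <- diag(3) + matrix(stats::runif(9, -0.05, 0.05), 3, 3)
    expect_gte(mr_energy(F, p), -1e-12)
  }
})

test_that("with C2 = 0 the model reduces to compressible neo-Hookean", {
  p <- mooney_rivlin(2.0, 0, 10)
  set.seed(10)
  for (rep in 1:10) {
    F <- random_deformation_gradient()
    J <- det(F)
    I1b <- J^(-2 / 3) * sum(diag(t(F) %*% F))
    W_nh <- 2.0 * (I1b - 3) + 5 * (J - 1)^2
    expect_equal(mr_energy(F, p), W_nh, tolerance = 1e-10)
  }
})

test_that("linear stress matches a 6x6 Voigt-matrix oracle", {
  p <- linear_elastic(210, 0.3)
  E <- p$E; nu <- p$nu
  f <- E / ((1 + nu) * (1 - 2 * nu))
  D <- f * rbind(
    c(1 - nu, nu, nu, 0, 0, 0), c(nu, 1 - nu, nu, 0, 0, 0),
    c(nu, nu, 1 - nu, 0, 0, 0),
    c(0, 0, 0, (1 - 2 * nu) / 2, 0, 0), c(0, 0, 0, 0, (1 - 2 * nu) / 2, 0),
    c(0, 0, 0, 0, 0, (1 - 2 * nu) / 2))
  set.seed(12)
  for (rep in 1:10) {
    A <- matrix(stats::rnorm(9, sd = 0.01), 3, 3)
    eps <- (A + t(A)) / 2
    voigt <- c(diag(eps), 2 * eps[1, 2], 2 * eps[2, 3], 2 * eps[1, 3])
    sv <- D %*% voigt
    sig <- linear_stress(eps, p)
    expect_equal(c(diag(sig), sig[1, 2], sig[2, 3], sig[1, 3]), as.vector(sv),
                 tolerance = 1e-10)
  }
  expect_equal(linear_stress(matrix(0, 3, 3), p), matrix(0, 3, 3))
  # hydrostatic strain: sigma = 3 K eps I
  K <- bulk_modulus(p$E, p$nu)
  expect_equal(linear_stress(0.01 * diag(3), p), 3 * K * 0.01 * diag(3),
               tolerance = 1e-10)
})
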