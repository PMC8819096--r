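# Nonlinear FEM core: assembly, Newton solution, mechanism detection.

test_that("reference state with no loads is in equilibrium", {
  m <- coarse_model()
  mesh <- coarse_mesh()
  ss <- build_spring_set(m$landmarks, mesh)
  bcs <- build_bc_set(mesh, "extension", steps = 2)
  lib <- material_library()
  mats <- list(cortical = lib$cortical, cancellous = lib$cancellous,
               scaphoid = lib$cortical, lunate = lib$cortical,
               capitate = lib$cortical, radius_cartilage = lib$cartilage,
               scaphoid_cartilage = lib$cartilage,
               lunate_cartilage = lib$cartilage,
               capitate_cartilage = lib$cartilage, slil = lib$slil)
  case <- simulation_case(mesh, mats, springs = ss, bcs = bcs)
  asm <- assemble(case, numeric(3 * nrow(mesh$nodes)))
  expect_equal(max(abs(asm$residual)), 0, tolerance = 1e-12)
  expect_equal(asm$energy, 0, tolerance = 1e-12)
})

test_that("global tangent matches finite differences of the residual", {
  set.seed(31)
  vm <- tetrahedralize(sphere_surface(2, 5, 6), 1.2)
  case <- simulation_case(vm, list(solid = material_library()$cartilage),
                          bcs = list(fixed = 1L, prescribed = integer(0),
                                     target = numeric(3), ramp = 1))
  n3 <- 3 * nrow(vm$nodes)
  u0 <- 0.05 * stats::rnorm(n3)
  a <- assemble(case, u0)
  K <- as.matrix(a$tangent)
  h <- 1e-6
  for (j in sample(n3, 10)) {
    up <- u0; up[j] <- up[j] + h
    um <- u0; um[j] <- um[j] - h
    col <- (assemble(case, up, want_tangent = FALSE)$residual -
              assemble(case, um, want_tangent = FALSE)$residual) / (2 * h)
    expect_equal(col, K[, j], tolerance = 1e-4)
  }
})

test_that("internal force is the gradient of the strain energy", {
  set.seed(32)
  vm <- tetrahedralize(sphere_surface(2, 5, 6), 1.2)
  case <- simulation_case(vm, list(solid = material_library()$cartilage),
                          bcs = list(fixed = 1L, prescribed = integer(0),
                                     target = numeric(3), ramp = 1))
  n3 <- 3 * nrow(vm$nodes)
  u0 <- 0.05 * stats::rnorm(n3)
  r <- assemble(case, u0, want_tangent = FALSE)$residual
  h <- 1e-6
  for (j in sample(n3, 8)) {
    up <- u0; up[j] <- up[j] + h
    um <- u0; um[j] <- um[j] - h
    g <- (assemble(case, up, want_tangent = FALSE)$energy -
            assemble(case, um, want_tangent = FALSE)$energy) / (2 * h)
    expect_equal(g, r[j], tolerance = 1e-5 * max(1, abs(r[j])))
  }
})

test_that("tet4 assembly passes the linear patch test to machine precision", {
  vm <- cube_mesh()
  mat <- linear_elastic(100, 0.3)
  case <- simulation_case(vm, list(solid = mat),
                          bcs = list(fixed = seq_len(nrow(vm$nodes)),
                                     prescribed = integer(0),
                                     target = numeric(3), ramp = 1))
  set.seed(33)
  A <- matrix(stats::rnorm(9, sd = 0.01), 3, 3)
  u <- as.vector(t(vm$nodes %*% t(A)))
  sig <- carpalfem:::.tet4_stress_cpp(vm$nodes, vm$tets, u, case$matcode,
                                      case$matpar)
  eps <- (A + t(A)) / 2
  se <- linear_stress(eps, mat)
  expected <- c(diag(se), se[1, 2], se[2, 3], se[1, 3])
  for (e in seq_len(nrow(sig)))
    expect_equal(unname(sig[e, ]), unname(expected), tolerance = 1e-13)
  # interior equilibrium: residual vanishes at interior nodes
  asm <- assemble(case, u, want_tangent = FALSE)
  bnd <- unique(as.vector(boundary_faces(vm)$triangles))
  interior <- setdiff(seq_len(nrow(vm$nodes)), bnd)
  expect_equal(max(abs(asm$residual[carpalfem:::node_dofs(interior)])), 0,
               tolerance = 1e-10)
})

test_that("single-element uniaxial Mooney-Rivlin matches the closed form", {
  p <- mooney_rivlin(4.1, 0.41, 19.3)
  lam3 <- 1.25
  case <- uniaxial_case(p, lam3, steps = 5)
  res <- newton_solve(case)
  expect_false(res$diverged)
  sig <- res$stress[[res$steps_completed]]
  # closed form: lateral stretch from zero lateral stress (1-D root solve on
  # the R-side constitutive law, independent of the FE path)
  f_lat <- function(l1) mr_stress(diag(c(l1, l1, lam3)), p)[1, 1]
  l1 <- stats::uniroot(f_lat, c(0.6, 1.1), tol = 1e-13)$root
  s33 <- mr_stress(diag(c(l1, l1, lam3)), p)[3, 3]
  expect_equal(max(abs(sig[, 3] - s33)) / abs(s33), 0, tolerance = 1e-4)
  expect_lt(max(abs(sig[, 1])), 1e-4 * abs(s33))
})

test_that("zero prescribed displacement converges immediately", {
  vm <- cube_mesh()
  case <- simulation_case(vm, list(solid = linear_elastic(10, 0.3)),
                          bcs = list(fixed = 1:4, prescribed = 5:8,
                                     target = c(0, 0, 0), ramp = 1))
  res <- newton_solve(case)
  expect_false(res$diverged)
  expect_identical(res$convergence$iterations, 1L)
  expect_equal(max(abs(res$u[[1]])), 0)
})

test_that("Newton residuals contract superlinearly near the solution", {
  p <- mooney_rivlin(4.1, 0.41, 19.3)
  case <- uniaxial_case(p, 1.3, steps = 1)
  cd <- carpalfem:::constraint_dofs(case$bcs)
  n3 <- 3 * nrow(case$mesh$nodes)
  free <- setdiff(seq_len(n3), c(cd$fixed, cd$prescribed))
  u <- numeric(n3)
  u[cd$prescribed] <- cd$target
  norms <- c()
  for (it in 1:8) {
    asm <- assemble(case, u)
    rn <- sqrt(sum(asm$residual[free]^2))
    norms <- c(norms, rn)
    if (rn < 1e-12) break
    u[free] <- u[free] + as.numeric(Matrix::solve(
      asm$tangent[free, free], -asm$residual[free]))
  }
  norms <- norms[norms > 1e-13]
  ratios <- norms[-1] / norms[-length(norms)]
  # contraction accelerates: last observed ratio far below the first
  expect_lt(ratios[length(ratios)], 0.05 * ratios[1])
})

test_that("fixed-node displacements are zero and reactions balance loads", {
  vm <- cube_mesh()
  bcs <- list(fixed = which(abs(vm$nodes[, 3]) < 1e-9),
              prescribed = which(abs(vm$nodes[, 3] - 1) < 1e-9),
              target = c(0, 0, 0.05), ramp = c(0.5, 1))
  case <- simulation_case(vm, list(solid = linear_elastic(50, 0.25)),
                          bcs = bcs)
  res <- newton_solve(case)
  expect_false(res$diverged)
  u <- matrix(res$u[[2]], ncol = 3, byrow = TRUE)
  expect_equal(max(abs(u[bcs$fixed, ])), 0)
  # total reaction at the base balances the force pulling the top
  asm <- assemble(case, res$u[[2]], want_tangent = FALSE)
  top_forces <- matrix(asm$residual[carpalfem:::node_dofs(bcs$prescribed)],
                       ncol = 3, byrow = TRUE)
  expect_equal(colSums(res$reactions), -colSums(top_forces), tolerance = 1e-8)
})

test_that("rigid translation with translated BCs yields identical stresses", {
  vm <- cube_mesh()
  bcs <- list(fixed = which(abs(vm$nodes[, 3]) < 1e-9),
              prescribed = which(abs(vm$nodes[, 3] - 1) < 1e-9),
              target = c(0, 0, 0.1), ramp = 1)
  mat <- list(solid = mooney_rivlin(4.1, 0.41, 19.3))
  r1 <- newton_solve(simulation_case(vm, mat, bcs = bcs))
  vm2 <- volume_mesh(sweep(vm$nodes, 2, c(5, -3, 2), "+"), vm$tets)
  r2 <- newton_solve(simulation_case(vm2, mat, bcs = bcs))
  expect_equal(r1$stress[[1]], r2$stress[[1]], tolerance = 1e-9)
})

test_that("mechanism detection counts unconstrained rigid freedoms", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh1 <- volume_mesh(nodes, matrix(1:4, 1), part = "b")
  mat <- list(b = linear_elastic(100, 0.3))
  fixed_case <- simulation_case(mesh1, mat,
                                bcs = list(fixed = 1:4,
                                           prescribed = integer(0),
                                           target = numeric(3), ramp = 1))
  expect_identical(as.integer(detect_mechanism(fixed_case)), 0L)
  free_case <- simulation_case(mesh1, mat,
                               bcs = list(fixed = integer(0),
                                          prescribed = integer(0),
                                          target = numeric(3), ramp = 1))
  expect_identical(as.integer(detect_mechanism(free_case)), 6L)
  # two bodies, one fixed, joined by one axial spring: five rigid freedoms
  nodes2 <- rbind(nodes, sweep(nodes, 2, c(3, 0, 0), "+"))
  mesh2 <- volume_mesh(nodes2, rbind(matrix(1:4, 1), matrix(5:8, 1)),
                       part = c("a", "b"))
  ss <- structure(list(springs = list(spring_element("link", 2L, 5L, 10, 2))),
                  class = "spring_set")
  spring_case <- simulation_case(mesh2, list(a = mat$b, b = mat$b),
                                 springs = ss,
                                 bcs = list(fixed = 1:4,
                                            prescribed = integer(0),
                                            target = numeric(3), ramp = 1))
  expect_identical(as.integer(detect_mechanism(spring_case)), 5L)
})

test_that("penalty contact transmits compression between separate parts", {
  # two stacked cubes with a 0.02 mm gap; pushing the top one down must load
  # the bottom one through the contact pair
  bottom <- cube_mesh()
  topvm <- cube_mesh()
  nodes <- rbind(bottom$nodes,
                 sweep(topvm$nodes, 2, c(0, 0, 1.02), "+"))
  tets <- rbind(bottom$tets, topvm$tets + nrow(bottom$nodes))
  mesh <- volume_mesh(nodes, tets,
                      part = rep(c("lower", "upper"),
                                 c(nrow(bottom$tets), nrow(topvm$tets))))
  push <- which(abs(nodes[, 3] - 2.02) < 1e-9)
  base <- which(abs(nodes[, 3]) < 1e-9)
  bcs <- list(fixed = base, prescribed = push, target = c(0, 0, -0.1),
              ramp = seq(0.25, 1, by = 0.25))
  mat <- linear_elastic(50, 0.25)
  case <- simulation_case(mesh, list(lower = mat, upper = mat), bcs = bcs,
                          contacts = list(contact_pair("upper", "lower",
                                                       penalty = 500)))
  res <- newton_solve(case)
  expect_false(res$diverged)
  en <- assemble(case, res$u[[res$steps_completed]],
                 want_tangent = FALSE)$elem_energy
  lower_energy <- sum(en[mesh$part == "lower"])
  expect_gt(lower_energy, 0.001 * sum(en))
  # without the contact pair the lower cube stays unloaded
  case0 <- simulation_case(mesh, list(lower = mat, upper = mat), bcs = bcs)
  res0 <- newton_solve(case0)
  en0 <- assemble(case0, res0$u[[res0$steps_completed]],
                  want_tangent = FALSE)$elem_energy
  expect_lt(sum(en0[mesh$part == "lower"]), 1e-12)
})
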