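# Ligament spring network: construction, forces, tangents, assembly.

test_that("spring set on the default model carries the tabulated stiffnesses", {
  m <- coarse_model()
  mesh <- coarse_mesh()
  ss <- build_spring_set(m$landmarks, mesh)
  ks <- vapply(ss$springs, `[[`, 0, "k")
  expect_equal(sort(ks), sort(c(150, 150, 230, 75, 40, 10, 50, 75,
                                50.75, 50.75)))
  # all springs unstressed as built
  for (sp in ss$springs) {
    fr <- spring_force(sp, mesh$nodes[sp$node_a, ], mesh$nodes[sp$node_b, ])
    expect_equal(fr$tension, 0, tolerance = 1e-12)
  }
  # endpoints lie on the named parts
  for (i in seq_along(ss$springs)) {
    sp <- ss$springs[[i]]
    pa <- carpalfem:::landmark_part_to_mesh_part(ss$provenance$part_a[i])
    expect_true(sp$node_a %in% part_nodes(mesh, pa))
  }
})

test_that("an unreachable landmark fails with a distance message", {
  mesh <- coarse_mesh()
  lm <- coarse_model()$landmarks[1, ]
  lm$ax <- 500
  expect_error(build_spring_set(lm, mesh, tolerance = 1), "tolerance")
})

test_that("spring force follows k (L - L0) with the tension-only option", {
  sp <- spring_element("dorsal scapholunate", 1L, 2L, 230, 1.0)
  # elongation 0.1 mm at k = 230 N/mm -> 23 N
  fr <- spring_force(sp, c(0, 0, 0), c(1.1, 0, 0))
  expect_equal(fr$tension, 23, tolerance = 1e-12)
  expect_equal(fr$fa, c(23, 0, 0))
  expect_equal(fr$fb, -fr$fa)
  expect_equal(spring_force(sp, c(0, 0, 0), c(1, 0, 0))$tension, 0)
  to <- spring_element("slack", 1L, 2L, 230, 1.0, tension_only = TRUE)
  expect_equal(spring_force(to, c(0, 0, 0), c(0.9, 0, 0))$tension, 0)
  expect_error(spring_force(sp, c(0, 0, 0), c(0, 0, 0)), "zero length")
})

test_that("spring tangent matches finite differences of the force", {
  set.seed(21)
  h <- 1e-7
  for (rep in 1:10) {
    sp <- spring_element("s", 1L, 2L, stats::runif(1, 1, 300),
                         stats::runif(1, 0.5, 3),
                         tension_only = rep %% 2 == 0)
    xa <- stats::rnorm(3); xb <- xa + stats::rnorm(3)
    if (carpalfem:::norm3(xb - xa) < 0.1) xb <- xa + c(1, 0, 0)
    K <- spring_tangent(sp, xa, xb)
    expect_equal(K, t(K), tolerance = 1e-10)
    x <- c(xa, xb)
    Kfd <- matrix(0, 6, 6)
    for (j in 1:6) {
      xp <- x; xp[j] <- xp[j] + h
      xm <- x; xm[j] <- xm[j] - h
      fp <- spring_force(sp, xp[1:3], xp[4:6]); fm <- spring_force(sp, xm[1:3], xm[4:6])
      # stiffness convention: minus the applied-force jacobian
      Kfd[, j] <- -(c(fp$fa, fp$fb) - c(fm$fa, fm$fb)) / (2 * h)
    }
    expect_equal(K, Kfd, tolerance = 1e-5)
  }
})

test_that("reference tangent of a unit spring is the axial dyad", {
  sp <- spring_element("s", 1L, 2L, 1, 2)
  K <- spring_tangent(sp, c(0, 0, 0), c(2, 0, 0))
  expect_equal(K[1:3, 1:3], diag(c(1, 0, 0)), tolerance = 1e-12)
})

test_that("spring forces obey Newton's third law in any configuration", {
  set.seed(22)
  m <- coarse_model()
  mesh <- coarse_mesh()
  ss <- build_spring_set(m$landmarks, mesh)
  u <- stats::rnorm(3 * nrow(mesh$nodes), sd = 0.5)
  sa <- carpalfem:::spring_assemble(ss, mesh$nodes, u, want_tangent = FALSE)
  total <- colSums(matrix(sa$f, ncol = 3, byrow = TRUE))
  expect_equal(total, c(0, 0, 0), tolerance = 1e-10)
})

test_that("assembled spring stiffness is symmetric PSD at reference", {
  m <- coarse_model()
  mesh <- coarse_mesh()
  ss <- build_spring_set(m$landmarks, mesh)
  sa <- carpalfem:::spring_assemble(ss, mesh$nodes,
                                    numeric(3 * nrow(mesh$nodes)))
  K <- as.matrix(Matrix::sparseMatrix(i = sa$ti, j = sa$tj, x = sa$tx,
                                      dims = rep(3 * nrow(mesh$nodes), 2)))
  expect_equal(K, t(K), tolerance = 1e-10)
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(abs(ev)))
  # one non-zero mode per distinct attachment pair at reference (ligaments
  # sharing both nodes stack their stiffness into the same rank-1 mode)
  pairs <- unique(t(vapply(ss$springs, function(sp)
    sort(c(sp$node_a, sp$node_b)), integer(2))))
  expect_identical(sum(ev > 1e-8 * max(abs(ev))), nrow(pairs))
})

test_that("removing the SLIL leaves the other springs' forces unchanged", {
  m <- coarse_model()
  mesh <- coarse_mesh()
  ss <- build_spring_set(m$landmarks, mesh)
  set.seed(23)
  u <- stats::rnorm(3 * nrow(mesh$nodes), sd = 0.2)
  f_full <- carpalfem:::spring_assemble(ss, mesh$nodes, u,
                                        want_tangent = FALSE)$f
  # the SLIL is a 3D block, not a spring: dropping its mesh part cannot
  # change any spring force evaluated at the same endpoint motions
  expect_length(ss$springs, 10L)
  f_again <- carpalfem:::spring_assemble(ss, mesh$nodes, u,
                                         want_tangent = FALSE)$f
  expect_identical(f_full, f_again)
})
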