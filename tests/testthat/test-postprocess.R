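# Pressure definition, envelopes and extrema.

test_that("hydrostatic pressure follows the compression-positive convention", {
  expect_equal(element_pressure(-5 * diag(3)), 5)
  shear <- matrix(c(0, 1, 0, 1, 0, 2, 0, 2, 0), 3, 3)
  expect_equal(element_pressure(shear), 0)
  expect_equal(element_pressure(diag(c(3, 0, 0))), -1)
  expect_equal(element_pressure(c(1, 2, 3, 9, 9, 9)), -2)
})

test_that("pressure is invariant under rotation of the stress tensor", {
  set.seed(41)
  for (rep in 1:15) {
    A <- matrix(stats::rnorm(9), 3, 3)
    sig <- (A + t(A)) / 2
    R <- carpalfem:::random_rotation()
    expect_equal(element_pressure(R %*% sig %*% t(R)), element_pressure(sig),
                 tolerance = 1e-10)
  }
})

# small solved case reused by the envelope tests
solved_cube <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      vm <- cube_mesh()
      bcs <- list(fixed = which(abs(vm$nodes[, 3]) < 1e-9),
                  prescribed = which(abs(vm$nodes[, 3] - 1) < 1e-9),
                  target = c(0, 0, -0.05), ramp = seq(0.25, 1, by = 0.25))
      case <- simulation_case(vm, list(solid = linear_elastic(50, 0.25)),
                              bcs = bcs)
      res <<- newton_solve(case)
    }
    res
  }
})

test_that("region envelope brackets the volume-weighted mean", {
  res <- solved_cube()
  env <- region_envelope(res, "solid")
  expect_identical(nrow(env), 4L)
  expect_true(all(env$min <= env$mean & env$mean <= env$max))
  # independent volume-weighted brute force at the last step
  sel <- seq_len(nrow(res$case$mesh$tets))
  p <- apply(res$stress[[4]], 1, function(v) -(v[1] + v[2] + v[3]) / 3) * 1e6
  vols <- res$case$mesh$volumes
  expect_equal(env$mean[4], sum(p * vols) / sum(vols), tolerance = 1e-10)
  expect_equal(env$min[4], min(p), tolerance = 1e-10)
  expect_equal(env$max[4], max(p), tolerance = 1e-10)
  expect_error(region_envelope(res, "nonexistent"), "no elements")
})

test_that("a linear ramp produces monotone envelope curves", {
  env <- region_envelope(solved_cube(), "solid")
  expect_true(all(diff(env$max) > -1e-9))
  expect_true(all(diff(env$mean) > -1e-9))
})

test_that("constant stress gives min = mean = max", {
  # uniform uniaxial compression state via the patch rig
  case <- uniaxial_case(mooney_rivlin(4.1, 0.41, 19.3), 0.95, steps = 2)
  res <- newton_solve(case)
  env <- region_envelope(res, "solid")
  expect_equal(env$min, env$max, tolerance = 1e-6 * max(abs(env$max)))
  expect_equal(env$min, env$mean, tolerance = 1e-6 * max(abs(env$max)))
})

test_that("extrema match an exhaustive step-element scan and swap on sign flip", {
  res <- solved_cube()
  mm <- max_compression_traction(res, "solid")
  ps <- unlist(lapply(seq_len(res$steps_completed), function(s)
    apply(res$stress[[s]], 1, function(v) -(v[1] + v[2] + v[3]) / 3) * 1e6))
  expect_equal(unname(mm["max_compression"]), max(pmax(ps, 0)))
  expect_equal(unname(mm["max_traction"]), max(pmax(-ps, 0)))
  # sign flip swaps the pair
  flipped <- res
  flipped$stress <- lapply(res$stress, function(s) -s)
  mm2 <- max_compression_traction(flipped, "solid")
  expect_equal(unname(mm2["max_compression"]), unname(mm["max_traction"]))
  expect_equal(unname(mm2["max_traction"]), unname(mm["max_compression"]))
})

test_that("an all-compressive field reports zero traction", {
  case <- uniaxial_case(mooney_rivlin(4.1, 0.41, 19.3), 0.9, steps = 2)
  res <- newton_solve(case)
  mm <- max_compression_traction(res, "solid")
  expect_gt(unname(mm["max_compression"]), 0)
  expect_equal(unname(mm["max_traction"]), 0)
})

test_that("restarting the ramp at a later step reproduces the curves", {
  vm <- cube_mesh()
  bcs1 <- list(fixed = which(abs(vm$nodes[, 3]) < 1e-9),
               prescribed = which(abs(vm$nodes[, 3] - 1) < 1e-9),
               target = c(0, 0, -0.05), ramp = c(0.5, 1))
  mat <- list(solid = linear_elastic(50, 0.25))
  full <- newton_solve(simulation_case(vm, mat, bcs = bcs1))
  bcs2 <- bcs1; bcs2$ramp <- 1
  tail_run <- newton_solve(simulation_case(vm, mat, bcs = bcs2))
  e1 <- region_envelope(full, "solid")
  e2 <- region_envelope(tail_run, "solid")
  expect_equal(unlist(e1[2, c("min", "mean", "max")]),
               unlist(e2[1, c("min", "mean", "max")]), tolerance = 1e-7)
})

test_that("result series and curve files are written", {
  res <- solved_cube()
  dir <- file.path(tempdir(), "series_out")
  write_result_series(res, dir)
  expect_identical(length(list.files(dir, pattern = "\\.vtu$")), 4L)
  f <- tempfile(fileext = ".tsv")
  write_pressure_curves(region_envelope(res, "solid"), f)
  got <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(got), 4L)
})
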