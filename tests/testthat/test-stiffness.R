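# Linear stiffness estimation and the summary statistics.

test_that("noiseless curves recover their slope exactly", {
  cv <- synthesize_curve(230, noise_sd = 0, toe_extent = 0, n = 20, seed = 1)
  expect_equal(fit_linear_stiffness(cv), 230, tolerance = 1e-9)
  # toe region (smooth) then linear branch with slope 100
  cv2 <- synthesize_curve(100, noise_sd = 0, toe_extent = 0.8, n = 80,
                          seed = 2, d_max = 2)
  expect_equal(fit_linear_stiffness(cv2, window = c(0.45, 1)), 100,
               tolerance = 1e-6)
  expect_error(fit_linear_stiffness(cv, window = c(0.999, 1)), "fewer than 3")
})

test_that("noisy fits land within three standard errors of the truth", {
  cv <- synthesize_curve(71.5, noise_sd = 1, toe_extent = 0, n = 50, seed = 4)
  k <- fit_linear_stiffness(cv, window = c(0, 1))
  d <- cv$displacement
  se <- 1 / sqrt(sum((d - mean(d))^2))
  expect_lt(abs(k - 71.5), 3 * se)
})

test_that("fitting is invariant to force offsets and scales with force", {
  cv <- synthesize_curve(120, noise_sd = 0.5, toe_extent = 0.3, n = 40,
                         seed = 5)
  k0 <- fit_linear_stiffness(cv)
  shifted <- load_displacement_curve(cv$displacement, cv$force + 37, "s")
  expect_equal(fit_linear_stiffness(shifted), k0, tolerance = 1e-10)
  scaled <- load_displacement_curve(cv$displacement, 2 * cv$force, "s")
  expect_equal(fit_linear_stiffness(scaled), 2 * k0, tolerance = 1e-10)
})

test_that("the six measured samples summarize to 71.50/39.00", {
  s <- summarize_stiffness(slil_stiffness_samples())
  expect_identical(s$mean_report, 71.50)
  expect_identical(s$sd_report, 39.00)
})

test_that("summary statistics follow their closed forms and homogeneity", {
  s <- summarize_stiffness(rep(7, 6))
  expect_equal(s$sd, 0)
  a <- 10; b <- 25
  s2 <- summarize_stiffness(c(a, b))
  expect_equal(s2$mean, (a + b) / 2)
  expect_equal(s2$sd, abs(a - b) / sqrt(2))
  vals <- slil_stiffness_samples()
  s3 <- summarize_stiffness(3 * vals)
  base <- summarize_stiffness(vals)
  expect_equal(s3$mean, 3 * base$mean)
  expect_equal(s3$sd, 3 * base$sd)
  expect_error(summarize_stiffness(5), "at least 2")
})

test_that("literature comparison classifies the experimental mean", {
  s <- summarize_stiffness(slil_stiffness_samples())
  cmp <- compare_to_literature(s)
  expect_false(cmp$inside[cmp$study == "Nikolopoulos"])   # 25-36
  expect_true(cmp$inside[cmp$study == "Eschweiler"])      # 50-150
  expect_identical(attr(cmp, "pooled_mean"), 65.50)
  expect_identical(attr(cmp, "pooled_sd"), 34.70)
  # a point value equal to the mean counts as inside (closed comparison)
  s66 <- summarize_stiffness(c(66, 66))
  cmp66 <- compare_to_literature(s66)
  expect_true(cmp66$inside[cmp66$study == "Wayne and Tremols"])
})

test_that("synthetic curves are seed-deterministic and validated", {
  a <- synthesize_curve(80, 1, 0.2, n = 30, seed = 9)
  b <- synthesize_curve(80, 1, 0.2, n = 30, seed = 9)
  expect_identical(a$force, b$force)
  expect_false(identical(a$force, synthesize_curve(80, 1, 0.2, 30, 10)$force))
  expect_error(synthesize_curve(-1, 0, 0, 30, 1), "positive")
  expect_error(synthesize_curve(10, 0, 0, 5, 1), "n >= 10")
  expect_error(load_displacement_curve(c(0, 1, 1), c(0, 1, 2)),
               "strictly increasing")
})

test_that("fit-then-summarize over six synthetic samples recovers the truth", {
  k_true <- slil_stiffness_samples()
  fits <- vapply(seq_along(k_true), function(i) {
    cv <- synthesize_curve(k_true[i], noise_sd = 0.5, toe_extent = 0.3,
                           n = 60, seed = 100 + i)
    fit_linear_stiffness(cv)
  }, 0)
  s <- summarize_stiffness(fits)
  truth <- summarize_stiffness(k_true)
  # generator noise at sd 0.5 N perturbs each fit by well under 1 N/mm
  expect_lt(abs(s$mean - truth$mean), 1)
})

test_that("stiffness fit is unbiased over many seeded replicates", {
  fits <- vapply(1:200, function(i)
    fit_linear_stiffness(synthesize_curve(71.5, noise_sd = 1,
                                          toe_extent = 0.4, n = 50,
                                          seed = i)), 0)
  expect_lt(abs(mean(fits) - 71.5) / 71.5, 0.01)
})

test_that("curves round-trip through delimited text", {
  cv <- synthesize_curve(55, 0.3, 0.2, n = 25, seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_curve(cv, f)
  back <- read_curve(f)
  expect_equal(back$displacement, cv$displacement, tolerance = 1e-12)
  expect_equal(back$force, cv$force, tolerance = 1e-12)
})
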