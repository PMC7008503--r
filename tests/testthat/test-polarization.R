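angles19 <- seq(0, 180, by = 10)

test_that("per-pixel P-SHG fit is exact on noiseless model data", {
  b_true <- b_from_pitch_oracle(48.25) # independent root-finder oracle
  gen <- make_polarization_series(
    b_map = matrix(b_true, 3, 3), phi0_map = 30, noise = "none"
  )
  fit <- fit_pshg_pixel(gen$series)
  expect_true(all(fit$converged))
  expect_true(all(abs(fit$b_map - b_true) < 1e-6))
  expect_true(all(abs(fit$phi0_map - 30) < 1e-6))

  # b = sqrt(2): the 45-degree pitch case
  gen2 <- make_polarization_series(matrix(sqrt(2), 2, 2), 120,
                                   noise = "none")
  fit2 <- fit_pshg_pixel(gen2$series)
  expect_true(all(abs(fit2$b_map - sqrt(2)) < 1e-6))

  # round trip through the pitch relation
  pa <- pitch_angles(fit)
  expect_lt(abs(pa$summary$mean_deg - 48.25), 1e-6)
})

test_that("P-SHG fit is scale-invariant and angle-shift equivariant", {
  b_true <- 1.8
  base <- make_polarization_series(matrix(b_true, 2, 2), 40, noise = "none")
  # global intensity scale is absorbed by the amplitude
  scaled <- base$series
  scaled$frames <- scaled$frames * 7.3
  f1 <- fit_pshg_pixel(base$series)
  f2 <- fit_pshg_pixel(scaled)
  expect_equal(f2$b_map, f1$b_map, tolerance = 1e-8)
  expect_equal(f2$A_map, f1$A_map * 7.3, tolerance = 1e-6)

  # shifting all polarization angles by delta shifts phi0 by delta mod 180
  delta <- 20
  shifted <- make_polarization_series(matrix(b_true, 2, 2), 40 + delta,
                                      noise = "none")
  f3 <- fit_pshg_pixel(shifted$series)
  expect_equal(f3$b_map, f1$b_map, tolerance = 1e-6)
  expect_true(all(abs((f3$phi0_map - f1$phi0_map) %% 180 - delta) < 1e-5))
})

test_that("P-SHG fit tolerates Poisson noise with small median bias", {
  b_true <- 1.4
  gen <- make_polarization_series(matrix(b_true, 12, 12), 75, peak = 500,
                                  noise = "poisson", seed = 99)
  fit <- fit_pshg_pixel(gen$series)
  ok <- fit$converged
  expect_gt(mean(ok), 0.95)
  med_bias <- abs(median(fit$b_map[ok]) - b_true) / b_true
  expect_lt(med_bias, 0.02)
})

test_that("checkerboard tensor-ratio maps are recovered spatially", {
  b_map <- matrix(1.2, 6, 6)
  b_map[(row(b_map) + col(b_map)) %% 2 == 0] <- 2.2
  gen <- make_polarization_series(b_map, 10, noise = "none")
  fit <- fit_pshg_pixel(gen$series)
  expect_equal(fit$b_map, b_map, tolerance = 1e-5)
})

test_that("pitch angle is the arctangent relation, strictly decreasing in b", {
  expect_equal(pitch_angle(sqrt(2)), 45)
  expect_equal(pitch_angle(1), atan(sqrt(2)) * 180 / pi) # 54.7356, magic angle
  expect_lt(abs(pitch_angle(1) - 54.7356), 1e-4)
  b <- seq(0.2, 5, by = 0.1)
  expect_true(all(diff(pitch_angle(b)) < 0))
  expect_true(all(pitch_angle(b) > 0 & pitch_angle(b) < 90))
  expect_error(pitch_angle(0))
  expect_error(pitch_angle(-2))
})

test_that("normalized SHG-CD has the closed-form values, bound and symmetry", {
  # achiral: identical channels
  p0 <- cd_image_pair(matrix(300, 5, 5), matrix(300, 5, 5))
  expect_equal(compute_shg_cd(p0)$mean_abs_cd, 0)

  # L = 3R: |3 - 1| / 2 = 1 per pixel
  p1 <- cd_image_pair(matrix(300, 5, 5), matrix(100, 5, 5))
  r1 <- compute_shg_cd(p1)
  expect_equal(r1$mean_abs_cd, 1)
  expect_equal(r1$mask_fraction, 1)

  # algebraic bound and sign flip under channel swap, summary unchanged
  gen <- make_cd_pair(matrix(runif(64, 0, 1.5), 8, 8), 400,
                      noise = "poisson", seed = 4)
  r <- compute_shg_cd(gen$pair)
  expect_true(all(abs(r$cd_map[r$mask]) <= 2))
  swapped <- compute_shg_cd(cd_image_pair(gen$pair$rhcp, gen$pair$lhcp,
                                          gen$pair$noise_threshold))
  expect_equal(swapped$cd_map, -r$cd_map)
  expect_equal(swapped$mean_abs_cd, r$mean_abs_cd)

  # generator closure at high counts: summary matches the target mean |CD|
  cd_map <- matrix(withr::with_seed(12, runif(400, 0.1, 0.8)), 20, 20)
  gen2 <- make_cd_pair(cd_map, 2000, noise = "poisson", seed = 13)
  r2 <- compute_shg_cd(gen2$pair)
  expect_lt(abs(r2$mean_abs_cd - mean(abs(cd_map))), 0.02)

  # noiseless closed form: cd = 1 gives {1.5, 0.5} * base
  gen3 <- make_cd_pair(matrix(1, 2, 2), 100, sign = "map", noise = "none")
  expect_equal(sort(unique(c(gen3$pair$lhcp, gen3$pair$rhcp))), c(50, 150))

  expect_error(compute_shg_cd(cd_image_pair(matrix(1, 3, 3),
                                            matrix(1, 3, 3), 50)),
               "empty mask")
  expect_error(make_cd_pair(matrix(3, 2, 2), 100, noise = "none"))
})

test_that("group CD comparison detects a two-fold difference and is symmetric", {
  # per-image mean |CD| with group means in ratio 2:1 at the reported
  # group sizes (121 normal, 134 fibrotic images)
  withr::with_seed(31, {
    a <- pmax(rnorm(121, 0.40, 0.10), 0.01)
    b <- pmax(rnorm(134, 0.20, 0.10), 0.01)
  })
  cmp <- compare_cd_groups(a, b)
  expect_lt(abs(cmp$ratio - 2), 0.25)
  expect_lt(cmp$p_value, 0.05)

  swap <- compare_cd_groups(b, a)
  expect_equal(swap$p_value, cmp$p_value)
  expect_equal(swap$ratio, 1 / cmp$ratio)

  same <- compare_cd_groups(a, a)
  expect_gt(same$p_value, 0.999)
  expect_equal(same$ratio, 1)

  expect_error(compare_cd_groups(a, numeric(0)))
})
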