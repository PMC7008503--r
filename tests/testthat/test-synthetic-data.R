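test_that("fiber phantom is deterministic, 12-bit-bounded and background-calibrated", {
  cfg <- fiber_phantom_config(image_size = 48, n_fibers = 6, seed = 14)
  img1 <- make_fiber_image(cfg)
  img2 <- make_fiber_image(cfg)
  expect_identical(img1$stack$planes, img2$stack$planes)
  expect_true(all(img1$stack$planes >= 0 & img1$stack$planes <= 4095))
  expect_true(img1$ground_truth$packing_fraction > 0)

  # pure background: above-threshold fraction follows the Poisson tail
  bg <- fiber_phantom_config(image_size = 96, n_fibers = 0,
                             background_counts = 12, seed = 15)
  img_bg <- make_fiber_image(bg)
  frac <- packing_efficiency(img_bg$stack)$fraction
  p_analytic <- stats::ppois(15, 12, lower.tail = FALSE)
  se <- sqrt(p_analytic * (1 - p_analytic) / 96^2)
  expect_lt(abs(frac - p_analytic), 4 * se)
  expect_equal(img_bg$ground_truth$packing_fraction, 0) # expectation < 15

  # clip events are counted when the expectation is pushed to the ceiling
  hot <- fiber_phantom_config(image_size = 32, n_fibers = 10,
                              peak_counts = 4095, seed = 16)
  img_hot <- make_fiber_image(hot)
  expect_gte(img_hot$ground_truth$n_clipped, 0)
  expect_true(max(img_hot$stack$planes) <= 4095)
})

test_that("a dense phantom can be tuned to a target packing fraction", {
  # tuning loop with the packing metric as the oracle: fiber count is the
  # dial, the dense fibrotic coverage level is the target
  target <- 0.69
  counts <- seq(6, 26, by = 2)
  fracs <- vapply(counts, function(nf) {
    cfg <- fiber_phantom_config(image_size = 64, n_fibers = nf, seed = 20)
    packing_efficiency(make_fiber_image(cfg)$stack)$fraction
  }, numeric(1))
  expect_true(any(fracs >= target) && any(fracs <= target)) # bracketed
  best <- counts[which.min(abs(fracs - target))]
  cfg <- fiber_phantom_config(image_size = 64, n_fibers = best, seed = 20)
  expect_lt(abs(packing_efficiency(make_fiber_image(cfg)$stack)$fraction -
                  target), 0.05)
})

test_that("ballistic depth stacks carry the creation ratio at every depth", {
  optics0 <- optical_properties(445, 0, 0)
  phant <- fiber_phantom_config(image_size = 40, n_fibers = 10,
                                peak_counts = 1000, seed = 19)
  gen <- make_depth_stack(phant, 2.5, optics0, section_slab(),
                          detection_geometry(), seq(10, 50, by = 10),
                          mc_config(5e4, seed = 22))
  prof <- measure_fb_profile(gen$pair)
  expect_true(all(abs(prof$fb_measured - 2.5) < 4 * prof$fb_se * 2 + 0.05))
  expect_equal(gen$ground_truth$R, c(`1` = 2.5))
  expect_error(make_depth_stack(phant, -1, optics0, section_slab(),
                                detection_geometry(), c(10, 20),
                                mc_config(1e3, seed = 1)))
  expect_error(make_depth_stack(phant, 2, optics0, section_slab(),
                                detection_geometry(), c(10, 300),
                                mc_config(1e3, seed = 1)))
})

test_that("attenuation generator is exact noiseless and unbiased with noise", {
  rec <- make_attenuation_record(mus = 327, d_cm = 0.02)
  expect_equal(rec$I / rec$I0, exp(-6.54))
  expect_equal(estimate_mus(rec)$mus, 327)

  mus_hat <- vapply(1:300, function(i) {
    r <- make_attenuation_record(mus = 327, d_cm = 0.02, noise_cv = 0.02,
                                 seed = 400 + i)
    estimate_mus(r)$mus
  }, numeric(1))
  expect_lt(abs(mean(mus_hat) - 327) / 327, 0.005)
})

test_that("spectral generator produces the requested power law", {
  flat <- make_spectral_dataset(m = 2, amplitude = 13)
  expect_equal(unique(flat$mus_reduced_cm1), 13) # lambda^0

  d <- make_spectral_dataset(m = 1.34, amplitude = 2e5)
  expect_equal(fit_whittle_matern(d)$m, 1.34, tolerance = 1e-9)
  expect_equal(sort(unique(d$wavelength_nm)),
               c(390, 495, 545, 780, 990, 1070))
  expect_error(make_spectral_dataset(m = 3, amplitude = 1))
  expect_error(make_spectral_dataset(m = 1.5, amplitude = 1, noise_cv = 0.1))
})

test_that("generators require and obey their seeds", {
  expect_error(make_polarization_series(matrix(1.5, 2, 2), 0), "seed")
  expect_error(make_cd_pair(matrix(0.5, 2, 2), 100), "seed")
  g1 <- make_cd_pair(matrix(0.5, 4, 4), 200, seed = 3)
  g2 <- make_cd_pair(matrix(0.5, 4, 4), 200, seed = 3)
  expect_identical(g1$pair$lhcp, g2$pair$lhcp)
  s1 <- make_polarization_series(matrix(1.5, 2, 2), 0, seed = 5)
  s2 <- make_polarization_series(matrix(1.5, 2, 2), 0, seed = 5)
  expect_identical(s1$series$frames, s2$series$frames)
})
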