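make_uniform_pair <- function(f_val, b_val, n = 30, nz = 4, eff_f = 1,
                              eff_b = 1, pitch = 0.354, dz = 10) {
  fs <- image_stack(array(f_val, dim = c(n, n, nz)), pitch, dz)
  bs <- image_stack(array(b_val, dim = c(n, n, nz)), pitch, dz)
  fb_stack_pair(fs, bs, eff_f, eff_b)
}

test_that("depth profile measures constructed ratios and applies calibration", {
  pair <- make_uniform_pair(200, 100)
  prof <- measure_fb_profile(pair)
  expect_s3_class(prof, "fb_profile")
  expect_equal(prof$fb_measured, rep(2, 4))
  expect_equal(prof$depth_um, c(0, 10, 20, 30))
  expect_true(all(prof$valid))

  # efficiencies (0.5, 1.0) turn a raw ratio of 1 into 2
  pair2 <- make_uniform_pair(100, 100, eff_f = 0.5, eff_b = 1)
  expect_equal(measure_fb_profile(pair2)$fb_measured, rep(2, 4))

  # calibration equivariance: scaling one efficiency by k scales F/B by 1/k
  pair3 <- make_uniform_pair(150, 100, eff_f = 3)
  pair4 <- make_uniform_pair(150, 100, eff_f = 1)
  expect_equal(measure_fb_profile(pair3)$fb_measured,
               measure_fb_profile(pair4)$fb_measured / 3)

  # a plane with no backward signal above threshold is flagged, not fatal
  bs <- array(100, dim = c(30, 30, 3))
  bs[, , 2] <- 0
  fs <- array(0, dim = c(30, 30, 3)) # forward also below threshold
  fs[, , c(1, 3)] <- 200
  pr <- measure_fb_profile(fb_stack_pair(
    image_stack(fs, 0.354, 10), image_stack(bs, 0.354, 10)
  ))
  expect_false(pr$valid[2])
  expect_true(is.na(pr$fb_measured[2]))
})

test_that("patch analysis tiles the field and reduces to the whole field", {
  pair <- make_uniform_pair(240, 120, n = 45, nz = 3)
  pm <- measure_fb_patches(pair, patch_size = 15)
  expect_equal(nrow(pm$patch_fb), 9)
  expect_equal(pm$patch_fb$fb, rep(2, 9)) # homogeneity
  expect_equal(pm$std_dev, 0)
  expect_equal(pm$patch_extent_um, 15 * 0.354, tolerance = 1e-12) # ~5.3 um
  expect_lt(abs(pm$patch_extent_um - 5.3), 0.02)

  # patch_size = image size reproduces the whole-field profile exactly
  pm_full <- measure_fb_patches(pair, patch_size = 45)
  prof <- measure_fb_profile(pair)
  expect_equal(pm_full$profiles$fb_measured, prof$fb_measured)

  expect_error(measure_fb_patches(pair, patch_size = 64))
})

test_that("two-region phantoms segregate by patch", {
  phant <- fiber_phantom_config(image_size = 30, n_fibers = 8,
                                peak_counts = 600, seed = 21)
  region <- matrix(1L, 30, 30)
  region[, 16:30] <- 2L
  optics <- as_optics(lung_optics$normal_445)
  gen <- make_depth_stack(phant, c(2.0, 3.0), optics, section_slab(),
                          detection_geometry(), seq(10, 40, by = 10),
                          mc_config(2e4, seed = 9), region_map = region)
  pm <- measure_fb_patches(gen$pair, patch_size = 15, min_signal_frac = 0)
  left <- pm$patch_fb$fb[pm$patch_fb$patch_col == 1]
  right <- pm$patch_fb$fb[pm$patch_fb$patch_col == 2]
  expect_true(mean(right, na.rm = TRUE) > mean(left, na.rm = TRUE))
})

test_that("creation-ratio extraction is exact in the ballistic limit and grid-optimal", {
  optics0 <- optical_properties(445, 0, 0) # mus' = 0
  fit <- extract_creation_ratio(
    flat_fb_profile(2.5), optics0, section_slab(), detection_geometry(),
    mc_config(2e4, seed = 13)
  )
  expect_equal(fit$fb_creation, 2.5)
  expect_false(fit$boundary)
  # grid-search optimality by brute force over the candidate table
  expect_true(all(fit$reduced_chi2 <= fit$candidates$reduced_chi2 + 1e-9))
  expect_equal(fit$candidates$candidate[which.min(fit$candidates$reduced_chi2)],
               fit$grid_minimum)

  # off-grid flat profile still lands between the bracketing candidates
  fit2 <- extract_creation_ratio(
    flat_fb_profile(2.6), optics0, section_slab(), detection_geometry(),
    mc_config(2e4, seed = 13)
  )
  expect_gt(fit2$fb_creation, 2.5)
  expect_lt(fit2$fb_creation, 2.75)

  expect_error(extract_creation_ratio(
    flat_fb_profile(2, depths_um = c(10, 20)), optics0, section_slab(),
    detection_geometry(), mc_config(1e3, seed = 1)
  ), "3 valid depths")
})

test_that("generator closure recovers a known creation ratio at reduced scale", {
  optics <- as_optics(lung_optics$normal_445)
  phant <- fiber_phantom_config(image_size = 48, n_fibers = 12, seed = 3)
  gen <- make_depth_stack(phant, 2.67, optics, section_slab(),
                          detection_geometry(), seq(10, 90, by = 20),
                          mc_config(3e4, seed = 41))
  prof <- measure_fb_profile(gen$pair)
  fit <- extract_creation_ratio(prof, optics, section_slab(),
                                detection_geometry(),
                                mc_config(3e4, seed = 57))
  expect_lt(abs(fit$fb_creation - 2.67), 0.25)
})

test_that("patch summaries pool stacks and tissues as specified", {
  pair <- make_uniform_pair(200, 100, n = 30, nz = 3)
  pm <- measure_fb_patches(pair, patch_size = 15)
  one <- summarize_patch_fits(list(pm))
  expect_equal(one$mean, 2)
  expect_true(is.na(one$se)) # single stack: SE undefined, flagged
  expect_equal(one$heterogeneity_sd, 0) # identical patches

  pm2 <- measure_fb_patches(make_uniform_pair(300, 100, n = 30, nz = 3),
                            patch_size = 15)
  two <- summarize_patch_fits(list(pm, pm2), tissue_ids = c(1, 1))
  expect_equal(two$mean, 2.5)
  expect_equal(two$n_stacks, 2)
  expect_error(summarize_patch_fits(list()))
})

test_that("patch-value population statistics are reproduced in simulation", {
  # per-patch values drawn from the reported normal-group distribution,
  # truncated positive, packaged as one patch map per stack
  patch_map_stub <- function(fb) {
    structure(list(
      patch_fb = tibble::tibble(fb = fb, valid = TRUE),
      mean = mean(fb), std_dev = sd(fb)
    ), class = "patch_map")
  }
  maps <- withr::with_seed(8, {
    lapply(1:75, function(i) {
      x <- rnorm(20, mean = 2.67, sd = 1.16)
      patch_map_stub(x[x > 0])
    })
  })
  smry <- summarize_patch_fits(maps)
  # truncation at 0 is negligible at this mean/sd
  expect_lt(abs(smry$mean - 2.67), 3 * 1.16 / sqrt(75 * 20) + 0.03)
  expect_lt(abs(smry$heterogeneity_sd - 1.16), 0.1)
  expect_false(is.na(smry$se))
})
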