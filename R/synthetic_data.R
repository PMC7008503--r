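#' Fiber phantom configuration
#'
#' Parameters of the synthetic curvilinear-fiber image generator that
#' stands in for SHG images of collagen. Fibers are random-walk
#' centerlines with curvature set by `waviness`, rendered as Gaussian
#' ridges, convolved with the lateral optical resolution, and
#' Poisson-sampled onto a 12-bit photon-count grid.
#'
#' @param image_size Image edge in pixels (square field).
#' @param pixel_pitch_um Pixel pitch, um (default 0.354, so a 15-px patch
#'   spans about 5.3 um).
#' @param n_fibers Number of fibers to draw.
#' @param fiber_width_um Fiber full width (Gaussian FWHM), um.
#' @param waviness Curvature scale: standard deviation (radians) of the
#'   per-step direction change of the centerline random walk.
#' @param peak_counts Mean photon counts at the brightest fiber pixel.
#' @param background_counts Mean background counts.
#' @param lateral_resolution_um Lateral optical resolution (FWHM) applied
#'   as a Gaussian blur (default 0.7 um).
#' @param seed Integer seed (mandatory; every generator is deterministic
#'   under a fixed seed).
#'
#' @return A `fiber_phantom_config` object.
#' @export
fiber_phantom_config <- function(image_size = 128, pixel_pitch_um = 0.354,
                                 n_fibers = 25, fiber_width_um = 1.5,
                                 waviness = 0.15, peak_counts = 300,
                                 background_counts = 2,
                                 lateral_resolution_um = 0.7, seed = 1) {
  check_number(image_size, "image_size", lower = 8)
  check_number(pixel_pitch_um, "pixel_pitch_um", lower = 0,
               closed_lower = FALSE)
  check_number(n_fibers, "n_fibers", lower = 0)
  check_number(fiber_width_um, "fiber_width_um", lower = 0,
               closed_lower = FALSE)
  check_number(waviness, "waviness", lower = 0)
  check_number(peak_counts, "peak_counts", lower = 0, upper = 4095)
  check_number(background_counts, "background_counts", lower = 0)
  check_number(seed, "seed")
  structure(
    list(image_size = as.integer(image_size),
         pixel_pitch_um = pixel_pitch_um, n_fibers = as.integer(n_fibers),
         fiber_width_um = fiber_width_um, waviness = waviness,
         peak_counts = peak_counts, background_counts = background_counts,
         lateral_resolution_um = lateral_resolution_um, seed = seed),
    class = "fiber_phantom_config"
  )
}

# separable Gaussian blur (sigma in pixels), reflecting boundaries
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(rev(v[seq_len(half)]), v, rev(v[(n - half + 1):n]))
    as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
  }
  out <- apply(img, 2, pad_conv)
  t(apply(out, 1, pad_conv))
}

# noiseless expected-count image for a phantom config
render_fiber_expectation <- function(config) {
  n <- config$image_size
  acc <- matrix(0, n, n)
  if (config$n_fibers > 0) {
    step <- 0.5
    n_steps <- ceiling(2 * n / step)
    for (f in seq_len(config$n_fibers)) {
      x <- runif(1, 1, n)
      y <- runif(1, 1, n)
      theta <- runif(1, 0, 2 * pi)
      for (s in seq_len(n_steps)) {
        theta <- theta + rnorm(1, 0, config$waviness)
        x <- x + step * cos(theta)
        y <- y + step * sin(theta)
        if (x < 1 || x > n || y < 1 || y > n) break
        acc[round(y), round(x)] <- acc[round(y), round(x)] + 1
      }
    }
  }
  sigma_fiber <- config$fiber_width_um / 2.355 / config$pixel_pitch_um
  sigma_psf <- config$lateral_resolution_um / 2.355 / config$pixel_pitch_um
  blurred <- gaussian_blur(acc, sqrt(sigma_fiber^2 + sigma_psf^2))
  expected <- matrix(config$background_counts, n, n)
  if (max(blurred) > 0) {
    expected <- expected + blurred / max(blurred) *
      (config$peak_counts - config$background_counts)
  }
  pmin(expected, 4095)
}

#' Synthetic fiber image
#'
#' Renders a single-plane photon-count image of curvilinear fibers with
#' Poisson noise, clipped to 12 bits, together with its generating ground
#' truth (the noiseless expectation image and the packing fraction of the
#' expectation above the standard 15-count threshold).
#'
#' @param config A [fiber_phantom_config()].
#'
#' @return A list: `stack` (an [image_stack()], one plane), `expected`
#'   (noiseless expectation matrix), `ground_truth` (config, expected
#'   packing fraction, clip count).
#' @export
make_fiber_image <- function(config) {
  stopifnot(inherits(config, "fiber_phantom_config"))
  with_seed(config$seed, {
    expected <- render_fiber_expectation(config)
    counts <- matrix(rpois(length(expected), expected), nrow(expected))
  })
  n_clipped <- sum(counts > 4095)
  counts <- pmin(counts, 4095)
  list(
    stack = image_stack(counts, pixel_pitch_um = config$pixel_pitch_um),
    expected = expected,
    ground_truth = list(
      config = config,
      packing_fraction = mean(expected > 15),
      n_clipped = n_clipped
    )
  )
}

#' Synthetic depth-resolved forward/backward stack pair
#'
#' Builds a co-registered forward/backward image stack whose expected
#' per-plane summed F/B ratio follows the Monte Carlo emission model
#' ([run_shg_emission()]) for a chosen creation ratio and optics; the
#' ground truth for closure tests of [extract_creation_ratio()]. The
#' backward channel carries the phantom's expected image; the forward
#' channel is scaled by the simulated measured ratio at each depth.
#' Per-pixel Poisson noise is applied to both channels.
#'
#' @param phantom A [fiber_phantom_config()]; its expectation image is
#'   reused at every depth (spatial pattern does not influence the
#'   whole-field ratio).
#' @param R Ground-truth creation ratio F_SHG/B_SHG.
#' @param optics An [optical_properties()] at the SHG wavelength.
#' @param slab A [slab_geometry()].
#' @param det A [detection_geometry()].
#' @param depths_um Equally spaced plane depths (um) within the slab.
#' @param mc An [mc_config()] for the generating simulations; child seeds
#'   are derived per depth.
#' @param efficiency_forward,efficiency_backward Detector efficiencies
#'   recorded in the returned pair.
#' @param region_map Optional integer matrix (phantom-sized) of region
#'   labels with `R` a vector giving one creation ratio per region, for
#'   two-population phantoms; default one region.
#'
#' @return A list: `pair` (an [fb_stack_pair()]), `ground_truth`
#'   (R, per-depth simulated measured ratios, seeds).
#' @export
make_depth_stack <- function(phantom, R, optics, slab, det, depths_um, mc,
                             efficiency_forward = 1, efficiency_backward = 1,
                             region_map = NULL) {
  stopifnot(inherits(phantom, "fiber_phantom_config"),
            inherits(optics, "optical_properties"),
            inherits(slab, "slab_geometry"),
            inherits(det, "detection_geometry"), inherits(mc, "mc_config"))
  if (length(depths_um) < 2) abort("need at least 2 depths.")
  dz <- diff(depths_um)
  if (any(abs(dz - dz[1]) > 1e-9) || dz[1] <= 0) {
    abort("`depths_um` must be equally spaced and increasing.")
  }
  if (any(depths_um < 0 | depths_um * 1e-4 > slab$thickness_cm)) {
    abort("`depths_um` must lie within the slab.")
  }
  if (is.null(region_map)) {
    region_map <- matrix(1L, phantom$image_size, phantom$image_size)
  }
  regions <- sort(unique(as.vector(region_map)))
  if (length(R) == 1) R <- rep(R, length(regions))
  if (length(R) != length(regions)) {
    abort("`R` must have one value per region in `region_map`.")
  }
  if (any(R <= 0)) abort("creation ratios must be positive.")
  medium <- scattering_medium(optics$mus, optics$g_single)

  expected <- with_seed(phantom$seed, render_fiber_expectation(phantom))
  # simulated measured ratio per (region, depth)
  rho <- matrix(NA_real_, length(regions), length(depths_um))
  for (r in seq_along(regions)) {
    for (j in seq_along(depths_um)) {
      mcj <- mc
      mcj$seed <- child_seed(mc$seed, r * 10000 + j)
      rho[r, j] <- run_shg_emission(R[r], depths_um[j] * 1e-4, medium, slab,
                                    det, mcj)$fb_measured
    }
  }

  nz <- length(depths_um)
  fwd <- bwd <- array(0, dim = c(dim(expected), nz))
  with_seed(child_seed(mc$seed, 999), {
    for (j in seq_len(nz)) {
      exp_b <- expected
      exp_f <- expected * (efficiency_forward / efficiency_backward)
      for (r in seq_along(regions)) {
        sel <- region_map == regions[r]
        exp_f[sel] <- exp_f[sel] * rho[r, j]
      }
      bwd[, , j] <- pmin(matrix(rpois(length(exp_b), exp_b), nrow(exp_b)), 4095)
      fwd[, , j] <- pmin(matrix(rpois(length(exp_f), exp_f), nrow(exp_f)), 4095)
    }
  })
  fs <- image_stack(fwd, pixel_pitch_um = phantom$pixel_pitch_um,
                    z_spacing_um = dz[1])
  bs <- image_stack(bwd, pixel_pitch_um = phantom$pixel_pitch_um,
                    z_spacing_um = dz[1])
  fs$z_origin_um <- bs$z_origin_um <- depths_um[1]
  list(
    pair = fb_stack_pair(fs, bs, efficiency_forward, efficiency_backward),
    ground_truth = list(
      R = setNames(R, regions), depths_um = depths_um,
      fb_simulated = rho, optics = optics, seed = mc$seed
    )
  )
}

#' Synthetic polarization-resolved series
#'
#' Evaluates the single-axis intensity model ([pshg_intensity()]) per
#' pixel and per polarization angle for given maps of the tensor ratio
#' `b` and orientation `phi0`, scaling each pixel so its peak expected
#' count equals `peak`, with optional Poisson noise.
#'
#' @param b_map Matrix of ground-truth tensor ratios (> 0).
#' @param phi0_map Matrix of ground-truth orientations (degrees), same
#'   shape as `b_map`; a scalar is recycled.
#' @param angles_deg Polarization angles (default 0-180 by 10).
#' @param peak Peak expected counts per pixel (default 500).
#' @param pixel_pitch_um Pixel pitch, um.
#' @param c_ratio Tensor ratio chi_XZX/chi_ZXX used in generation
#'   (default 1).
#' @param noise `"poisson"` or `"none"`.
#' @param seed Seed for the Poisson draw (required when `noise` is
#'   `"poisson"`).
#'
#' @return A list: `series` (a [polarization_series()]) and
#'   `ground_truth` (b and phi0 maps, peak, c_ratio).
#' @export
make_polarization_series <- function(b_map, phi0_map,
                                     angles_deg = seq(0, 180, by = 10),
                                     peak = 500, pixel_pitch_um = 0.354,
                                     c_ratio = 1,
                                     noise = c("poisson", "none"),
                                     seed = NULL) {
  noise <- match.arg(noise)
  if (!is.matrix(b_map)) abort("`b_map` must be a matrix.")
  if (length(phi0_map) == 1) {
    phi0_map <- matrix(phi0_map, nrow(b_map), ncol(b_map))
  }
  if (!identical(dim(b_map), dim(phi0_map))) {
    abort("`b_map` and `phi0_map` must be co-shaped.")
  }
  if (any(b_map <= 0)) abort("`b_map` must be positive.")
  if (noise == "poisson" && is.null(seed)) {
    abort("`seed` is required for Poisson noise.")
  }
  nz <- length(angles_deg)
  frames <- array(0, dim = c(dim(b_map), nz))
  # per-pixel peak of the unit-amplitude model over the angle grid
  unit_peak <- matrix(0, nrow(b_map), ncol(b_map))
  for (k in seq_len(nz)) {
    frames[, , k] <- pshg_intensity(angles_deg[k], 1, b_map, phi0_map,
                                    c_ratio)
    unit_peak <- pmax(unit_peak, frames[, , k])
  }
  for (k in seq_len(nz)) {
    frames[, , k] <- frames[, , k] / unit_peak * peak
  }
  if (noise == "poisson") {
    frames <- with_seed(seed, {
      array(rpois(length(frames), frames), dim = dim(frames))
    })
    frames <- pmin(frames, 4095)
  }
  list(
    series = polarization_series(frames, angles_deg, pixel_pitch_um),
    ground_truth = list(b_map = b_map, phi0_map = phi0_map, peak = peak,
                        c_ratio = c_ratio)
  )
}

#' Synthetic circular-dichroism image pair
#'
#' Solves the left/right intensities from a target per-pixel normalized CD
#' magnitude, `CD = |L - R| / ((L + R) / 2)`, with `L + R = 2 *
#' base_intensity` and a random (or map-given) per-pixel sign, then
#' applies Poisson noise.
#'
#' @param cd_map Matrix of target per-pixel CD values; magnitudes must
#'   not exceed the algebraic bound 2.
#' @param base_intensity Mean of the two expected intensities per pixel.
#' @param sign `"random"` draws the per-pixel polarity sign uniformly;
#'   `"map"` takes it from the sign of `cd_map`.
#' @param noise `"poisson"` or `"none"`.
#' @param noise_threshold Threshold stored in the returned pair.
#' @param seed Seed (required when any randomness is requested).
#'
#' @return A list: `pair` (a [cd_image_pair()]) and `ground_truth`
#'   (signed cd map actually applied, base intensity).
#' @export
make_cd_pair <- function(cd_map, base_intensity, sign = c("random", "map"),
                         noise = c("poisson", "none"), noise_threshold = 15,
                         seed = NULL) {
  sign <- match.arg(sign)
  noise <- match.arg(noise)
  if (!is.matrix(cd_map)) abort("`cd_map` must be a matrix.")
  if (any(abs(cd_map) > 2)) abort("|CD| cannot exceed 2.")
  check_number(base_intensity, "base_intensity", lower = 0,
               closed_lower = FALSE)
  needs_rng <- sign == "random" || noise == "poisson"
  if (needs_rng && is.null(seed)) abort("`seed` is required.")
  gen <- function() {
    s <- if (sign == "random") {
      matrix(base::sample(c(-1, 1), length(cd_map), replace = TRUE),
             nrow(cd_map))
    } else {
      ifelse(cd_map >= 0, 1, -1)
    }
    signed_cd <- s * abs(cd_map)
    lhcp <- base_intensity * (1 + signed_cd / 2)
    rhcp <- base_intensity * (1 - signed_cd / 2)
    if (noise == "poisson") {
      lhcp <- matrix(rpois(length(lhcp), lhcp), nrow(lhcp))
      rhcp <- matrix(rpois(length(rhcp), rhcp), nrow(rhcp))
    }
    list(lhcp = lhcp, rhcp = rhcp, signed_cd = signed_cd)
  }
  out <- if (needs_rng) with_seed(seed, gen()) else gen()
  list(
    pair = cd_image_pair(out$lhcp, out$rhcp, noise_threshold),
    ground_truth = list(cd_map = out$signed_cd,
                        base_intensity = base_intensity)
  )
}

#' Synthetic Beer-Lambert attenuation records
#'
#' Forward model `I = alpha * I0 * exp(-d * mus) * (1 + eps)`, with
#' optional multiplicative Gaussian noise of coefficient of variation
#' `noise_cv`.
#'
#' @param mus Ground-truth scattering coefficient(s), cm^-1 (vectorised:
#'   one record per element).
#' @param d_cm Sample thickness, cm.
#' @param alpha Index-mismatch loss factor in (0, 1\].
#' @param I0 Incident power (detector units).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0 = noiseless).
#' @param seed Seed (required when `noise_cv > 0`).
#'
#' @return A tibble with columns `I`, `I0`, `alpha`, `d_cm` (the inputs
#'   [estimate_mus()] consumes) and the ground truth `mus_true`.
#' @export
make_attenuation_record <- function(mus, d_cm, alpha = 1, I0 = 1,
                                    noise_cv = 0, seed = NULL) {
  if (any(mus < 0)) abort("`mus` must be nonnegative.")
  check_number(d_cm, "d_cm", lower = 0, closed_lower = FALSE)
  check_number(alpha, "alpha", lower = 0, upper = 1, closed_lower = FALSE)
  check_number(I0, "I0", lower = 0, closed_lower = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  I <- alpha * I0 * exp(-d_cm * mus)
  if (noise_cv > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_cv > 0`.")
    I <- with_seed(seed, I * pmax(1 + rnorm(length(I), 0, noise_cv), 1e-12))
    I <- pmin(I, alpha * I0)
  }
  tibble(I = I, I0 = I0, alpha = alpha, d_cm = d_cm, mus_true = mus)
}

#' Synthetic reduced-scattering spectrum
#'
#' Power-law forward model `mus'(lambda) = amplitude * lambda^(2m - 4)` at
#' the standard measurement wavelengths, with optional multiplicative
#' noise, for closure tests of [fit_whittle_matern()].
#'
#' @param m Ground-truth shape factor, within the (0.5, 2.5) sanity
#'   window.
#' @param amplitude Prefactor (> 0) at `lambda = 1 nm`.
#' @param wavelengths_nm Measurement wavelengths (default 390, 495, 545,
#'   780, 990, 1070 nm).
#' @param replicates Replicate measurements per wavelength.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Seed (required when `noise_cv > 0`).
#'
#' @return A tibble with `wavelength_nm`, `mus_reduced_cm1`, and the
#'   ground truth `m_true`.
#' @export
make_spectral_dataset <- function(m, amplitude,
                                  wavelengths_nm = c(390, 495, 545, 780,
                                                     990, 1070),
                                  replicates = 1, noise_cv = 0,
                                  seed = NULL) {
  check_number(m, "m", lower = 0.5, upper = 2.5,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(amplitude, "amplitude", lower = 0, closed_lower = FALSE)
  if (any(wavelengths_nm <= 0)) abort("wavelengths must be positive.")
  check_number(replicates, "replicates", lower = 1)
  check_number(noise_cv, "noise_cv", lower = 0)
  lam <- rep(wavelengths_nm, each = replicates)
  vals <- amplitude * lam^(2 * m - 4)
  if (noise_cv > 0) {
    if (is.null(seed)) abort("`seed` is required when `noise_cv > 0`.")
    vals <- with_seed(seed,
                      vals * pmax(1 + rnorm(length(vals), 0, noise_cv), 1e-12))
  }
  tibble(wavelength_nm = lam, mus_reduced_cm1 = vals, m_true = m)
}
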