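#' Henyey-Greenstein phase-function curve
#'
#' Evaluates `a * (1 - g^2) / (1 + g^2 - 2 g cos(theta))^(3/2)`, the
#' one-parameter angular scattering density used to fit goniometry
#' profiles.
#'
#' @param angle_deg Scattering angles in degrees.
#' @param g Anisotropy in (-1, 1).
#' @param a Overall scale (default 1).
#'
#' @return Numeric vector of intensities.
#' @export
hg_phase <- function(angle_deg, g, a = 1) {
  a * (1 - g^2) / (1 + g^2 - 2 * g * cos(deg2rad(angle_deg)))^1.5
}

#' Scattering coefficient from on-axis attenuation
#'
#' Inverts the Beer-Lambert law `I = alpha * I0 * exp(-d * mus)` for the
#' scattering coefficient, treating absorption as negligible (collagen-rich
#' tissue). `alpha` is a loss factor for refractive-index mismatches at the
#' sample faces, supplied by calibration (default 1).
#'
#' @param records A data frame with columns `I`, `I0`, `d_cm` and
#'   optionally `alpha` (one row per measurement).
#'
#' @return The input as a tibble with an added `mus` column (cm^-1).
#' @examples
#' estimate_mus(data.frame(I = exp(-6.54), I0 = 1, d_cm = 0.02))
#' @export
estimate_mus <- function(records) {
  records <- as_tibble(records)
  required <- c("I", "I0", "d_cm")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("`records` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"alpha" %in% names(records)) records$alpha <- 1
  with(records, {
    if (any(I0 <= 0)) abort("`I0` must be positive.")
    if (any(alpha <= 0 | alpha > 1)) abort("`alpha` must be in (0, 1].")
    if (any(d_cm <= 0)) abort("`d_cm` must be positive.")
    if (any(I <= 0)) abort("`I` must be positive.")
    if (any(I > alpha * I0)) {
      abort("`I` exceeds `alpha * I0`: negative optical depth.")
    }
  })
  dplyr::mutate(records, mus = log(.data$alpha * .data$I0 / .data$I) /
                  .data$d_cm)
}

#' Fit the Henyey-Greenstein phase function to a goniometry profile
#'
#' Unweighted least-squares fit of the HG curve to measured intensity
#' versus scattering angle, returning the effective anisotropy `g_ef`.
#' With multiple scattering in the sample, `g_ef` under-estimates the
#' single-scattering anisotropy; see [correct_anisotropy()].
#'
#' The fit is of radiance sampled by a small detector scanning in a plane,
#' so no `sin(theta)` solid-angle factor is applied. By default the first
#' 2 degrees are excluded so the ballistic (unscattered) delta does not
#' contaminate the fit.
#'
#' @param profile A data frame with columns `angle_deg` and `intensity`,
#'   or an `angular_histogram` from [run_goniometry()] (its scattered-only
#'   per-solid-angle intensities are used).
#' @param fit_range Two-element numeric: angular window in degrees kept in
#'   the fit (default `c(2, 180)`).
#'
#' @return An `hg_fit` object with elements `g_ef`, `a`, `r_squared`,
#'   `data` (the fitted points with a `fitted` column) and `n`.
#'   `tidy()` and `glance()` methods are provided.
#' @examples
#' prof <- tibble::tibble(angle_deg = seq(3, 90, 1),
#'                        intensity = hg_phase(seq(3, 90, 1), g = 0.7))
#' fit_hg(prof)$g_ef
#' @export
fit_hg <- function(profile, fit_range = c(2, 180)) {
  if (inherits(profile, "angular_histogram")) {
    profile <- tibble(angle_deg = profile$histogram$angle_deg,
                      intensity = profile$histogram$intensity)
  }
  profile <- as_tibble(profile)
  if (!all(c("angle_deg", "intensity") %in% names(profile))) {
    abort("`profile` needs columns `angle_deg` and `intensity`.")
  }
  if (is.unsorted(profile$angle_deg, strictly = TRUE)) {
    abort("`angle_deg` must be strictly increasing.")
  }
  if (any(profile$intensity < 0)) abort("`intensity` must be nonnegative.")
  keep <- profile$angle_deg >= fit_range[1] & profile$angle_deg <= fit_range[2]
  pts <- profile[keep, ]
  if (nrow(pts) < 5) abort("need at least 5 points inside `fit_range`.")
  if (all(pts$intensity == 0)) abort("degenerate profile: all intensities 0.")

  # coarse grid on g with the scale solved analytically, then LM refinement
  grid <- seq(-0.95, 0.99, by = 0.01)
  sse <- vapply(grid, function(g) {
    base <- hg_phase(pts$angle_deg, g)
    a <- sum(base * pts$intensity) / sum(base^2)
    sum((pts$intensity - a * base)^2)
  }, numeric(1))
  g0 <- grid[which.min(sse)]
  base0 <- hg_phase(pts$angle_deg, g0)
  a0 <- sum(base0 * pts$intensity) / sum(base0^2)

  fit <- minpack.lm::nlsLM(
    intensity ~ hg_phase(angle_deg, g, a),
    data = pts,
    start = list(g = g0, a = a0),
    lower = c(-0.999999, 0),
    upper = c(0.999999, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  est <- coef(fit)
  pts$fitted <- hg_phase(pts$angle_deg, est[["g"]], est[["a"]])
  ss_res <- sum((pts$intensity - pts$fitted)^2)
  ss_tot <- sum((pts$intensity - mean(pts$intensity))^2)
  structure(
    list(
      g_ef = unname(est[["g"]]), a = unname(est[["a"]]),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      data = pts, n = nrow(pts), fit_range = fit_range
    ),
    class = "hg_fit"
  )
}

#' @export
print.hg_fit <- function(x, ...) {
  cat(sprintf("HG phase-function fit: g_ef = %.4f (a = %.4g, R^2 = %.4f, n = %d)\n",
              x$g_ef, x$a, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.hg_fit <- function(x, ...) {
  tibble(term = c("g_ef", "a"), estimate = c(x$g_ef, x$a))
}

#' @export
glance.hg_fit <- function(x, ...) {
  tibble(g_ef = x$g_ef, r_squared = x$r_squared, n = x$n)
}

#' Correct a measured effective anisotropy for multiple scattering
#'
#' Multiple scattering in a slab of finite optical depth broadens the
#' goniometric angular response, so the fitted `g_ef` lies below the true
#' single-scattering anisotropy. This builds the forward mapping
#' `g_ef_sim(g_single)` by running the slab goniometry Monte Carlo and the
#' HG fit for each candidate `g_single`, then inverts it for the measured
#' `g_ef` by monotone piecewise-linear interpolation.
#'
#' @param g_ef Measured effective anisotropy to correct.
#' @param mus Scattering coefficient of the sample, cm^-1.
#' @param slab A [slab_geometry()] describing the measured section.
#' @param mc An [mc_config()]; each candidate uses a child seed derived
#'   from `mc$seed` so the lookup is reproducible.
#' @param grid Candidate `g_single` values (default 0.80 to 0.98 by 0.02).
#' @param fit_range Passed to [fit_hg()].
#'
#' @return An `anisotropy_correction` object with `g_single`, the measured
#'   `g_ef`, and `lookup`, a tibble of the simulated mapping.
#' @export
correct_anisotropy <- function(g_ef, mus, slab, mc,
                               grid = seq(0.80, 0.98, by = 0.02),
                               fit_range = c(2, 180)) {
  check_number(g_ef, "g_ef", lower = -1, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(mus, "mus", lower = 0)
  stopifnot(inherits(slab, "slab_geometry"), inherits(mc, "mc_config"))
  if (length(grid) < 5) abort("`grid` needs at least 5 candidate g values.")
  grid <- sort(grid)

  g_ef_sim <- vapply(seq_along(grid), function(i) {
    mci <- mc
    mci$seed <- child_seed(mc$seed, i)
    hist <- run_goniometry(scattering_medium(mus, grid[i]), slab, mci)
    fit_hg(hist, fit_range = fit_range)$g_ef
  }, numeric(1))

  lookup <- tibble(g_single = grid, g_ef_sim = g_ef_sim)
  if (g_ef < min(g_ef_sim) || g_ef > max(g_ef_sim)) {
    abort(sprintf(
      "measured g_ef = %.4f lies outside the simulated range [%.4f, %.4f]; widen `grid`.",
      g_ef, min(g_ef_sim), max(g_ef_sim)
    ))
  }
  # invert the (noisy-monotone) mapping; enforce monotonicity with cummax
  mono <- cummax(g_ef_sim)
  g_single <- approx(mono, grid, xout = g_ef, ties = "ordered")$y
  structure(
    list(g_single = g_single, g_ef = g_ef, lookup = lookup,
         monotone = !is.unsorted(g_ef_sim)),
    class = "anisotropy_correction"
  )
}

#' @export
print.anisotropy_correction <- function(x, ...) {
  cat(sprintf("Anisotropy correction: g_ef = %.4f -> g_single = %.4f\n",
              x$g_ef, x$g_single))
  invisible(x)
}

#' Reduced scattering coefficient
#'
#' `mus' = mus * (1 - g)`: the transport-equivalent isotropic scattering
#' rate combining the scattering coefficient and the single-scattering
#' anisotropy.
#'
#' @param mus Scattering coefficient, cm^-1 (vectorised).
#' @param g_single Single-scattering anisotropy, <= 1 (vectorised).
#'
#' @return `mus * (1 - g_single)` in cm^-1.
#' @examples
#' reduced_scattering(260, 0.950) # 13.0
#' @export
reduced_scattering <- function(mus, g_single) {
  if (any(mus < 0)) abort("`mus` must be nonnegative.")
  if (any(g_single > 1)) abort("`g_single` must be <= 1.")
  mus * (1 - g_single)
}

#' Bundle bulk optical properties for one tissue and wavelength
#'
#' @param wavelength_nm Wavelength in nm.
#' @param mus Scattering coefficient, cm^-1.
#' @param g_single Single-scattering anisotropy in \[0, 1).
#'
#' @return An `optical_properties` object; `mus_reduced` is derived as
#'   `mus * (1 - g_single)`.
#' @examples
#' optical_properties(445, 327, 0.914)
#' @export
optical_properties <- function(wavelength_nm, mus, g_single) {
  check_number(wavelength_nm, "wavelength_nm", lower = 0, closed_lower = FALSE)
  check_number(mus, "mus", lower = 0)
  check_number(g_single, "g_single", lower = 0, upper = 1,
               closed_upper = FALSE)
  structure(
    list(wavelength_nm = wavelength_nm, mus = mus, g_single = g_single,
         mus_reduced = reduced_scattering(mus, g_single)),
    class = "optical_properties"
  )
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties at %g nm: mus = %g cm^-1, g = %g, mus' = %g cm^-1\n",
    x$wavelength_nm, x$mus, x$g_single, x$mus_reduced
  ))
  invisible(x)
}

#' Whittle-Matern spectral fit of the reduced scattering coefficient
#'
#' Under the Whittle-Matern refractive-index correlation model the reduced
#' scattering coefficient follows a power law `mus'(lambda) ~ lambda^(2m-4)`,
#' where the shape factor `m` is one half of the mass fractal dimension of
#' the sub-resolution structure. The fit is ordinary least squares of
#' `log(mus')` on `log(lambda)`; replicate measurements at a wavelength are
#' averaged (in log space) before fitting.
#'
#' @param data A data frame with columns `wavelength_nm` and
#'   `mus_reduced_cm1` (one row per measurement; replicates allowed).
#'
#' @return A `wm_fit` object with `m`, `fractal_dimension = 2 m`,
#'   `spectral_exponent = 2 m - 4`, `amplitude` (the prefactor at
#'   `lambda = 1 nm`), `residual_sd` (log space), and the per-wavelength
#'   means used. `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @examples
#' d <- make_spectral_dataset(m = 1.61, amplitude = 5e5)
#' fit_whittle_matern(d)$m
#' @export
fit_whittle_matern <- function(data) {
  data <- as_tibble(data)
  if (!all(c("wavelength_nm", "mus_reduced_cm1") %in% names(data))) {
    abort("`data` needs columns `wavelength_nm` and `mus_reduced_cm1`.")
  }
  if (any(data$mus_reduced_cm1 <= 0)) {
    abort("`mus_reduced_cm1` must be positive for the log-log fit.")
  }
  avg <- data |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(
      log_mus_reduced = mean(log(.data$mus_reduced_cm1)),
      n_replicates = dplyr::n(), .groups = "drop"
    )
  if (nrow(avg) < 3) abort("need at least 3 distinct wavelengths.")
  fit <- lm(log_mus_reduced ~ log(wavelength_nm), data = avg)
  slope <- unname(coef(fit)[2])
  m <- (slope + 4) / 2
  structure(
    list(
      m = m, fractal_dimension = 2 * m, spectral_exponent = slope,
      amplitude = exp(unname(coef(fit)[1])),
      residual_sd = if (nrow(avg) > 2) {
        sqrt(sum(resid(fit)^2) / (nrow(avg) - 2))
      } else {
        NA_real_
      },
      data = avg, lm_fit = fit
    ),
    class = "wm_fit"
  )
}

#' @export
print.wm_fit <- function(x, ...) {
  cat(sprintf(
    "Whittle-Matern spectral fit: m = %.4f (exponent %.4f, fractal dimension %.4f)\n",
    x$m, x$spectral_exponent, x$fractal_dimension
  ))
  invisible(x)
}

#' @export
tidy.wm_fit <- function(x, ...) {
  tibble(
    term = c("m", "spectral_exponent", "amplitude", "fractal_dimension"),
    estimate = c(x$m, x$spectral_exponent, x$amplitude, x$fractal_dimension)
  )
}

#' @export
glance.wm_fit <- function(x, ...) {
  tibble(m = x$m, fractal_dimension = x$fractal_dimension,
         residual_sd = x$residual_sd, n_wavelengths = nrow(x$data))
}
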