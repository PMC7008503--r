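#' Single-axis P-SHG intensity model
#'
#' SHG intensity versus linear excitation polarization angle for a fiber of
#' in-plane orientation `phi0_deg` under C6v symmetry:
#' `I(phi) = A * ((sin^2 D + b cos^2 D)^2 + c^2 sin^2(2 D))`, `D = phi - phi0`,
#' with `b = chi_ZZZ / chi_ZXX` and `c = chi_XZX / chi_ZXX` (Kleinman
#' symmetry fixes `c = 1`).
#'
#' @param phi_deg Polarization angles in degrees (vectorised).
#' @param A Overall amplitude.
#' @param b Tensor ratio chi_ZZZ / chi_ZXX (> 0 for collagen).
#' @param phi0_deg In-plane fiber orientation, degrees.
#' @param c_ratio Tensor ratio chi_XZX / chi_ZXX (default 1).
#'
#' @return Intensities (same length as `phi_deg`).
#' @export
pshg_intensity <- function(phi_deg, A, b, phi0_deg, c_ratio = 1) {
  d <- deg2rad(phi_deg - phi0_deg)
  A * ((sin(d)^2 + b * cos(d)^2)^2 + c_ratio^2 * sin(2 * d)^2)
}

#' Polarization-resolved image series
#'
#' One photon-count frame per linear excitation polarization angle
#' (default 0 to 180 degrees in 10-degree steps, 19 frames).
#'
#' @param frames 3-D array (rows, cols, angle) of photon counts, or a list
#'   of matrices.
#' @param angles_deg Polarization angles, strictly increasing within
#'   \[0, 180\], one per frame.
#' @param pixel_pitch_um Pixel pitch in um.
#'
#' @return A `polarization_series` object.
#' @export
polarization_series <- function(frames, angles_deg = seq(0, 180, by = 10),
                                pixel_pitch_um = 0.354) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) abort("all frames must have the same shape.")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort("`frames` must be a 3-D array or list of matrices.")
  }
  if (dim(frames)[3] != length(angles_deg)) {
    abort("need exactly one frame per angle.")
  }
  if (is.unsorted(angles_deg, strictly = TRUE) ||
      any(angles_deg < 0 | angles_deg > 180)) {
    abort("`angles_deg` must be strictly increasing within [0, 180].")
  }
  structure(
    list(frames = frames, angles_deg = angles_deg,
         pixel_pitch_um = pixel_pitch_um),
    class = "polarization_series"
  )
}

# fit the single-axis model to one pixel's angular intensity trace
fit_pshg_trace <- function(angles_deg, intensity, c_free = FALSE) {
  i_max <- which.max(intensity)
  i_min <- which.min(intensity)
  ratio <- sqrt(max(intensity[i_max], 1e-12) / max(intensity[i_min], 1e-12))
  starts <- list(
    list(phi0 = angles_deg[i_max] %% 180, b = ratio,
         A = max(intensity[i_min], 1e-12)),
    list(phi0 = (angles_deg[i_max] - 90) %% 180, b = 1 / ratio,
         A = max(intensity[i_max], 1e-12))
  )
  dat <- data.frame(phi = angles_deg, y = intensity)
  best <- NULL
  best_sse <- Inf
  for (s in starts) {
    fit <- tryCatch({
      if (c_free) {
        minpack.lm::nlsLM(
          y ~ pshg_intensity(phi, A, b, phi0, c_ratio),
          data = dat,
          start = c(s, list(c_ratio = 1)),
          lower = c(A = 0, b = 1e-6, phi0 = -360, c_ratio = 0),
          control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                               ptol = 1e-15)
        )
      } else {
        minpack.lm::nlsLM(
          y ~ pshg_intensity(phi, A, b, phi0),
          data = dat,
          start = s,
          lower = c(A = 0, b = 1e-6, phi0 = -360),
          control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-15,
                                               ptol = 1e-15)
        )
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(resid(fit)^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    return(list(A = NA_real_, b = NA_real_, phi0 = NA_real_,
                c_ratio = NA_real_, r_squared = NA_real_, converged = FALSE))
  }
  est <- coef(best)
  ss_tot <- sum((intensity - mean(intensity))^2)
  list(
    A = unname(est[["A"]]), b = unname(est[["b"]]),
    phi0 = unname(est[["phi0"]]) %% 180,
    c_ratio = if (c_free) unname(est[["c_ratio"]]) else 1,
    r_squared = if (ss_tot > 0) 1 - best_sse / ss_tot else NA_real_,
    converged = TRUE
  )
}

#' Per-pixel polarization-resolved SHG tensor fit
#'
#' Fits the single-axis C6v intensity model ([pshg_intensity()]) to each
#' masked pixel's intensity-versus-angle trace by nonlinear least squares,
#' returning maps of the tensor ratio `b = chi_ZZZ / chi_ZXX`, the fiber
#' orientation `phi0`, the amplitude, and the goodness of fit. Kleinman
#' symmetry (`c = 1`) is assumed by default; set `c_free = TRUE` to fit
#' `c` as well.
#'
#' @param series A [polarization_series()].
#' @param mask Logical matrix selecting pixels to fit; default: pixels
#'   whose summed intensity over angles is positive.
#' @param c_free Fit the chi_XZX / chi_ZXX ratio instead of fixing it at 1.
#'
#' @return A `pshg_fit` object with matrices `b_map`, `phi0_map`, `A_map`,
#'   `r2_map`, logical `converged`, the `mask`, and `angles_deg`.
#'   Non-convergent pixels are flagged, not fatal. `tidy()` returns the
#'   per-pixel estimates as a tibble.
#' @export
fit_pshg_pixel <- function(series, mask = NULL, c_free = FALSE) {
  stopifnot(inherits(series, "polarization_series"))
  if (length(series$angles_deg) < 7) {
    abort("need at least 7 polarization angles.")
  }
  d <- dim(series$frames)
  if (is.null(mask)) {
    mask <- apply(series$frames, c(1, 2), sum) > 0
  }
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    abort("`mask` must be a logical matrix matching the frame shape.")
  }
  b_map <- phi0_map <- A_map <- r2_map <- c_map <-
    matrix(NA_real_, d[1], d[2])
  converged <- matrix(FALSE, d[1], d[2])
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]
    j <- idx[k, 2]
    res <- fit_pshg_trace(series$angles_deg, series$frames[i, j, ],
                          c_free = c_free)
    b_map[i, j] <- res$b
    phi0_map[i, j] <- res$phi0
    A_map[i, j] <- res$A
    r2_map[i, j] <- res$r_squared
    c_map[i, j] <- res$c_ratio
    converged[i, j] <- res$converged
  }
  structure(
    list(b_map = b_map, phi0_map = phi0_map, A_map = A_map,
         c_map = c_map, r2_map = r2_map, converged = converged, mask = mask,
         angles_deg = series$angles_deg, c_free = c_free),
    class = "pshg_fit"
  )
}

#' @export
print.pshg_fit <- function(x, ...) {
  ok <- x$converged & x$mask
  cat(sprintf(
    "P-SHG pixel fit: %d / %d masked pixels converged; median b = %.4f\n",
    sum(ok), sum(x$mask), median(x$b_map[ok])
  ))
  invisible(x)
}

#' @export
tidy.pshg_fit <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble(
    row = idx[, 1], col = idx[, 2],
    b = x$b_map[idx], phi0_deg = x$phi0_map[idx], A = x$A_map[idx],
    r_squared = x$r2_map[idx], converged = x$converged[idx]
  )
}

#' Field-averaged P-SHG fit
#'
#' Fits the single-axis model to the mean intensity trace over the masked
#' field instead of pixel by pixel; a complement to [fit_pshg_pixel()] for
#' fields with a dominant fiber orientation.
#'
#' @inheritParams fit_pshg_pixel
#' @return A one-row tibble with `b`, `phi0_deg`, `A`, `r_squared`.
#' @export
fit_pshg_field <- function(series, mask = NULL, c_free = FALSE) {
  stopifnot(inherits(series, "polarization_series"))
  d <- dim(series$frames)
  if (is.null(mask)) mask <- apply(series$frames, c(1, 2), sum) > 0
  trace <- vapply(seq_len(d[3]), function(k) {
    mean(series$frames[, , k][mask])
  }, numeric(1))
  res <- fit_pshg_trace(series$angles_deg, trace, c_free = c_free)
  tibble(b = res$b, phi0_deg = res$phi0, A = res$A,
         r_squared = res$r_squared)
}

#' Alpha-helical pitch angle from the tensor ratio
#'
#' Under the single-axis molecular model the effective pitch angle of the
#' collagen alpha-helix is `theta_p = atan(sqrt(2) / b)`, strictly
#' decreasing in the tensor ratio `b`.
#'
#' @param b Tensor ratio(s) chi_ZZZ / chi_ZXX, > 0.
#'
#' @return Pitch angle(s) in degrees, in (0, 90).
#' @examples
#' pitch_angle(sqrt(2)) # 45 degrees
#' @export
pitch_angle <- function(b) {
  if (any(!is.finite(b)) || any(b <= 0)) abort("`b` must be positive.")
  rad2deg(atan(sqrt(2) / b))
}

#' Pitch-angle map and summary from a P-SHG fit
#'
#' @param fit A `pshg_fit` from [fit_pshg_pixel()].
#'
#' @return A `pitch_result`: `map` (degrees, NA off-mask or
#'   non-convergent) and `summary`, a one-row tibble with the masked mean,
#'   SE and pixel count.
#' @export
pitch_angles <- function(fit) {
  stopifnot(inherits(fit, "pshg_fit"))
  ok <- fit$converged & fit$mask & is.finite(fit$b_map) & fit$b_map > 0
  map <- matrix(NA_real_, nrow(fit$b_map), ncol(fit$b_map))
  map[ok] <- pitch_angle(fit$b_map[ok])
  vals <- map[ok]
  structure(
    list(
      map = map,
      summary = tibble(
        mean_deg = mean(vals),
        se_deg = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else NA_real_,
        n_pixels = length(vals)
      )
    ),
    class = "pitch_result"
  )
}

#' @export
print.pitch_result <- function(x, ...) {
  cat(sprintf("Pitch angle: %.3f deg (SE %.4g, %d pixels)\n",
              x$summary$mean_deg, x$summary$se_deg, x$summary$n_pixels))
  invisible(x)
}

#' Circular-dichroism image pair
#'
#' Co-registered SHG images acquired under left- and right-handed circular
#' excitation.
#'
#' @param lhcp,rhcp Photon-count matrices of identical shape.
#' @param noise_threshold Count threshold above the noise background; a
#'   pixel enters the CD mask when its mean intensity `(L + R) / 2`
#'   exceeds it.
#'
#' @return A `cd_image_pair` object.
#' @export
cd_image_pair <- function(lhcp, rhcp, noise_threshold = 15) {
  if (!is.matrix(lhcp) || !is.matrix(rhcp) ||
      !identical(dim(lhcp), dim(rhcp))) {
    abort("`lhcp` and `rhcp` must be co-registered matrices.")
  }
  check_number(noise_threshold, "noise_threshold", lower = 0)
  structure(list(lhcp = lhcp, rhcp = rhcp, noise_threshold = noise_threshold),
            class = "cd_image_pair")
}

#' Normalized SHG circular dichroism
#'
#' Per-pixel normalized CD,
#' `CD = (I_LHCP - I_RHCP) / ((I_LHCP + I_RHCP) / 2)`, computed over the
#' mask of pixels whose mean intensity exceeds the noise threshold. The
#' sign of the per-pixel response depends on fiber polarity, so the
#' summary statistic is the mean of |CD| over the mask (the raw sum of
#' |CD| is also reported, but it scales with mask area and is not
#' comparable across fields). |CD| is algebraically bounded by 2.
#'
#' @param pair A [cd_image_pair()].
#'
#' @return A `cd_result`: signed `cd_map` (NA off-mask), logical `mask`,
#'   `mean_abs_cd`, `sum_abs_cd`, `mask_fraction`, `n_pixels`.
#' @examples
#' p <- cd_image_pair(matrix(300, 4, 4), matrix(100, 4, 4))
#' compute_shg_cd(p)$mean_abs_cd # |300-100|/200 = 1
#' @export
compute_shg_cd <- function(pair) {
  stopifnot(inherits(pair, "cd_image_pair"))
  mean_img <- (pair$lhcp + pair$rhcp) / 2
  mask <- mean_img > pair$noise_threshold
  if (!any(mask)) abort("empty mask: no pixels above the noise threshold.")
  cd_map <- matrix(NA_real_, nrow(mean_img), ncol(mean_img))
  cd_map[mask] <- (pair$lhcp[mask] - pair$rhcp[mask]) / mean_img[mask]
  structure(
    list(
      cd_map = cd_map, mask = mask,
      mean_abs_cd = mean(abs(cd_map[mask])),
      sum_abs_cd = sum(abs(cd_map[mask])),
      mask_fraction = mean(mask), n_pixels = sum(mask)
    ),
    class = "cd_result"
  )
}

#' @export
print.cd_result <- function(x, ...) {
  cat(sprintf(
    "SHG-CD: mean |CD| = %.4f over %d pixels (%.1f%% of field)\n",
    x$mean_abs_cd, x$n_pixels, 100 * x$mask_fraction
  ))
  invisible(x)
}

#' Compare SHG-CD between two groups of images
#'
#' Compares per-image mean |CD| summaries between two groups with a
#' two-sample Student's t-test (the two-group arm of the group-comparison
#' protocol; see [compare_groups()]).
#'
#' @param results_a,results_b Numeric vectors of per-image mean |CD|
#'   values, or lists of `cd_result` objects.
#'
#' @return A one-row tibble: group means and SEs, `ratio` (A over B),
#'   `statistic`, `p_value`, and `significant` at alpha = 0.05.
#' @export
compare_cd_groups <- function(results_a, results_b) {
  pull_cd <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(r) {
      if (!inherits(r, "cd_result")) abort("expected cd_result objects.")
      r$mean_abs_cd
    }, numeric(1))
  }
  a <- pull_cd(results_a)
  b <- pull_cd(results_b)
  if (length(a) < 2 || length(b) < 2) {
    abort("need at least 2 images per group.")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(
    mean_a = mean(a), se_a = sd(a) / sqrt(length(a)),
    mean_b = mean(b), se_b = sd(b) / sqrt(length(b)),
    ratio = mean(a) / mean(b),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    significant = tt$p.value < 0.05
  )
}
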