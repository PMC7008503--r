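#' Photon-count image stack
#'
#' Container for a z-stack of photon-count images, the unit every image
#' analysis consumes. Planes are stored as a rows x cols x depth numeric
#' array of nonnegative integer counts.
#'
#' @param planes A 3-D array (rows, cols, planes), a matrix (single plane),
#'   or a list of equally sized matrices.
#' @param pixel_pitch_um Pixel pitch in um.
#' @param z_spacing_um Plane spacing in um.
#' @param bit_depth Detector bit depth (default 12; counts must fit).
#'
#' @return An `image_stack` object.
#' @export
image_stack <- function(planes, pixel_pitch_um, z_spacing_um = 1,
                        bit_depth = 12) {
  if (is.list(planes)) {
    dims <- unique(lapply(planes, dim))
    if (length(dims) != 1) abort("all planes must have the same shape.")
    planes <- array(unlist(planes), dim = c(dims[[1]], length(planes)))
  }
  if (is.matrix(planes)) planes <- array(planes, dim = c(dim(planes), 1))
  if (!is.array(planes) || length(dim(planes)) != 3) {
    abort("`planes` must be a matrix, 3-D array, or list of matrices.")
  }
  check_number(pixel_pitch_um, "pixel_pitch_um", lower = 0,
               closed_lower = FALSE)
  check_number(z_spacing_um, "z_spacing_um", lower = 0, closed_lower = FALSE)
  check_number(bit_depth, "bit_depth", lower = 1)
  if (any(planes < 0)) abort("counts must be nonnegative.")
  if (any(planes > 2^bit_depth - 1)) {
    abort(sprintf("counts exceed the %d-bit maximum %d.", bit_depth,
                  2^bit_depth - 1))
  }
  structure(
    list(planes = planes, pixel_pitch_um = pixel_pitch_um,
         z_spacing_um = z_spacing_um, bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf(
    "Image stack: %d x %d px x %d planes, %g um pitch, %g um z-spacing, %d-bit\n",
    d[1], d[2], d[3], x$pixel_pitch_um, x$z_spacing_um, x$bit_depth
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$planes)

#' Paired forward/backward detector stacks
#'
#' Co-registered image stacks from the forward (transmission) and backward
#' (epi) SHG detectors, plus their calibrated collection efficiencies.
#'
#' @param forward,backward [image_stack()] objects with identical shapes
#'   and z grids.
#' @param efficiency_forward,efficiency_backward Detector collection
#'   efficiencies (> 0); measured ratios are corrected by dividing each
#'   channel by its efficiency.
#'
#' @return An `fb_stack_pair` object.
#' @export
fb_stack_pair <- function(forward, backward, efficiency_forward = 1,
                          efficiency_backward = 1) {
  stopifnot(inherits(forward, "image_stack"), inherits(backward, "image_stack"))
  if (!identical(dim(forward$planes), dim(backward$planes))) {
    abort("forward and backward stacks must have identical shapes.")
  }
  if (forward$z_spacing_um != backward$z_spacing_um) {
    abort("forward and backward stacks must share the z grid.")
  }
  check_number(efficiency_forward, "efficiency_forward", lower = 0,
               closed_lower = FALSE)
  check_number(efficiency_backward, "efficiency_backward", lower = 0,
               closed_lower = FALSE)
  structure(
    list(forward = forward, backward = backward,
         efficiency_forward = efficiency_forward,
         efficiency_backward = efficiency_backward),
    class = "fb_stack_pair"
  )
}

fb_plane_stats <- function(fplane, bplane, eff_f, eff_b, mask_threshold) {
  mask <- fplane > mask_threshold | bplane > mask_threshold
  sf <- sum(fplane[mask])
  sb <- sum(bplane[mask])
  valid <- sb > 0
  fb <- if (valid) (sf / eff_f) / (sb / eff_b) else NA_real_
  # Poisson propagation on the raw count sums
  se <- if (valid && sf > 0) fb * sqrt(1 / sf + 1 / sb) else NA_real_
  list(fb = fb, se = se, n_pixels = sum(mask), sum_f = sf, sum_b = sb,
       valid = valid)
}

#' Depth-resolved measured F/B profile
#'
#' For each plane of a co-registered forward/backward stack pair, sums the
#' counts of both channels over pixels where either channel exceeds
#' `mask_threshold`, corrects by the detector efficiencies, and forms the
#' measured F/B ratio. The per-depth uncertainty is propagated from Poisson
#' counting statistics of the two sums. Depth is measured from the top
#' (backward-detector side) face; plane 1 is the shallowest.
#'
#' @param pair An [fb_stack_pair()].
#' @param mask_threshold Count threshold for a pixel to contribute
#'   (default 15, matching the packing-efficiency mask on 12-bit data).
#'
#' @return An `fb_profile`: a tibble with columns `depth_um`,
#'   `fb_measured`, `fb_se`, `n_pixels`, `valid`. Planes with no backward
#'   signal above threshold are flagged invalid (NA ratio) rather than
#'   dropped.
#' @export
measure_fb_profile <- function(pair, mask_threshold = 15) {
  stopifnot(inherits(pair, "fb_stack_pair"))
  check_number(mask_threshold, "mask_threshold", lower = 0)
  nz <- dim(pair$forward$planes)[3]
  z0 <- if (is.null(pair$forward$z_origin_um)) 0 else pair$forward$z_origin_um
  rows <- purrr::map(seq_len(nz), function(k) {
    st <- fb_plane_stats(pair$forward$planes[, , k], pair$backward$planes[, , k],
                         pair$efficiency_forward, pair$efficiency_backward,
                         mask_threshold)
    tibble(
      depth_um = z0 + (k - 1) * pair$forward$z_spacing_um,
      fb_measured = st$fb, fb_se = st$se, n_pixels = st$n_pixels,
      valid = st$valid
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fb_profile", class(out))
  attr(out, "mask_threshold") <- mask_threshold
  out
}

#' Per-patch F/B analysis
#'
#' Tiles each plane into non-overlapping square patches (default 15 x 15
#' pixels, about 5.3 x 5.3 um at the native pitch) and computes the
#' depth-resolved F/B within each patch, to quantify the spatial
#' heterogeneity of the SHG directionality. A patch-plane is valid when at
#' least `min_signal_frac` of its pixels exceed `mask_threshold` in the
#' forward channel.
#'
#' @param pair An [fb_stack_pair()].
#' @param patch_size Patch edge in pixels (default 15). Trailing pixels
#'   that do not fill a whole patch are dropped.
#' @param mask_threshold Count threshold for the pixel mask (default 15).
#' @param min_signal_frac Minimum fraction of above-threshold forward-channel
#'   pixels for a patch-plane to be valid (default 0.25).
#'
#' @return A `patch_map` object: `profiles` (tibble of per-patch, per-depth
#'   F/B), `patch_fb` (tibble of per-patch depth-pooled F/B), and summary
#'   `mean` and `std_dev` over valid patches.
#' @export
measure_fb_patches <- function(pair, patch_size = 15, mask_threshold = 15,
                               min_signal_frac = 0.25) {
  stopifnot(inherits(pair, "fb_stack_pair"))
  check_number(patch_size, "patch_size", lower = 3)
  d <- dim(pair$forward$planes)
  if (d[1] < patch_size || d[2] < patch_size) {
    abort("image dimensions must be at least `patch_size`.")
  }
  nr <- d[1] %/% patch_size
  nc <- d[2] %/% patch_size
  nz <- d[3]
  z0 <- if (is.null(pair$forward$z_origin_um)) 0 else pair$forward$z_origin_um
  eff_f <- pair$efficiency_forward
  eff_b <- pair$efficiency_backward

  grid <- tidyr::expand_grid(patch_row = seq_len(nr), patch_col = seq_len(nc))
  profiles <- purrr::pmap(grid, function(patch_row, patch_col) {
    ri <- ((patch_row - 1) * patch_size + 1):(patch_row * patch_size)
    ci <- ((patch_col - 1) * patch_size + 1):(patch_col * patch_size)
    purrr::map(seq_len(nz), function(k) {
      fp <- pair$forward$planes[ri, ci, k]
      bp <- pair$backward$planes[ri, ci, k]
      st <- fb_plane_stats(fp, bp, eff_f, eff_b, mask_threshold)
      signal_frac <- mean(fp > mask_threshold)
      tibble(
        patch_row = patch_row, patch_col = patch_col,
        depth_um = z0 + (k - 1) * pair$forward$z_spacing_um,
        fb_measured = st$fb, fb_se = st$se,
        sum_f = st$sum_f, sum_b = st$sum_b,
        valid = st$valid && signal_frac >= min_signal_frac
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  patch_fb <- profiles |>
    dplyr::group_by(.data$patch_row, .data$patch_col) |>
    dplyr::summarise(
      fb = if (any(.data$valid) && sum(.data$sum_b[.data$valid]) > 0) {
        (sum(.data$sum_f[.data$valid]) / eff_f) /
          (sum(.data$sum_b[.data$valid]) / eff_b)
      } else {
        NA_real_
      },
      n_valid_depths = sum(.data$valid), .groups = "drop"
    ) |>
    dplyr::mutate(valid = !is.na(.data$fb))

  ok <- patch_fb$fb[patch_fb$valid]
  structure(
    list(
      profiles = profiles, patch_fb = patch_fb,
      patch_size = patch_size,
      patch_extent_um = patch_size * pair$forward$pixel_pitch_um,
      mean = if (length(ok) > 0) mean(ok) else NA_real_,
      std_dev = if (length(ok) > 1) sd(ok) else NA_real_,
      n_patches = nrow(patch_fb), n_valid = length(ok)
    ),
    class = "patch_map"
  )
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf(
    "Patch F/B map: %d patches of %d px (%.2f um), %d valid; mean = %.3f, sd = %.3f\n",
    x$n_patches, x$patch_size, x$patch_extent_um, x$n_valid, x$mean, x$std_dev
  ))
  invisible(x)
}

# simulate the measured F/B at given depths for one candidate creation ratio
simulate_fb_curve <- function(R, depths_um, optics, slab, det, mc,
                              seed_offset = 0, source_profile = "cone",
                              isotropic_equivalent = FALSE) {
  medium <- scattering_medium(optics$mus, optics$g_single)
  vapply(seq_along(depths_um), function(j) {
    mcj <- mc
    mcj$seed <- child_seed(mc$seed, seed_offset * 1000 + j)
    run_shg_emission(R, depths_um[j] * 1e-4, medium, slab, det, mcj,
                     source_profile = source_profile,
                     isotropic_equivalent = isotropic_equivalent)$fb_measured
  }, numeric(1))
}

#' Extract the SHG creation ratio from a measured F/B depth profile
#'
#' The intrinsic emission directionality F_SHG/B_SHG ("creation ratio") is
#' recovered from the depth-dependent measured F/B by forward-modelling:
#' for each candidate ratio on a grid, the Monte Carlo emission model
#' ([run_shg_emission()]) predicts the measured F/B at the profile's
#' depths under the sample's bulk optical properties at the SHG
#' wavelength; the candidate minimising the reduced chi-squared against
#' the measured profile (with its Poisson-propagated uncertainties) is
#' returned, refined between grid points by parabolic interpolation of the
#' chi-squared surface. Per-candidate seeds are fixed so the chi-squared
#' surface is deterministic for a given configuration.
#'
#' @param profile An `fb_profile` from [measure_fb_profile()] (or any data
#'   frame with `depth_um`, `fb_measured`, `fb_se`, `valid`).
#' @param optics An [optical_properties()] at the SHG wavelength.
#' @param slab A [slab_geometry()].
#' @param det A [detection_geometry()].
#' @param mc An [mc_config()]; `n_photons` is per candidate per depth.
#' @param grid Candidate creation ratios (default 1.0 to 5.0 by 0.25).
#' @param source_profile,isotropic_equivalent Passed to
#'   [run_shg_emission()].
#'
#' @return A `creation_fit` object: `fb_creation`, `reduced_chi2`,
#'   `candidates` (tibble of per-candidate reduced chi-squared),
#'   `profile` with the best simulated curve attached, and a
#'   `boundary` flag set when the minimum sits on the grid edge.
#' @export
extract_creation_ratio <- function(profile, optics, slab, det, mc,
                                   grid = seq(1, 5, by = 0.25),
                                   source_profile = c("cone", "axial"),
                                   isotropic_equivalent = FALSE) {
  stopifnot(inherits(optics, "optical_properties"),
            inherits(slab, "slab_geometry"),
            inherits(det, "detection_geometry"), inherits(mc, "mc_config"))
  source_profile <- match.arg(source_profile)
  profile <- as_tibble(profile)
  if (!all(c("depth_um", "fb_measured", "fb_se", "valid") %in% names(profile))) {
    abort("`profile` needs columns depth_um, fb_measured, fb_se, valid.")
  }
  use <- profile[profile$valid & is.finite(profile$fb_measured) &
                   is.finite(profile$fb_se) & profile$fb_se > 0, ]
  if (nrow(use) < 3) abort("need at least 3 valid depths.")
  if (length(grid) < 2) abort("`grid` needs at least 2 candidates.")
  grid <- sort(grid)
  dof <- nrow(use) - 1

  curves <- purrr::map(seq_along(grid), function(i) {
    simulate_fb_curve(grid[i], use$depth_um, optics, slab, det, mc,
                      seed_offset = i, source_profile = source_profile,
                      isotropic_equivalent = isotropic_equivalent)
  })
  chi2 <- vapply(curves, function(sim) {
    sum(((use$fb_measured - sim) / use$fb_se)^2) / dof
  }, numeric(1))

  i_min <- which.min(chi2)
  boundary <- i_min == 1 || i_min == length(grid)
  if (!boundary) {
    # parabola through the bracketing triple for sub-grid resolution
    x <- grid[(i_min - 1):(i_min + 1)]
    y <- chi2[(i_min - 1):(i_min + 1)]
    denom <- (y[1] - 2 * y[2] + y[3])
    if (is.finite(denom) && denom > 0) {
      r_best <- x[2] - (x[3] - x[1]) / 2 * (y[3] - y[1]) /
        (2 * (y[1] - 2 * y[2] + y[3]))
      r_best <- min(max(r_best, x[1]), x[3])
      chi2_best <- y[2] - (y[3] - y[1])^2 / (8 * denom)
    } else {
      r_best <- grid[i_min]
      chi2_best <- chi2[i_min]
    }
  } else {
    r_best <- grid[i_min]
    chi2_best <- chi2[i_min]
  }

  prof_out <- use
  prof_out$fb_simulated_best <- curves[[i_min]]
  structure(
    list(
      fb_creation = r_best, reduced_chi2 = chi2_best,
      candidates = tibble(candidate = grid, reduced_chi2 = chi2),
      profile = prof_out, boundary = boundary, dof = dof,
      grid_minimum = grid[i_min]
    ),
    class = "creation_fit"
  )
}

#' @export
print.creation_fit <- function(x, ...) {
  cat(sprintf(
    "SHG creation-ratio fit: F_SHG/B_SHG = %.3f (reduced chi^2 = %.3g, %d depths)%s\n",
    x$fb_creation, x$reduced_chi2, x$dof + 1,
    if (x$boundary) " [boundary solution]" else ""
  ))
  invisible(x)
}

#' @export
tidy.creation_fit <- function(x, ...) x$candidates

#' @export
glance.creation_fit <- function(x, ...) {
  tibble(fb_creation = x$fb_creation, reduced_chi2 = x$reduced_chi2,
         boundary = x$boundary, n_depths = x$dof + 1)
}

#' Summarise patch-level F/B across stacks and tissues
#'
#' Pools per-patch F/B values across a collection of stacks: the group
#' mean and standard error are computed over per-stack means, and the
#' heterogeneity statistic is the standard deviation of patch values
#' computed within each tissue and then averaged across tissues.
#'
#' @param maps A list of `patch_map` objects (one per stack).
#' @param tissue_ids Optional vector assigning each stack to a tissue;
#'   defaults to one tissue per stack.
#'
#' @return A one-row tibble: `mean`, `se` (NA with a single stack),
#'   `n_stacks`, `heterogeneity_sd`.
#' @export
summarize_patch_fits <- function(maps, tissue_ids = NULL) {
  if (inherits(maps, "patch_map")) maps <- list(maps)
  if (length(maps) == 0) abort("`maps` is empty.")
  if (!all(vapply(maps, inherits, logical(1), "patch_map"))) {
    abort("`maps` must be a list of patch_map objects.")
  }
  if (is.null(tissue_ids)) tissue_ids <- seq_along(maps)
  if (length(tissue_ids) != length(maps)) {
    abort("`tissue_ids` must match `maps` in length.")
  }
  stack_means <- vapply(maps, function(m) m$mean, numeric(1))
  if (!any(is.finite(stack_means))) abort("no valid patches in any map.")
  patch_values <- purrr::map2(maps, tissue_ids, function(m, id) {
    tibble(tissue = id, fb = m$patch_fb$fb[m$patch_fb$valid])
  }) |> dplyr::bind_rows()
  per_tissue_sd <- patch_values |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(sd = sd(.data$fb), .groups = "drop")
  tibble(
    mean = mean(stack_means, na.rm = TRUE),
    se = if (sum(is.finite(stack_means)) > 1) {
      sd(stack_means, na.rm = TRUE) / sqrt(sum(is.finite(stack_means)))
    } else {
      NA_real_
    },
    n_stacks = length(maps),
    heterogeneity_sd = mean(per_tissue_sd$sd, na.rm = TRUE)
  )
}
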