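#' Slab geometry for photon transport
#'
#' Describes the tissue section as an infinite slab of finite thickness with
#' matched or mismatched refractive indices at its faces. Depths are measured
#' from the top face (the backward-detector side), so the bottom face at
#' `thickness_cm` is the forward-detector side.
#'
#' @param thickness_cm Slab thickness in cm (a 200 um section is 0.02).
#' @param n_inside Refractive index of the tissue (default 1.40).
#' @param n_outside Refractive index of the surrounding medium
#'   (default 1.33, aqueous mounting).
#'
#' @return A `slab_geometry` object.
#' @examples
#' slab_geometry(0.02)
#' @export
slab_geometry <- function(thickness_cm, n_inside = 1.40, n_outside = 1.33) {
  check_number(thickness_cm, "thickness_cm", lower = 0, closed_lower = FALSE)
  check_number(n_inside, "n_inside", lower = 1)
  check_number(n_outside, "n_outside", lower = 1)
  structure(
    list(thickness_cm = thickness_cm, n_inside = n_inside,
         n_outside = n_outside),
    class = "slab_geometry"
  )
}

#' Scattering medium
#'
#' Bulk optical properties of a turbid medium: scattering coefficient
#' `mus` (cm^-1), single-scattering anisotropy `g` (the mean cosine of the
#' Henyey-Greenstein deflection angle), and absorption coefficient `mua`
#' (cm^-1). For collagen-rich tissue absorption is negligible next to
#' scattering, so `mua` defaults to 0.
#'
#' @param mus Scattering coefficient, cm^-1.
#' @param g Single-scattering anisotropy, strictly inside (-1, 1).
#' @param mua Absorption coefficient, cm^-1 (default 0).
#'
#' @return A `scattering_medium` object.
#' @examples
#' scattering_medium(mus = 327, g = 0.914)
#' @export
scattering_medium <- function(mus, g, mua = 0) {
  check_number(mus, "mus", lower = 0)
  check_number(g, "g", lower = -1, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(mua, "mua", lower = 0)
  structure(list(mus = mus, g = g, mua = mua), class = "scattering_medium")
}

#' Detection geometry
#'
#' Numerical apertures of the two detection paths: the forward
#' (transmission, condenser) side and the backward (epi, objective) side.
#'
#' @param na_forward Forward-collection numerical aperture (default 0.9,
#'   a typical high-NA condenser).
#' @param na_backward Backward-collection numerical aperture (default 0.8,
#'   a 40x water-immersion objective).
#'
#' @return A `detection_geometry` object.
#' @export
detection_geometry <- function(na_forward = 0.9, na_backward = 0.8) {
  check_number(na_forward, "na_forward", lower = 0, closed_lower = FALSE)
  check_number(na_backward, "na_backward", lower = 0, closed_lower = FALSE)
  structure(list(na_forward = na_forward, na_backward = na_backward),
            class = "detection_geometry")
}

#' Monte Carlo run configuration
#'
#' @param n_photons Number of photon histories to launch.
#' @param seed Integer seed; every run is bit-identical for a fixed seed.
#' @param roulette_threshold Weight below which Russian roulette is played
#'   (only reached when `mua > 0`).
#' @param roulette_survival Survival probability of the roulette.
#'
#' @return An `mc_config` object.
#' @export
mc_config <- function(n_photons, seed, roulette_threshold = 1e-4,
                      roulette_survival = 0.1) {
  check_number(n_photons, "n_photons", lower = 1)
  check_number(seed, "seed")
  check_number(roulette_threshold, "roulette_threshold", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(roulette_survival, "roulette_survival", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  structure(
    list(n_photons = as.integer(n_photons), seed = seed,
         roulette_threshold = roulette_threshold,
         roulette_survival = roulette_survival),
    class = "mc_config"
  )
}

#' Sample the Henyey-Greenstein scattering cosine
#'
#' Inverse-CDF draw of the cosine of the polar deflection angle from the
#' Henyey-Greenstein phase function with anisotropy `g`. For `g = 0` the
#' cosine is uniform on \[-1, 1\]; otherwise the standard closed-form
#' inverse is used, so the expectation of the returned cosine equals `g`.
#'
#' @param g Anisotropy, strictly inside (-1, 1). Scalar.
#' @param u Uniform variates in \[0, 1). Vectorised.
#'
#' @return Numeric vector of cosines in \[-1, 1\].
#' @examples
#' mean(sample_hg_cos(0.9, runif(1e4))) # close to 0.9
#' @export
sample_hg_cos <- function(g, u) {
  check_number(g, "g", lower = -1, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  if (!is.numeric(u) || any(u < 0 | u >= 1)) {
    abort("`u` must be numeric in [0, 1).")
  }
  if (abs(g) < 1e-12) {
    return(2 * u - 1)
  }
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Slab goniometry by Monte Carlo
#'
#' Launches photons normally incident on the top face of the slab and
#' propagates them with exponential free paths (rate `mus + mua`),
#' Henyey-Greenstein deflection and uniform azimuth, tallying the exit
#' polar angle (relative to the incident axis) of every photon that leaves
#' the slab. Ballistic (never-scattered) photons are tallied separately
#' because they form a delta at 0 degrees that the phase function does not
#' describe.
#'
#' @param medium A [scattering_medium()].
#' @param slab A [slab_geometry()].
#' @param mc An [mc_config()].
#' @param n_bins Number of angular bins over \[0, 180\] degrees
#'   (default 180, i.e. 1-degree bins).
#'
#' @return An `angular_histogram` object: a list with `histogram` (a tibble
#'   with `angle_deg` bin midpoints and `weight`), `ballistic_weight`,
#'   `n_launched`, and the run configuration.
#' @examples
#' h <- run_goniometry(scattering_medium(260, 0.95), slab_geometry(0.02),
#'                     mc_config(1e4, seed = 1))
#' head(h$histogram)
#' @export
run_goniometry <- function(medium, slab, mc, n_bins = 180) {
  stopifnot(inherits(medium, "scattering_medium"),
            inherits(slab, "slab_geometry"), inherits(mc, "mc_config"))
  check_number(n_bins, "n_bins", lower = 1)
  res <- .mc_goniometry_cpp(
    n_photons = mc$n_photons, seed = mc$seed,
    mus = medium$mus, mua = medium$mua, g = medium$g,
    thickness = slab$thickness_cm, n_bins = as.integer(n_bins),
    roulette_threshold = mc$roulette_threshold,
    roulette_survival = mc$roulette_survival
  )
  width <- 180 / n_bins
  edges <- seq(0, 180, by = width)
  lo <- head(edges, -1)
  hi <- tail(edges, -1)
  # per-solid-angle intensity: what a small detector scanning the polar
  # angle measures (the azimuthal ring's solid angle is divided out)
  ring_sr <- 2 * pi * (cos(deg2rad(lo)) - cos(deg2rad(hi)))
  structure(
    list(
      histogram = tibble(
        angle_deg = lo + width / 2,
        angle_lo = lo,
        angle_hi = hi,
        weight = as.numeric(res$weights),
        intensity = as.numeric(res$weights) / ring_sr
      ),
      ballistic_weight = res$ballistic_weight,
      absorbed_weight = res$absorbed_weight,
      total_exit_weight = res$total_exit_weight,
      n_launched = mc$n_photons,
      medium = medium, slab = slab, mc = mc
    ),
    class = "angular_histogram"
  )
}

#' @export
print.angular_histogram <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo goniometry: %d photons, mus = %g cm^-1, g = %g, d = %g cm\n",
    x$n_launched, x$medium$mus, x$medium$g, x$slab$thickness_cm
  ))
  cat(sprintf("  scattered exit weight %.1f, ballistic %.1f, absorbed %.1f\n",
              sum(x$histogram$weight), x$ballistic_weight, x$absorbed_weight))
  invisible(x)
}

#' Depth-resolved SHG emission by Monte Carlo
#'
#' Simulates the detection of second-harmonic photons created at a given
#' depth inside the slab with an intrinsic forward/backward creation ratio
#' `creation_ratio` (F_SHG/B_SHG). A fraction `R/(R+1)` of photons is
#' launched into the forward (+z) emission cone and `1/(R+1)` into the
#' backward cone; each propagates through the scattering medium at the SHG
#' wavelength and is tallied if it exits a face within the corresponding
#' detection numerical aperture. The simulated measured ratio is
#' `forward_weight / backward_weight`.
#'
#' @param creation_ratio Intrinsic F_SHG/B_SHG at the source, > 0.
#' @param source_depth_cm Creation depth below the top face, in cm,
#'   within \[0, thickness\].
#' @param medium A [scattering_medium()] at the SHG wavelength.
#' @param slab A [slab_geometry()].
#' @param det A [detection_geometry()].
#' @param mc An [mc_config()].
#' @param source_profile `"cone"` (default) draws initial directions
#'   uniformly in solid angle within the detection-matched cone about the
#'   axis; `"axial"` launches strictly along the axis.
#' @param isotropic_equivalent If `TRUE`, transport uses the reduced
#'   (similarity-transformed) description `mus' = mus * (1 - g)` with
#'   isotropic scattering instead of the full `(mus, g)` pair.
#'
#' @return An `fb_tally` object: forward/backward/lost weights, photon
#'   counts per detector, and `fb_measured = forward_weight / backward_weight`
#'   (NA when no backward photons were detected).
#' @examples
#' run_shg_emission(2.67, 0.005, scattering_medium(327, 0.914),
#'                  slab_geometry(0.02), detection_geometry(),
#'                  mc_config(1e4, seed = 7))
#' @export
run_shg_emission <- function(creation_ratio, source_depth_cm, medium, slab,
                             det, mc, source_profile = c("cone", "axial"),
                             isotropic_equivalent = FALSE) {
  check_number(creation_ratio, "creation_ratio", lower = 0,
               closed_lower = FALSE)
  stopifnot(inherits(medium, "scattering_medium"),
            inherits(slab, "slab_geometry"),
            inherits(det, "detection_geometry"), inherits(mc, "mc_config"))
  check_number(source_depth_cm, "source_depth_cm", lower = 0,
               upper = slab$thickness_cm)
  source_profile <- match.arg(source_profile)
  check_flag(isotropic_equivalent, "isotropic_equivalent")
  if (det$na_forward > slab$n_outside || det$na_backward > slab$n_outside) {
    abort("detection NA cannot exceed the outside refractive index.")
  }
  mus <- medium$mus
  g <- medium$g
  if (isotropic_equivalent) {
    mus <- medium$mus * (1 - medium$g)
    g <- 0
  }
  cos_min_f <- sqrt(1 - (det$na_forward / slab$n_outside)^2)
  cos_min_b <- sqrt(1 - (det$na_backward / slab$n_outside)^2)
  res <- .mc_fb_cpp(
    n_photons = mc$n_photons, seed = mc$seed,
    mus = mus, mua = medium$mua, g = g,
    thickness = slab$thickness_cm, source_depth = source_depth_cm,
    frac_forward = creation_ratio / (creation_ratio + 1),
    cos_min_f = cos_min_f, cos_min_b = cos_min_b,
    axial_source = source_profile == "axial",
    roulette_threshold = mc$roulette_threshold,
    roulette_survival = mc$roulette_survival
  )
  fb <- if (res$backward_weight > 0) {
    res$forward_weight / res$backward_weight
  } else {
    NA_real_
  }
  structure(
    list(
      forward_weight = res$forward_weight,
      backward_weight = res$backward_weight,
      lost_weight = res$lost_weight,
      absorbed_weight = res$absorbed_weight,
      n_forward = res$n_forward, n_backward = res$n_backward,
      fb_measured = fb,
      creation_ratio = creation_ratio, source_depth_cm = source_depth_cm,
      n_launched = mc$n_photons
    ),
    class = "fb_tally"
  )
}

#' @export
print.fb_tally <- function(x, ...) {
  cat(sprintf(
    "SHG emission tally: R = %g at depth %g cm, %d photons\n",
    x$creation_ratio, x$source_depth_cm, x$n_launched
  ))
  cat(sprintf("  F = %.1f, B = %.1f, lost = %.1f; measured F/B = %.4f\n",
              x$forward_weight, x$backward_weight, x$lost_weight,
              x$fb_measured))
  invisible(x)
}
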