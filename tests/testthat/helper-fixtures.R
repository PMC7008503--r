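# Shared fixtures: tabulated bulk optical properties of normal and
# fibrotic (IPF) lung at the SHG (445 nm) and fundamental (890 nm)
# wavelengths, used as ground-truth inputs for closure experiments.

lung_optics <- list(
  normal_445 = list(wavelength_nm = 445, mus = 327, g = 0.914),
  normal_890 = list(wavelength_nm = 890, mus = 260, g = 0.950),
  ipf_445 = list(wavelength_nm = 445, mus = 405, g = 0.908),
  ipf_890 = list(wavelength_nm = 890, mus = 283, g = 0.946)
)

section_slab <- function() slab_geometry(0.02) # 200-um vibratome section

as_optics <- function(x) optical_properties(x$wavelength_nm, x$mus, x$g)

# independent oracle: HG cosine CDF by numerical integration of the
# density, inverted with a root-finder (no closed-form inverse used)
hg_cdf_oracle <- function(x, g) {
  dens <- function(mu) 0.5 * (1 - g^2) / (1 + g^2 - 2 * g * mu)^1.5
  stats::integrate(dens, -1, x, rel.tol = 1e-12)$value
}

hg_quantile_oracle <- function(p, g) {
  stats::uniroot(function(x) hg_cdf_oracle(x, g) - p, c(-1, 1),
                 tol = 1e-12)$root
}

# independent oracle: tensor ratio b whose pitch angle is theta_deg,
# found by root-finding on the pitch relation rather than algebra
b_from_pitch_oracle <- function(theta_deg) {
  stats::uniroot(
    function(b) atan(sqrt(2) / b) * 180 / pi - theta_deg,
    c(1e-3, 1e3), tol = 1e-12
  )$root
}

# flat synthetic F/B profile for ballistic trivial cases
flat_fb_profile <- function(fb, depths_um = seq(10, 90, by = 10), se = 0.01) {
  tibble::tibble(depth_um = depths_um, fb_measured = fb, fb_se = se,
                 n_pixels = 100L, valid = TRUE)
}
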