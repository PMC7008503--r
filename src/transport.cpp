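#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>

// Layered-slab photon transport with Henyey-Greenstein scattering.
// Geometry: slab occupies z in [0, thickness]; photons enter at z = 0
// travelling along +z (goniometry) or are created at an interior depth
// (SHG emission). Matched refractive-index boundaries: photons exit as
// soon as a free path carries them across a face. Absorption is handled
// by weight attenuation with Russian roulette below a weight threshold.

namespace {

// uniform double in [0, 1) built from the top 53 bits so the value is
// identical across standard-library implementations
inline double runif01(std::mt19937_64& rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

// inverse-CDF sample of the HG scattering cosine
inline double hg_cos(double g, double u) {
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  const double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double mu = (1.0 + g * g - t * t) / (2.0 * g);
  if (mu > 1.0) mu = 1.0;
  if (mu < -1.0) mu = -1.0;
  return mu;
}

struct Dir {
  double ux, uy, uz;
};

// MCML direction update: deflect by polar cosine ct about the current
// direction with uniform azimuth psi
inline void spin(Dir& d, double ct, double psi, double eps = 1e-10) {
  const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  const double cp = std::cos(psi), sp = std::sin(psi);
  if (std::fabs(d.uz) > 1.0 - eps) {
    d.ux = st * cp;
    d.uy = st * sp;
    d.uz = ct * (d.uz >= 0 ? 1.0 : -1.0);
  } else {
    const double denom = std::sqrt(1.0 - d.uz * d.uz);
    const double ux = st * (d.ux * d.uz * cp - d.uy * sp) / denom + d.ux * ct;
    const double uy = st * (d.uy * d.uz * cp + d.ux * sp) / denom + d.uy * ct;
    const double uz = -st * cp * denom + d.uz * ct;
    d.ux = ux;
    d.uy = uy;
    d.uz = uz;
  }
}

inline std::mt19937_64 make_rng(double seed) {
  std::seed_seq ss{static_cast<std::uint32_t>(seed),
                   static_cast<std::uint32_t>(0x9e3779b9UL)};
  return std::mt19937_64(ss);
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mc_goniometry_cpp")]]
Rcpp::List mc_goniometry_cpp(int n_photons, double seed, double mus,
                             double mua, double g, double thickness,
                             int n_bins, double roulette_threshold,
                             double roulette_survival) {
  std::mt19937_64 rng = make_rng(seed);
  const double mut = mus + mua;
  const double albedo = (mut > 0) ? mus / mut : 1.0;
  const double bin_width = 180.0 / n_bins;
  Rcpp::NumericVector weights(n_bins);
  double ballistic = 0.0, absorbed = 0.0, total_exit = 0.0;

  for (int i = 0; i < n_photons; ++i) {
    Dir d{0.0, 0.0, 1.0};
    double z = 0.0, w = 1.0;
    long nscat = 0;
    bool alive = true;
    while (alive) {
      double step;
      if (mut > 0) {
        step = -std::log(1.0 - runif01(rng)) / mut;
      } else {
        step = 2.0 * thickness + 1.0;  // vacuum: exit in one stride
      }
      z += d.uz * step;
      if (z < 0.0 || z > thickness) {
        const double theta = std::acos(std::max(-1.0, std::min(1.0, d.uz))) *
                             (180.0 / M_PI);
        if (nscat == 0) {
          ballistic += w;
        } else {
          int bin = static_cast<int>(theta / bin_width);
          if (bin >= n_bins) bin = n_bins - 1;
          weights[bin] += w;
        }
        total_exit += w;
        alive = false;
      } else {
        if (mua > 0) {
          absorbed += w * (1.0 - albedo);
          w *= albedo;
          if (w < roulette_threshold) {
            if (runif01(rng) < roulette_survival) {
              w /= roulette_survival;
            } else {
              absorbed += w;
              alive = false;
              continue;
            }
          }
        }
        const double ct = hg_cos(g, runif01(rng));
        const double psi = 2.0 * M_PI * runif01(rng);
        spin(d, ct, psi);
        ++nscat;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights,
      Rcpp::Named("ballistic_weight") = ballistic,
      Rcpp::Named("absorbed_weight") = absorbed,
      Rcpp::Named("total_exit_weight") = total_exit);
}

//' @noRd
// [[Rcpp::export(name = ".mc_fb_cpp")]]
Rcpp::List mc_fb_cpp(int n_photons, double seed, double mus, double mua,
                     double g, double thickness, double source_depth,
                     double frac_forward, double cos_min_f, double cos_min_b,
                     bool axial_source, double roulette_threshold,
                     double roulette_survival) {
  std::mt19937_64 rng = make_rng(seed);
  const double mut = mus + mua;
  const double albedo = (mut > 0) ? mus / mut : 1.0;
  double fwd = 0.0, bwd = 0.0, lost = 0.0, absorbed = 0.0;
  long n_fwd = 0, n_bwd = 0;

  // stratified launch: exactly frac_forward of the total weight goes into
  // the forward cone (the fractional remainder is carried by a photon
  // pair), removing binomial split noise from the simulated F/B
  const double np_fwd = n_photons * frac_forward;
  const long nf_full = static_cast<long>(std::floor(np_fwd + 1e-12));
  const double frac = np_fwd - nf_full;
  const bool has_frac = frac > 1e-12 && frac < 1.0 - 1e-12;
  const long total = n_photons + (has_frac ? 1 : 0);

  for (long i = 0; i < total; ++i) {
    bool forward_launch;
    double w0;
    if (i < nf_full) {
      forward_launch = true;
      w0 = 1.0;
    } else if (has_frac && i == nf_full) {
      forward_launch = true;
      w0 = frac;
    } else if (has_frac && i == nf_full + 1) {
      forward_launch = false;
      w0 = 1.0 - frac;
    } else {
      forward_launch = false;
      w0 = 1.0;
    }
    Dir d;
    if (axial_source) {
      d.ux = 0.0;
      d.uy = 0.0;
      d.uz = forward_launch ? 1.0 : -1.0;
    } else {
      // uniform in solid angle inside the detection-matched cone
      const double cmin = forward_launch ? cos_min_f : cos_min_b;
      const double uz = 1.0 - runif01(rng) * (1.0 - cmin);
      const double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      const double psi = 2.0 * M_PI * runif01(rng);
      d.ux = st * std::cos(psi);
      d.uy = st * std::sin(psi);
      d.uz = forward_launch ? uz : -uz;
    }
    double z = source_depth, w = w0;
    bool alive = true;
    while (alive) {
      double step;
      if (mut > 0) {
        step = -std::log(1.0 - runif01(rng)) / mut;
      } else {
        step = 2.0 * thickness + 1.0;
      }
      z += d.uz * step;
      if (z > thickness) {  // bottom face: forward detector side
        if (d.uz >= cos_min_f) {
          fwd += w;
          ++n_fwd;
        } else {
          lost += w;
        }
        alive = false;
      } else if (z < 0.0) {  // top face: backward detector side
        if (-d.uz >= cos_min_b) {
          bwd += w;
          ++n_bwd;
        } else {
          lost += w;
        }
        alive = false;
      } else {
        if (mua > 0) {
          absorbed += w * (1.0 - albedo);
          w *= albedo;
          if (w < roulette_threshold) {
            if (runif01(rng) < roulette_survival) {
              w /= roulette_survival;
            } else {
              absorbed += w;
              alive = false;
              continue;
            }
          }
        }
        const double ct = hg_cos(g, runif01(rng));
        const double psi = 2.0 * M_PI * runif01(rng);
        spin(d, ct, psi);
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("forward_weight") = fwd, Rcpp::Named("backward_weight") = bwd,
      Rcpp::Named("lost_weight") = lost,
      Rcpp::Named("absorbed_weight") = absorbed,
      Rcpp::Named("n_forward") = static_cast<double>(n_fwd),
      Rcpp::Named("n_backward") = static_cast<double>(n_bwd));
}
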