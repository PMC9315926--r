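#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Render sparse Gaussian emitters into an image stack.
// spots: matrix with columns (frame 0-based, x_px, y_px, amplitude), where
// amplitude is the total integrated intensity of the spot (a.u.) and
// sigma_px the PSF sd. Pixel (row r, col c) is centred at x = c, y = r
// (0-based, x = column axis). Returns an H x W x T array.
// [[Rcpp::export]]
NumericVector render_stack(NumericMatrix spots, double sigma_px,
                           int H, int W, int T) {
  NumericVector out(H * (R_xlen_t)W * T);
  out.attr("dim") = IntegerVector::create(H, W, T);
  const int halo = (int)std::ceil(4.0 * sigma_px);
  const double norm = 1.0 / (2.0 * M_PI * sigma_px * sigma_px);
  const double inv2s2 = 1.0 / (2.0 * sigma_px * sigma_px);
  for (int k = 0; k < spots.nrow(); ++k) {
    int f = (int)spots(k, 0);
    if (f < 0 || f >= T) continue;
    double x = spots(k, 1), y = spots(k, 2), amp = spots(k, 3);
    if (amp <= 0) continue;
    int c0 = std::max(0, (int)std::floor(x) - halo);
    int c1 = std::min(W - 1, (int)std::ceil(x) + halo);
    int r0 = std::max(0, (int)std::floor(y) - halo);
    int r1 = std::min(H - 1, (int)std::ceil(y) + halo);
    R_xlen_t fo = (R_xlen_t)f * H * W;
    for (int c = c0; c <= c1; ++c) {
      double dx2 = (c - x) * (c - x);
      R_xlen_t co = fo + (R_xlen_t)c * H;
      for (int r = r0; r <= r1; ++r) {
        double d2 = dx2 + (r - y) * (r - y);
        out[co + r] += amp * norm * std::exp(-d2 * inv2s2);
      }
    }
  }
  return out;
}

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

static inline double mindist(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// Raster-scan a field of Brownian particles with a 2D Gaussian beam
// exp(-2 r^2 / w0^2). Particle positions advance between scan lines
// (per_pixel = false) or between pixels (per_pixel = true); periodic
// boundaries preserve stationarity. xy is n x 2 (micrometres) and is
// modified in place so consecutive frames are continuous in time.
// brightness = expected photon counts per particle per dwell at beam centre.
// Returns expected (noise-free) counts as an H x W x T array; Poisson
// sampling is applied by the R caller. Uses R's RNG (seedable).
// [[Rcpp::export]]
NumericVector raster_scan(NumericMatrix xy, int H, int W, int T,
                          double pixel_um, double dwell_s, double line_s,
                          double D, double w0, double brightness,
                          bool per_pixel) {
  NumericVector out(H * (R_xlen_t)W * T);
  out.attr("dim") = IntegerVector::create(H, W, T);
  const int n = xy.nrow();
  const double Lx = W * pixel_um, Ly = H * pixel_um;
  const double sd_line = std::sqrt(2.0 * D * line_s);
  const double sd_pix = std::sqrt(2.0 * D * dwell_s);
  const double flyback = line_s - W * dwell_s;  // >= 0 by validation
  const double sd_fly = std::sqrt(2.0 * D * (flyback > 0 ? flyback : 0));
  const double cut = 3.0 * w0, cut2 = cut * cut;
  const double inv_w2 = 2.0 / (w0 * w0);
  const int halo_px = (int)std::ceil(cut / pixel_um);
  for (int f = 0; f < T; ++f) {
    R_xlen_t fo = (R_xlen_t)f * H * W;
    for (int r = 0; r < H; ++r) {
      double y_line = r * pixel_um;
      if (per_pixel) {
        for (int c = 0; c < W; ++c) {
          if (sd_pix > 0)
            for (int k = 0; k < n; ++k) {
              xy(k, 0) = wrap(xy(k, 0) + norm_rand() * sd_pix, Lx);
              xy(k, 1) = wrap(xy(k, 1) + norm_rand() * sd_pix, Ly);
            }
          double xc = c * pixel_um, acc = 0.0;
          for (int k = 0; k < n; ++k) {
            double dx = mindist(xy(k, 0) - xc, Lx);
            double dy = mindist(xy(k, 1) - y_line, Ly);
            double d2 = dx * dx + dy * dy;
            if (d2 < cut2) acc += std::exp(-d2 * inv_w2);
          }
          out[fo + (R_xlen_t)c * H + r] = brightness * acc;
        }
        if (sd_fly > 0)
          for (int k = 0; k < n; ++k) {
            xy(k, 0) = wrap(xy(k, 0) + norm_rand() * sd_fly, Lx);
            xy(k, 1) = wrap(xy(k, 1) + norm_rand() * sd_fly, Ly);
          }
      } else {
        if (sd_line > 0)
          for (int k = 0; k < n; ++k) {
            xy(k, 0) = wrap(xy(k, 0) + norm_rand() * sd_line, Lx);
            xy(k, 1) = wrap(xy(k, 1) + norm_rand() * sd_line, Ly);
          }
        for (int k = 0; k < n; ++k) {
          double dy = mindist(xy(k, 1) - y_line, Ly);
          if (std::fabs(dy) >= cut) continue;
          double px = xy(k, 0) / pixel_um;
          int c0 = (int)std::floor(px) - halo_px;
          int c1 = (int)std::ceil(px) + halo_px;
          for (int c = c0; c <= c1; ++c) {
            double dx = mindist(xy(k, 0) - c * pixel_um, Lx);
            double d2 = dx * dx + dy * dy;
            if (d2 >= cut2) continue;
            int cw = ((c % W) + W) % W;
            out[fo + (R_xlen_t)cw * H + r] += brightness * std::exp(-d2 * inv_w2);
          }
        }
      }
    }
  }
  return out;
}
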