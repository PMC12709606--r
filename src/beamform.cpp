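#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Synthesize focused RF channel data for a set of scan lines.
//
// Single-scattering, attenuation-free linear model. Each line fires a
// focused transmit from the full (walking) aperture centered on the line;
// the transmit waveform reaching a scatterer is the superposition of the
// per-element Gaussian-windowed tones with focal delays, so the lateral
// transmit beam profile (and hence the van Cittert-Zernike receive
// coherence of diffuse speckle) emerges from the physics rather than being
// imposed. Receive signals are spherically spread (1/r) copies of that
// waveform delayed by the scatterer-to-element path.
//
// sx, sz, amp : scatterer lateral/axial positions (m) and amplitudes
// off         : element offsets relative to the line origin (m)
// line_x      : lateral beam origins (m)
// zf          : transmit focal depth (m); c0, fs, f0: sound speed, RF
//               sampling rate, center frequency; n_cycles: pulse length in
//               periods; n_time: RF samples per line (t = (row-1)/fs)
// cull_margin : scatterers farther than the geometric transmit beam
//               half-width plus this margin (m) from the line are skipped;
//               use a large value (e.g. 1) to disable culling.
// [[Rcpp::export]]
List cpp_simulate_lines(NumericVector sx, NumericVector sz, NumericVector amp,
                        NumericVector off, NumericVector line_x,
                        double zf, double c0, double fs, double f0,
                        double n_cycles, int n_time, double cull_margin) {
  const int n_scat = sx.size();
  const int n_el = off.size();
  const int n_lines = line_x.size();
  const int os = 4;                       // oversampling of the pulse buffer
  const double fso = os * fs;

  // pulse table: Gaussian-windowed cosine, length n_cycles periods
  const double Tp = n_cycles / f0;
  const double Tc = Tp / 2.0;
  const double sigma = Tp / 6.0;
  const int Lp = (int)std::ceil(Tp * fso) + 1;
  std::vector<double> pulse(Lp);
  for (int k = 0; k < Lp; ++k) {
    double t = k / fso - Tc;
    pulse[k] = std::exp(-t * t / (2.0 * sigma * sigma)) *
               std::cos(2.0 * M_PI * f0 * t);
  }

  double half_ap = 0.0;
  for (int i = 0; i < n_el; ++i) half_ap = std::max(half_ap, std::fabs(off[i]));

  // focal one-way path per element (same for every line: walking aperture)
  std::vector<double> foc_path(n_el);
  for (int i = 0; i < n_el; ++i) foc_path[i] = std::sqrt(off[i] * off[i] + zf * zf);

  List out(n_lines);
  std::vector<double> g;                  // transmit-waveform buffer (per scatterer)
  std::vector<double> t_arr(n_el), w_arr(n_el);

  for (int l = 0; l < n_lines; ++l) {
    NumericMatrix rf(n_time, n_el);
    const double lx = line_x[l];

    for (int s = 0; s < n_scat; ++s) {
      const double a = amp[s];
      if (a == 0.0) continue;
      const double dx = sx[s] - lx;
      const double z = sz[s];
      // geometric transmit beam half-width at this depth, plus margin
      const double halfw = half_ap * std::fabs(1.0 - z / zf) + cull_margin;
      if (std::fabs(dx) > halfw) continue;

      // transmit arrival times (virtual common focal timing)
      double tmin = R_PosInf, tmax = R_NegInf;
      for (int i = 0; i < n_el; ++i) {
        const double ddx = dx - off[i];
        const double d = std::sqrt(ddx * ddx + z * z);
        // subtract the pulse half-length so the envelope center (not the
        // pulse onset) sits at the geometric arrival time
        const double t = (zf - foc_path[i] + d) / c0 - Tc;
        t_arr[i] = t;
        w_arr[i] = 1.0 / d;
        if (t < tmin) tmin = t;
        if (t > tmax) tmax = t;
      }
      const double tbuf0 = tmin - 1.0 / fso;
      const int Lg = (int)std::ceil((tmax - tbuf0) * fso) + Lp + 2;
      g.assign(Lg, 0.0);
      for (int i = 0; i < n_el; ++i) {
        const double u = (t_arr[i] - tbuf0) * fso;
        const int base = (int)std::floor(u);
        const double frac = u - base;
        const double w = w_arr[i];
        // add pulse shifted by frac samples (linear interpolation)
        double prev = 0.0;
        for (int k = 0; k < Lp; ++k) {
          g[base + k] += w * ((1.0 - frac) * pulse[k] + frac * prev);
          prev = pulse[k];
        }
        g[base + Lp] += w * frac * prev;
      }
      // pulse center offset: waveform g(t) represents transmit field whose
      // envelope center for element i sits at t_arr[i] + Tc
      const double t_g_end = tbuf0 + (Lg - 1) / fso;

      for (int j = 0; j < n_el; ++j) {
        const double rdx = dx - off[j];
        const double dr = std::sqrt(rdx * rdx + z * z);
        const double tr = dr / c0;
        const double wr = a / dr;
        // RF rows n (0-based) with t_n = n/fs and t_n - tr within buffer
        int n0 = (int)std::ceil((tbuf0 + tr) * fs);
        int n1 = (int)std::floor((t_g_end + tr) * fs);
        if (n0 < 0) n0 = 0;
        if (n1 > n_time - 1) n1 = n_time - 1;
        double *col = &rf(0, j);
        for (int n = n0; n <= n1; ++n) {
          const double u = (n / fs - tr - tbuf0) * fso;
          const int iu = (int)u;
          if (iu < 0 || iu >= Lg - 1) continue;
          const double fu = u - iu;
          col[n] += wr * ((1.0 - fu) * g[iu] + fu * g[iu + 1]);
        }
      }
    }
    out[l] = rf;
  }
  return out;
}

// Normalized short-lag correlations on delay-aligned channel data.
//
// A       : n_depth x N aligned aperture signals for one scan line
//           (row r corresponds to depth sample r)
// pix_rows: 0-based rows at which to evaluate (pixel centers)
// kernel_half: axial kernel half-length in rows (kernel = 2*kh + 1 rows,
//           clamped at the array edges)
// M       : number of lags
//
// Returns an n_pix x M matrix of correlation coefficients R(m). Element
// pairs in which either member has zero energy over the kernel are skipped
// and the averaging denominator reduced; if every pair of a lag is skipped
// the lag's value is 0.
// [[Rcpp::export]]
NumericMatrix cpp_slsc_aligned(NumericMatrix A, IntegerVector pix_rows,
                               int kernel_half, int M) {
  const int n_depth = A.nrow();
  const int n_el = A.ncol();
  if (M >= n_el) stop("M must be smaller than the element count");
  const int n_pix = pix_rows.size();
  NumericMatrix out(n_pix, M);
  std::vector<double> energy(n_el);

  for (int p = 0; p < n_pix; ++p) {
    const int r = pix_rows[p];
    int r0 = r - kernel_half, r1 = r + kernel_half;
    if (r0 < 0) r0 = 0;
    if (r1 > n_depth - 1) r1 = n_depth - 1;
    for (int i = 0; i < n_el; ++i) {
      double e = 0.0;
      const double *col = &A(0, i);
      for (int n = r0; n <= r1; ++n) e += col[n] * col[n];
      energy[i] = e;
    }
    for (int m = 1; m <= M; ++m) {
      double acc = 0.0;
      int used = 0;
      for (int i = 0; i + m < n_el; ++i) {
        const double ei = energy[i], ej = energy[i + m];
        if (ei <= 0.0 || ej <= 0.0) continue;
        const double *ci = &A(0, i);
        const double *cj = &A(0, i + m);
        double num = 0.0;
        for (int n = r0; n <= r1; ++n) num += ci[n] * cj[n];
        acc += num / std::sqrt(ei * ej);
        ++used;
      }
      out(p, m - 1) = used > 0 ? acc / used : 0.0;
    }
  }
  return out;
}
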