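// Sample-level kernels. Signal rendering, the centred moving average and
// epoch grouping touch every raw sample (17e6/axis at 40 Hz, 86e6 for the
// ECG, per participant), so these inner loops are compiled; all analysis
// logic and thresholds stay in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Render three quantized accelerometer axes in one pass.
// Sample i observes the latent process at t = i/fs * drift_scale; the
// per-minute amplitude lambda (already gain-scaled, split across axes by
// the caller) applies while worn, and the noise SD switches between worn
// and off-body levels. Motion is a band-limited oscillation: a weighted
// sum of sinusoidal components (freqs in Hz, unit-RMS weights, per-axis x
// per-component phases) describing the wearer's body motion, so both
// devices render the same continuous waveform at their own clocks.
// Codes are offset-binary: round half-to-even to match R's round().
// [[Rcpp::export]]
NumericMatrix render_axes_cpp(double n_samples, double fs, double drift_scale,
                              double clock_offset_s,
                              NumericVector amp_per_minute,
                              LogicalVector wear_per_minute,
                              double noise_sd, double offbody_sd,
                              NumericVector gravity, NumericVector freqs,
                              NumericVector weights, NumericMatrix phases,
                              double step, double code_offset,
                              double max_code) {
  R_xlen_t n = (R_xlen_t)n_samples;
  R_xlen_t nmin = amp_per_minute.size();
  int ncomp = freqs.size();
  NumericMatrix out(n, 3);
  double inv_fs = 1.0 / fs;
  std::vector<double> omega(ncomp);
  for (int j = 0; j < ncomp; ++j) omega[j] = 2.0 * M_PI * freqs[j];
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = clock_offset_s + i * inv_fs * drift_scale;
    R_xlen_t m = (R_xlen_t)(t / 60.0);
    if (m < 0) m = 0;
    if (m >= nmin) m = nmin - 1;
    bool w = wear_per_minute[m];
    double amp = w ? amp_per_minute[m] : 0.0;
    double sd = w ? noise_sd : offbody_sd;
    for (int k = 0; k < 3; ++k) {
      double s = 0.0;
      if (amp != 0.0) {
        for (int j = 0; j < ncomp; ++j) {
          s += weights[j] * std::sin(omega[j] * t + phases(k, j));
        }
      }
      double v = gravity[k] + amp * s + sd * norm_rand();
      double code = std::nearbyint(v / step) + code_offset;
      if (code < 0.0) code = 0.0;
      else if (code > max_code) code = max_code;
      out(i, k) = (code - code_offset) * step;
    }
  }
  return out;
}

// Render the ECG: uniform baseline noise everywhere, plus a half-sine
// 1 mV R-wave of spike_width seconds at each beat while worn.
// [[Rcpp::export]]
NumericVector render_ecg_cpp(double n_samples, double fs, double drift_scale,
                             double clock_offset_s,
                             LogicalVector wear_per_minute, double period,
                             double spike_width, double noise_amp) {
  R_xlen_t n = (R_xlen_t)n_samples;
  R_xlen_t nmin = wear_per_minute.size();
  NumericVector out(n);
  double inv_fs = 1.0 / fs;
  for (R_xlen_t i = 0; i < n; ++i) {
    double t = clock_offset_s + i * inv_fs * drift_scale;
    R_xlen_t m = (R_xlen_t)(t / 60.0);
    if (m < 0) m = 0;
    if (m >= nmin) m = nmin - 1;
    double v = noise_amp * (2.0 * unif_rand() - 1.0);
    if (wear_per_minute[m]) {
      double ph = t - std::floor(t / period) * period;
      if (ph < spike_width) v += std::sin(M_PI * ph / spike_width);
    }
    out[i] = v;
  }
  return out;
}

// Centred rectangular moving average over [i-h, i+h], truncated at the
// edges, via a sliding sum.
// [[Rcpp::export]]
NumericVector running_mean_cpp(NumericVector x, int h) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  double s = 0.0;
  R_xlen_t lo = 0, hi = -1;
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t want_hi = i + h; if (want_hi > n - 1) want_hi = n - 1;
    R_xlen_t want_lo = i - h; if (want_lo < 0) want_lo = 0;
    while (hi < want_hi) s += x[++hi];
    while (lo < want_lo) s -= x[lo++];
    out[i] = s / (double)(hi - lo + 1);
  }
  return out;
}

// Pointwise |x - movavg(x)| >= threshold with the same centred truncated
// window, fused into one pass to avoid materialising the smoothed series.
// [[Rcpp::export]]
LogicalVector active_deviation_cpp(NumericVector x, int h, double threshold) {
  R_xlen_t n = x.size();
  LogicalVector out(n);
  double s = 0.0;
  R_xlen_t lo = 0, hi = -1;
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t want_hi = i + h; if (want_hi > n - 1) want_hi = n - 1;
    R_xlen_t want_lo = i - h; if (want_lo < 0) want_lo = 0;
    while (hi < want_hi) s += x[++hi];
    while (lo < want_lo) s -= x[lo++];
    out[i] = std::fabs(x[i] - s / (double)(hi - lo + 1)) >= threshold;
  }
  return out;
}

// Euclidean norm across the three axes, single pass.
// [[Rcpp::export]]
NumericVector vector_magnitude_cpp(NumericVector x, NumericVector y,
                                   NumericVector z) {
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
  }
  return out;
}

// Per-epoch sample counts and MAD for a contiguous series: sample i falls
// in epoch floor((offset_sec + i/fs) / epoch_s). Two passes (epoch means,
// then mean absolute deviations). Returns the first epoch index on the
// midnight-anchored grid, counts, and MAD (NaN for empty epochs).
// [[Rcpp::export]]
List epoch_mad_cpp(NumericVector v, double fs, double offset_sec,
                   double epoch_s) {
  R_xlen_t n = v.size();
  double inv_fs = 1.0 / fs;
  double i0 = std::floor(offset_sec / epoch_s);
  double ilast = std::floor((offset_sec + (n - 1) * inv_fs) / epoch_s);
  R_xlen_t nb = (R_xlen_t)(ilast - i0) + 1;
  IntegerVector counts(nb);
  NumericVector sums(nb), dev(nb), mad(nb);
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t g = (R_xlen_t)(std::floor((offset_sec + i * inv_fs) / epoch_s) - i0);
    counts[g]++;
    sums[g] += v[i];
  }
  NumericVector means(nb);
  for (R_xlen_t g = 0; g < nb; ++g) {
    means[g] = counts[g] > 0 ? sums[g] / counts[g] : 0.0;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t g = (R_xlen_t)(std::floor((offset_sec + i * inv_fs) / epoch_s) - i0);
    dev[g] += std::fabs(v[i] - means[g]);
  }
  for (R_xlen_t g = 0; g < nb; ++g) {
    mad[g] = counts[g] > 0 ? dev[g] / counts[g] : NA_REAL;
  }
  return List::create(_["first_epoch"] = i0, _["counts"] = counts,
                      _["mad"] = mad);
}

// Per-minute totals of samples and of active samples, minute k covering
// [60k, 60(k+1)) seconds relative to the minute grid origin.
// [[Rcpp::export]]
List minute_tabulate_cpp(LogicalVector active, double fs, double offset_sec) {
  R_xlen_t n = active.size();
  double inv_fs = 1.0 / fs;
  R_xlen_t nb = (R_xlen_t)((offset_sec + (n - 1) * inv_fs) / 60.0) + 1;
  IntegerVector tot(nb), act(nb);
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t m = (R_xlen_t)((offset_sec + i * inv_fs) / 60.0);
    tot[m]++;
    if (active[i]) act[m]++;
  }
  return List::create(_["total"] = tot, _["active"] = act);
}
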