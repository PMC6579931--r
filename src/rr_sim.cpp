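#include <Rcpp.h>
using namespace Rcpp;

// Sequential RR-interval recurrence. Interval i opens at beat time t_i and has
// length mean_ibi + resp_amp*sin(2*pi*f_r*t_i) + lf_amp*sin(2*pi*f_lf*t_i + phase)
// + N(0, noise_sd^2); the beat clock then advances by that interval. Amplitudes
// and noise may change at segment boundaries (vagal withdrawal during stress),
// so per-segment values are passed as vectors indexed by the segment that
// contains t_i. Draws come from R's RNG so set.seed() governs the output.
// [[Rcpp::export(".rr_recurrence")]]
List rr_recurrence(double mean_ibi, double resp_freq, double lf_freq,
                   double phase, NumericVector seg_end,
                   NumericVector resp_amp, NumericVector lf_amp,
                   NumericVector noise_sd) {
  const double duration = seg_end[seg_end.size() - 1];
  const double two_pi = 2.0 * M_PI;
  std::vector<double> beats, ibis;
  const R_xlen_t guess = (R_xlen_t)(duration * 1000.0 / mean_ibi) + 16;
  beats.reserve(guess + 1);
  ibis.reserve(guess);
  double t = 0.0;
  int seg = 0;
  beats.push_back(0.0);
  for (;;) {
    while (seg < seg_end.size() - 1 && t >= seg_end[seg]) ++seg;
    double ibi = mean_ibi + resp_amp[seg] * std::sin(two_pi * resp_freq * t) +
                 lf_amp[seg] * std::sin(two_pi * lf_freq * t + phase);
    if (noise_sd[seg] > 0.0) ibi += R::rnorm(0.0, noise_sd[seg]);
    if (ibi < 1.0) ibi = 1.0;  // keep intervals positive
    double tn = t + ibi / 1000.0;
    if (tn > duration + 1e-12) break;
    beats.push_back(tn);
    ibis.push_back(ibi);
    t = tn;
  }
  return List::create(_["beat_times"] = wrap(beats), _["ibi_ms"] = wrap(ibis));
}
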