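#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Greedy template-matching peel loop for one chunk of traces.
//
// R       : traces chunk (samples x channels), modified IN PLACE (residual)
// thr     : per-channel negative detection thresholds (uV)
// wav     : template array (n_units x T x C), R column-major layout
// dims    : c(n_units, T, C)
// peak_idx: 1-based per-unit sample of the negative peak
// max_offset, max_passes: search offsets (samples) and peel passes
// amp_lo, amp_hi: amplitude clamp bounds
//
// Returns a matrix with one row per accepted event:
// [unit (1-based), peak row in chunk (1-based), amplitude, delta_ss]
// [[Rcpp::export]]
NumericMatrix tm_sort_chunk(NumericMatrix R, NumericVector thr,
                            NumericVector wav, IntegerVector dims,
                            IntegerVector peak_idx, int max_offset,
                            int max_passes, double amp_lo, double amp_hi,
                            int thin_radius, int refrac_samples) {
  const int n = R.nrow();
  const int C = R.ncol();
  const int n_units = dims[0];
  const int T = dims[1];
  if (dims[2] != C) stop("channel count mismatch");
  const int n_off = 2 * max_offset + 1;

  // repack templates unit-contiguous, sample-fastest: W[k][s + T*c]
  std::vector< std::vector<double> > W(n_units, std::vector<double>(T * C));
  std::vector<double> norms2(n_units, 0.0);
  for (int k = 0; k < n_units; ++k) {
    for (int c = 0; c < C; ++c) {
      for (int s = 0; s < T; ++s) {
        double v = wav[k + (double)n_units * (s + (double)T * c)];
        W[k][s + T * c] = v;
        norms2[k] += v * v;
      }
    }
  }

  const double *Rp = R.begin();
  double *Rm = R.begin();
  // candidate window must fit: row t needs [t - (T-1) - mo, t + (T-1) + mo]
  const int lo_bound = (T - 1) + max_offset;
  const int hi_bound = n - 1 - (T - 1) - max_offset;

  std::vector<double> ev_unit, ev_row, ev_amp, ev_dss;
  // accepted event rows per unit: a unit cannot be fitted again within
  // refrac_samples of one of its own accepted spikes (per-unit refractory
  // enforcement, which stops collision residuals from being re-explained by
  // the unit that was just subtracted)
  std::vector< std::vector<int> > unit_rows(n_units);
  auto unit_blocked = [&](int k, int row) {
    const std::vector<int> &v = unit_rows[k];
    for (size_t i = 0; i < v.size(); ++i)
      if (std::abs(v[i] - row) <= refrac_samples) return true;
    return false;
  };

  for (int pass = 0; pass < max_passes; ++pass) {
    // detect: interior local minima below threshold on any channel; keep the
    // depth (most negative value over channels) per detected row
    std::vector< std::pair<int, double> > det;
    for (int c = 0; c < C; ++c) {
      const double *col = Rp + (size_t)c * n;
      const double th = thr[c];
      for (int t = 1; t < n - 1; ++t) {
        double v = col[t];
        if (v < th && v <= col[t - 1] && v <= col[t + 1])
          det.push_back(std::make_pair(t, v));
      }
    }
    if (det.empty()) break;
    std::sort(det.begin(), det.end());
    // merge duplicate rows (keep deepest), then thin: noise wiggles inside a
    // spike's negative lobe produce many nearby minima; cluster detections
    // whose gap is <= thin_radius and keep the deepest row per cluster.
    // Spikes colliding closer than the radius surface in later peel passes.
    std::vector<int> cand2;
    {
      std::vector< std::pair<int, double> > uniq;
      for (size_t q = 0; q < det.size(); ++q) {
        if (!uniq.empty() && uniq.back().first == det[q].first) {
          if (det[q].second < uniq.back().second)
            uniq.back().second = det[q].second;
        } else {
          uniq.push_back(det[q]);
        }
      }
      int best_t = uniq[0].first;
      double best_v = uniq[0].second;
      int prev_t = uniq[0].first;
      for (size_t q = 1; q <= uniq.size(); ++q) {
        bool flush = (q == uniq.size()) ||
                     (uniq[q].first - prev_t > thin_radius);
        if (flush) {
          if (best_t >= lo_bound && best_t <= hi_bound) cand2.push_back(best_t);
          if (q < uniq.size()) {
            best_t = uniq[q].first;
            best_v = uniq[q].second;
          }
        } else if (uniq[q].second < best_v) {
          best_t = uniq[q].first;
          best_v = uniq[q].second;
        }
        if (q < uniq.size()) prev_t = uniq[q].first;
      }
    }
    if (cand2.empty()) break;

    const int nc = (int)cand2.size();
    std::vector<int> best_k(nc, -1), best_o(nc, 0);
    std::vector<double> best_amp(nc, 0.0), best_dss(nc, 0.0);

    for (int q = 0; q < nc; ++q) {
      const int t = cand2[q];
      double bdss = 0.0;
      for (int k = 0; k < n_units; ++k) {
        const int p = peak_idx[k] - 1;
        const double n2 = norms2[k];
        if (refrac_samples > 0 && unit_blocked(k, t)) continue;
        for (int o = -max_offset; o <= max_offset; ++o) {
          const int base = t + o - p;
          double dot = 0.0;
          const double *w = W[k].data();
          for (int c = 0; c < C; ++c) {
            const double *col = Rp + (size_t)c * n + base;
            const double *wc = w + (size_t)c * T;
            for (int s = 0; s < T; ++s) dot += wc[s] * col[s];
          }
          double a = dot / n2;
          if (a < amp_lo) a = amp_lo;
          if (a > amp_hi) a = amp_hi;
          double dss = 2.0 * a * dot - a * a * n2;
          if (dss > bdss) {
            bdss = dss;
            best_k[q] = k;
            best_o[q] = o;
            best_amp[q] = a;
            best_dss[q] = dss;
          }
        }
      }
    }

    // greedy accept in decreasing improvement order, blocking +/- T samples
    std::vector<int> ord;
    for (int q = 0; q < nc; ++q)
      if (best_k[q] >= 0 && best_dss[q] > 0) ord.push_back(q);
    if (ord.empty()) break;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return best_dss[a] > best_dss[b]; });
    std::vector<char> blocked(n, 0);
    int accepted = 0;
    for (size_t qi = 0; qi < ord.size(); ++qi) {
      const int q = ord[qi];
      const int t = cand2[q];
      if (blocked[t]) continue;
      const int k = best_k[q];
      const int o = best_o[q];
      const double a = best_amp[q];
      const int base = t + o - (peak_idx[k] - 1);
      const double *w = W[k].data();
      for (int c = 0; c < C; ++c) {
        double *col = Rm + (size_t)c * n + base;
        const double *wc = w + (size_t)c * T;
        for (int s = 0; s < T; ++s) col[s] -= a * wc[s];
      }
      int bl = std::max(0, t - T), bh = std::min(n - 1, t + T);
      for (int b = bl; b <= bh; ++b) blocked[b] = 1;
      unit_rows[k].push_back(t + o);
      ev_unit.push_back(k + 1);
      ev_row.push_back(t + o + 1);
      ev_amp.push_back(a);
      ev_dss.push_back(best_dss[q]);
      ++accepted;
    }
    if (accepted == 0) break;
  }

  NumericMatrix out((int)ev_unit.size(), 4);
  for (int i = 0; i < (int)ev_unit.size(); ++i) {
    out(i, 0) = ev_unit[i];
    out(i, 1) = ev_row[i];
    out(i, 2) = ev_amp[i];
    out(i, 3) = ev_dss[i];
  }
  return out;
}
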