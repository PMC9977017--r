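#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Phase-rectified signal averaging (PRSA).
//
// Anchors are beats where the interval lengthens (deceleration) or shortens
// (acceleration) relative to the previous beat; relative changes larger than
// `anchor_filter` are treated as artefacts and skipped. Only anchors with a
// full +/-L beat neighbourhood contribute. The capacity is the Bauer
// four-point estimate (X(0) + X(1) - X(-1) - X(-2)) / 4 on the phase-aligned
// average X(k).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_prsa(NumericVector rr, int L, double anchor_filter) {
  const int n = rr.size();
  double dc = NA_REAL, ac = NA_REAL;
  int n_dec = 0, n_acc = 0;
  // running sums for the four phase points k = -2, -1, 0, 1
  double sd[4] = {0, 0, 0, 0}, sa[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    if (i - L < 0 || i + L > n - 1) continue;  // full window required
    if (i < 2) continue;                        // need X(-2)
    const double prev = rr[i - 1], cur = rr[i];
    if (prev <= 0) continue;
    const double rel = std::fabs(cur - prev) / prev;
    if (rel > anchor_filter) continue;
    if (cur > prev) {
      sd[0] += rr[i - 2]; sd[1] += rr[i - 1]; sd[2] += rr[i]; sd[3] += rr[i + 1];
      ++n_dec;
    } else if (cur < prev) {
      sa[0] += rr[i - 2]; sa[1] += rr[i - 1]; sa[2] += rr[i]; sa[3] += rr[i + 1];
      ++n_acc;
    }
  }
  if (n_dec > 0)
    dc = (sd[2] + sd[3] - sd[1] - sd[0]) / (4.0 * n_dec);
  if (n_acc > 0)
    ac = (sa[2] + sa[3] - sa[1] - sa[0]) / (4.0 * n_acc);
  return NumericVector::create(_["DC"] = dc, _["AC"] = ac,
                               _["n_dec"] = (double)n_dec,
                               _["n_acc"] = (double)n_acc);
}

// ---------------------------------------------------------------------------
// Sample / approximate entropy, m = 2, tolerance r (absolute units).
// ---------------------------------------------------------------------------

static double sampen_m2(const NumericVector& x, double r) {
  const int n = x.size();
  if (n < 4) return 0.0;
  long A = 0, B = 0;  // template matches of length 3 and 2
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 2; ++j) {
      if (std::fabs(x[i] - x[j]) <= r && std::fabs(x[i + 1] - x[j + 1]) <= r) {
        ++B;
        if (std::fabs(x[i + 2] - x[j + 2]) <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return 0.0;
  return -std::log((double)A / (double)B);
}

static double apen_m2(const NumericVector& x, double r) {
  const int n = x.size();
  if (n < 4) return 0.0;
  auto phi = [&](int m) {
    const int N = n - m + 1;
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      int cnt = 0;
      for (int j = 0; j < N; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k)
          if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
        if (match) ++cnt;
      }
      s += std::log((double)cnt / (double)N);
    }
    return s / N;
  };
  return phi(2) - phi(3);
}

// ---------------------------------------------------------------------------
// Detrended fluctuation analysis slope over integer box sizes [lo, hi].
// ---------------------------------------------------------------------------

static double dfa_slope(const NumericVector& x, int lo, int hi) {
  const int n = x.size();
  if (n < 2 * lo) return 0.0;
  std::vector<double> y(n);
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += x[i];
  mu /= n;
  double c = 0.0;
  for (int i = 0; i < n; ++i) { c += x[i] - mu; y[i] = c; }
  std::vector<double> lx, ly;
  for (int box = lo; box <= hi && box <= n / 2; box += std::max(1, box / 8)) {
    const int nb = n / box;
    double f2 = 0.0;
    for (int b = 0; b < nb; ++b) {
      // linear detrend within the box
      double sx = 0, sy = 0, sxx = 0, sxy = 0;
      for (int k = 0; k < box; ++k) {
        sx += k; sy += y[b * box + k]; sxx += (double)k * k;
        sxy += k * y[b * box + k];
      }
      const double den = box * sxx - sx * sx;
      const double slope = den > 0 ? (box * sxy - sx * sy) / den : 0.0;
      const double icpt = (sy - slope * sx) / box;
      for (int k = 0; k < box; ++k) {
        const double res = y[b * box + k] - (icpt + slope * k);
        f2 += res * res;
      }
    }
    const double f = std::sqrt(f2 / (nb * box));
    if (f > 0) { lx.push_back(std::log((double)box)); ly.push_back(std::log(f)); }
  }
  if (lx.size() < 2) return 0.0;
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  const int m = lx.size();
  for (int i = 0; i < m; ++i) { sx += lx[i]; sy += ly[i]; sxx += lx[i] * lx[i]; sxy += lx[i] * ly[i]; }
  const double den = m * sxx - sx * sx;
  return den > 0 ? (m * sxy - sx * sy) / den : 0.0;
}

// ---------------------------------------------------------------------------
// Lomb-Scargle band powers on irregularly sampled beats.
// Returns integrated power (ms^2) in ULF/VLF/LF/HF bands plus total.
// ---------------------------------------------------------------------------

static void lomb_bands(const NumericVector& t, const NumericVector& v,
                       double* out /* ulf, vlf, lf, hf, tot */) {
  const int n = t.size();
  for (int i = 0; i < 5; ++i) out[i] = 0.0;
  if (n < 4) return;
  const double span = t[n - 1] - t[0];
  if (span <= 0) return;
  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += v[i];
  mu /= n;
  std::vector<double> c(n);
  for (int i = 0; i < n; ++i) c[i] = v[i] - mu;
  const double df = 1.0 / (2.0 * span);  // 2x oversampled grid
  const double fmax = 0.4;
  const int K = (int)std::floor(fmax / df + 1e-12);
  // phase rotation per frequency step, so no trig in the inner loop
  std::vector<double> cd(n), sd(n), cw(n), sw(n);
  for (int i = 0; i < n; ++i) {
    const double a = 2.0 * M_PI * df * t[i];
    cd[i] = std::cos(a); sd[i] = std::sin(a);
    cw[i] = cd[i]; sw[i] = sd[i];  // state at f = df
  }
  for (int k = 1; k <= K; ++k) {
    double yc = 0, ys = 0, cc = 0, cs = 0;
    for (int i = 0; i < n; ++i) {
      const double co = cw[i], si = sw[i];
      yc += c[i] * co; ys += c[i] * si;
      cc += co * co; cs += co * si;
      cw[i] = co * cd[i] - si * sd[i];  // advance to next frequency
      sw[i] = si * cd[i] + co * sd[i];
    }
    // tau rotation in closed form: 2wtau = atan2(S2, C2)
    const double s2 = 2.0 * cs, c2 = 2.0 * cc - n;
    const double R = std::hypot(s2, c2);
    const double cc_tau = 0.5 * (n + R), ss_tau = 0.5 * (n - R);
    const double two_wtau = std::atan2(s2, c2);
    const double ct = std::cos(0.5 * two_wtau), st = std::sin(0.5 * two_wtau);
    const double yct = yc * ct + ys * st;
    const double yst = ys * ct - yc * st;
    double p = 0.0;
    if (cc_tau > 1e-12) p += yct * yct / cc_tau;
    if (ss_tau > 1e-12) p += yst * yst / ss_tau;
    const double pw = p / n;  // band-integral contribution, ms^2
    const double f = k * df;
    int band;
    if (f <= 0.003) band = 0;
    else if (f <= 0.04) band = 1;
    else if (f <= 0.15) band = 2;
    else band = 3;
    out[band] += pw;
    out[4] += pw;
  }
}

static double quantile7(std::vector<double> x, double p) {
  std::sort(x.begin(), x.end());
  const int n = x.size();
  if (n == 1) return x[0];
  const double h = (n - 1) * p;
  const int lo = (int)std::floor(h);
  const int hi = std::min(lo + 1, n - 1);
  return x[lo] + (h - lo) * (x[hi] - x[lo]);
}

// ---------------------------------------------------------------------------
// All 24 HRV metrics for one analysis window of beats.
// Order must match hrv_metric_names() on the R side.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_rr_window_metrics(NumericVector beat_t, NumericVector rr,
                                    int prsa_L, double prsa_filter,
                                    bool do_freq = true,
                                    bool do_entropy = true,
                                    bool do_dfa = true) {
  const int n = rr.size();
  NumericVector out(24);
  std::fill(out.begin(), out.end(), 0.0);
  if (n < 2) return out;

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += rr[i];
  mu /= n;
  double m2 = 0, m3 = 0, m4 = 0;
  for (int i = 0; i < n; ++i) {
    const double d = rr[i] - mu;
    m2 += d * d; m3 += d * d * d; m4 += d * d * d * d;
  }
  const double var_pop = m2 / n;
  const double var_smp = m2 / (n - 1);
  const double sdnn = std::sqrt(var_smp);
  m3 /= n; m4 /= n;

  std::vector<double> sorted(rr.begin(), rr.end());
  const double med = quantile7(sorted, 0.5);
  const double iqr = quantile7(sorted, 0.75) - quantile7(sorted, 0.25);

  // histogram mode: 50 ms bins anchored at 0, lowest winning bin midpoint
  double lo = *std::min_element(rr.begin(), rr.end());
  double hi = *std::max_element(rr.begin(), rr.end());
  int b0 = (int)std::floor(lo / 50.0), b1 = (int)std::floor(hi / 50.0);
  std::vector<int> counts(b1 - b0 + 1, 0);
  for (int i = 0; i < n; ++i) ++counts[(int)std::floor(rr[i] / 50.0) - b0];
  int best = 0;
  for (size_t k = 1; k < counts.size(); ++k) if (counts[k] > counts[best]) best = k;
  const double mode = (b0 + best) * 50.0 + 25.0;

  double ssd = 0;
  int nn50 = 0;
  for (int i = 1; i < n; ++i) {
    const double d = rr[i] - rr[i - 1];
    ssd += d * d;
    if (std::fabs(d) > 50.0) ++nn50;
  }
  const double rmssd = std::sqrt(ssd / (n - 1));
  const double pnn50 = 100.0 * nn50 / (n - 1);
  double mhr = 0;
  for (int i = 0; i < n; ++i) mhr += 60000.0 / rr[i];
  mhr /= n;

  double bands[5] = {0, 0, 0, 0, 0};
  if (do_freq) lomb_bands(beat_t, rr, bands);

  const double r_tol = 0.2 * std::sqrt(var_pop);
  const double sampen =
      (do_entropy && var_pop > 0) ? sampen_m2(rr, r_tol) : 0.0;
  const double apen = (do_entropy && var_pop > 0) ? apen_m2(rr, r_tol) : 0.0;

  NumericVector pr = cpp_prsa(rr, prsa_L, prsa_filter);
  const double prsa_ac = NumericVector::is_na(pr[1]) ? 0.0 : pr[1];
  const double prsa_dc = NumericVector::is_na(pr[0]) ? 0.0 : pr[0];

  const double a1 = do_dfa ? dfa_slope(rr, 4, 16) : 0.0;
  const double a2 = do_dfa ? dfa_slope(rr, 16, 64) : 0.0;

  const double sd1 = std::sqrt(0.5 * ssd / std::max(1, n - 1));
  const double sd2sq = 2.0 * var_smp - 0.5 * ssd / std::max(1, n - 1);
  const double sd2 = sd2sq > 0 ? std::sqrt(sd2sq) : 0.0;
  const double sd1sd2 = sd2 > 0 ? sd1 / sd2 : 0.0;

  out[0] = mu;
  out[1] = med;
  out[2] = mode;
  out[3] = var_smp;
  out[4] = var_pop > 0 ? m3 / std::pow(var_pop, 1.5) : 0.0;
  out[5] = var_pop > 0 ? m4 / (var_pop * var_pop) - 3.0 : 0.0;
  out[6] = iqr;
  out[7] = sdnn;
  out[8] = rmssd;
  out[9] = pnn50;
  out[10] = mhr;
  out[11] = bands[0];
  out[12] = bands[1];
  out[13] = bands[2];
  out[14] = bands[3];
  out[15] = bands[3] > 0 ? bands[2] / bands[3] : 0.0;
  out[16] = bands[4];
  out[17] = sampen;
  out[18] = apen;
  out[19] = prsa_ac;
  out[20] = prsa_dc;
  out[21] = a1;
  out[22] = a2;
  out[23] = sd1sd2;
  return out;
}

// ---------------------------------------------------------------------------
// RR artefact filter: keep intervals in [lo, hi] ms changing no more than
// max_rel from the previous accepted beat.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_rr_artifact_keep(NumericVector rr, double lo, double hi,
                                   double max_rel) {
  const int n = rr.size();
  LogicalVector keep(n);
  double last = NA_REAL;
  for (int i = 0; i < n; ++i) {
    const double x = rr[i];
    bool ok = x >= lo && x <= hi;
    if (ok && !ISNA(last)) ok = std::fabs(x - last) / last <= max_rel;
    keep[i] = ok;
    if (ok) last = x;
  }
  return keep;
}

// ---------------------------------------------------------------------------
// Darbellay-Vajda adaptive partitioning on integer ranks (1..n per axis).
//
// Cells are products of half-open rank intervals [lo, hi). A cell splits into
// 2^d subcells at the midpoints of its rank intervals when it holds at least
// min_cell * 2^d points and the chi-square uniformity statistic across the
// subcells exceeds `crit` (the chi-square critical value, supplied by R).
// ---------------------------------------------------------------------------

struct DVState {
  const IntegerMatrix* ranks;
  int d;
  int min_cell;
  double crit;
  std::vector<std::vector<int>> leaf_lo, leaf_hi;
  std::vector<std::vector<int>> leaf_pts;
};

static void dv_recurse(DVState& st, std::vector<int>& pts,
                       std::vector<int> lo, std::vector<int> hi) {
  const int d = st.d;
  const int nsub = 1 << d;
  const int nc = pts.size();
  bool splittable = nc >= st.min_cell * nsub;
  std::vector<int> mid(d);
  if (splittable) {
    for (int j = 0; j < d; ++j) {
      if (hi[j] - lo[j] < 2) { splittable = false; break; }
      mid[j] = lo[j] + (hi[j] - lo[j]) / 2;
    }
  }
  if (splittable) {
    std::vector<std::vector<int>> sub(nsub);
    for (int idx : pts) {
      int code = 0;
      for (int j = 0; j < d; ++j)
        if ((*st.ranks)(idx, j) >= mid[j]) code |= (1 << j);
      sub[code].push_back(idx);
    }
    const double expect = (double)nc / nsub;
    double T = 0.0;
    for (int s = 0; s < nsub; ++s) {
      const double dev = sub[s].size() - expect;
      T += dev * dev / expect;
    }
    if (T > st.crit) {
      for (int s = 0; s < nsub; ++s) {
        std::vector<int> slo(d), shi(d);
        for (int j = 0; j < d; ++j) {
          if (s & (1 << j)) { slo[j] = mid[j]; shi[j] = hi[j]; }
          else { slo[j] = lo[j]; shi[j] = mid[j]; }
        }
        dv_recurse(st, sub[s], slo, shi);
      }
      return;
    }
  }
  st.leaf_lo.push_back(lo);
  st.leaf_hi.push_back(hi);
  st.leaf_pts.push_back(pts);
}

// [[Rcpp::export]]
List cpp_dv_partition(IntegerMatrix ranks, int min_cell, double crit) {
  const int n = ranks.nrow(), d = ranks.ncol();
  DVState st;
  st.ranks = &ranks; st.d = d; st.min_cell = min_cell; st.crit = crit;
  std::vector<int> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = i;
  std::vector<int> lo(d, 1), hi(d, n + 1);
  dv_recurse(st, pts, lo, hi);
  const int L = st.leaf_lo.size();
  IntegerMatrix mlo(L, d), mhi(L, d);
  IntegerVector cnt(L);
  IntegerVector assign(n);
  for (int l = 0; l < L; ++l) {
    for (int j = 0; j < d; ++j) { mlo(l, j) = st.leaf_lo[l][j]; mhi(l, j) = st.leaf_hi[l][j]; }
    cnt[l] = st.leaf_pts[l].size();
    for (int idx : st.leaf_pts[l]) assign[idx] = l + 1;
  }
  return List::create(_["lo"] = mlo, _["hi"] = mhi, _["count"] = cnt,
                      _["assign"] = assign);
}

// ---------------------------------------------------------------------------
// Transfer entropy from x to y with k = l = t = w = 1.
//
// The triples (y_i, y_{i-1}, x_{i-1}) are rank-normalised per coordinate and
// partitioned with the 3-D D-V scheme; the plug-in conditional mutual
// information is summed over leaves with marginal counts taken over each
// leaf's projected rank ranges. Natural log (nats).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_te_from_ranks(IntegerMatrix ranks, int min_cell, double crit) {
  // rank columns: y_i, y_{i-1}, x_{i-1}
  const int m = ranks.nrow();
  List part = cpp_dv_partition(ranks, min_cell, crit);
  IntegerMatrix lo = part["lo"], hi = part["hi"];
  IntegerVector cnt = part["count"];
  const int L = lo.nrow();
  double te = 0.0;
  for (int l = 0; l < L; ++l) {
    const int nc = cnt[l];
    if (nc == 0) continue;
    // marginal over ylag axis: ranks are a permutation of 1..m
    const int n_b = hi(l, 1) - lo(l, 1);
    int n_ab = 0, n_bc = 0;  // (y, ylag) and (ylag, xlag) joint counts
    for (int i = 0; i < m; ++i) {
      const bool in_b = ranks(i, 1) >= lo(l, 1) && ranks(i, 1) < hi(l, 1);
      if (!in_b) continue;
      if (ranks(i, 0) >= lo(l, 0) && ranks(i, 0) < hi(l, 0)) ++n_ab;
      if (ranks(i, 2) >= lo(l, 2) && ranks(i, 2) < hi(l, 2)) ++n_bc;
    }
    if (n_ab == 0 || n_bc == 0) continue;
    te += ((double)nc / m) *
          std::log((double)nc * n_b / ((double)n_ab * n_bc));
  }
  return te;
}
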