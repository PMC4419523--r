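#include <Rcpp.h>
using namespace Rcpp;

// local maxima of p with flat-run handling: runs of equal values are
// collapsed by carrying the last nonzero slope sign forward
static std::vector<int> local_maxima(const std::vector<double>& p) {
  std::vector<int> out;
  const int n = p.size();
  if (n < 3) return out;
  int prev = 0; // last nonzero slope sign
  for (int i = 1; i < n; ++i) {
    double d = p[i] - p[i - 1];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (prev > 0 && s < 0) out.push_back(i - 1); // 0-based index of the peak
    prev = s;
  }
  return out;
}

// natural cubic spline through shared knots x (strictly increasing), one
// curve per row of Y (nch x m), evaluated at 1..n; adds into acc with sign
static void add_envelope(const NumericMatrix& H, const std::vector<int>& knots,
                         NumericMatrix& acc) {
  const int nch = H.nrow(), n = H.ncol();
  const int m0 = knots.size();
  // mirror up to two extrema at each boundary
  int nm = std::min(2, m0 - 1);
  std::vector<double> x;
  std::vector<int> src;
  for (int i = nm; i >= 1; --i) {
    x.push_back(2.0 * knots[0] - knots[i]);
    src.push_back(knots[i]);
  }
  for (int i = 0; i < m0; ++i) { x.push_back(knots[i]); src.push_back(knots[i]); }
  for (int i = 1; i <= nm; ++i) {
    x.push_back(2.0 * knots[m0 - 1] - knots[m0 - 1 - i]);
    src.push_back(knots[m0 - 1 - i]);
  }
  const int m = x.size();
  std::vector<double> h(m - 1);
  for (int i = 0; i < m - 1; ++i) h[i] = x[i + 1] - x[i];
  // factor the tridiagonal system once (natural boundary)
  const int mi = m - 2; // interior knots
  std::vector<double> cp(std::max(mi, 0));
  std::vector<double> b(std::max(mi, 0));
  for (int i = 0; i < mi; ++i) b[i] = 2.0 * (h[i] + h[i + 1]);
  for (int i = 0; i < mi; ++i) {
    double den = (i == 0) ? b[0] : (b[i] - h[i] * cp[i - 1]);
    cp[i] = h[i + 1] / den;
  }
  // interval index for each output point 0..n-1 (x values are 0-based knots)
  std::vector<int> iv(n);
  {
    int j = 0;
    for (int t = 0; t < n; ++t) {
      while (j < m - 2 && x[j + 1] <= t) ++j;
      iv[t] = j;
    }
  }
  std::vector<double> Yk(m), D(std::max(mi, 0)), M(m);
  for (int ch = 0; ch < nch; ++ch) {
    for (int i = 0; i < m; ++i) Yk[i] = H(ch, src[i]);
    for (int i = 0; i < mi; ++i)
      D[i] = 6.0 * ((Yk[i + 2] - Yk[i + 1]) / h[i + 1] -
                    (Yk[i + 1] - Yk[i]) / h[i]);
    for (int i = 0; i < mi; ++i) {
      double den = (i == 0) ? b[0] : (b[i] - h[i] * cp[i - 1]);
      D[i] = (i == 0) ? D[0] / den : (D[i] - h[i] * D[i - 1]) / den;
    }
    std::fill(M.begin(), M.end(), 0.0);
    if (mi > 0) {
      M[mi] = D[mi - 1];
      for (int i = mi - 2; i >= 0; --i) M[i + 1] = D[i] - cp[i] * M[i + 2];
    }
    for (int t = 0; t < n; ++t) {
      int j = iv[t];
      double hh = h[j], u = x[j + 1] - t, v = t - x[j];
      acc(ch, t) += (M[j] * u * u * u + M[j + 1] * v * v * v) / (6.0 * hh) +
                    (Yk[j] / hh - M[j] * hh / 6.0) * u +
                    (Yk[j + 1] / hh - M[j + 1] * hh / 6.0) * v;
    }
  }
}

// mean directional envelope and amplitude for MEMD sifting.
// H: channels x samples, dirs: n_dir x channels.
// Returns list(mean = channels x samples, amp = samples, used = count).
// [[Rcpp::export]]
List memd_envelope_cpp(NumericMatrix H, NumericMatrix dirs) {
  const int nch = H.nrow(), n = H.ncol(), K = dirs.nrow();
  NumericMatrix env_mean(nch, n);
  NumericVector amp(n);
  int used = 0;
  std::vector<double> p(n);
  NumericMatrix upper(nch, n), lower(nch, n);
  for (int k = 0; k < K; ++k) {
    for (int t = 0; t < n; ++t) {
      double s = 0.0;
      for (int c = 0; c < nch; ++c) s += dirs(k, c) * H(c, t);
      p[t] = s;
    }
    std::vector<int> mx = local_maxima(p);
    for (int t = 0; t < n; ++t) p[t] = -p[t];
    std::vector<int> mn = local_maxima(p);
    if (mx.size() < 2 || mn.size() < 2) continue;
    std::fill(upper.begin(), upper.end(), 0.0);
    std::fill(lower.begin(), lower.end(), 0.0);
    add_envelope(H, mx, upper);
    add_envelope(H, mn, lower);
    for (int t = 0; t < n; ++t) {
      double a2 = 0.0;
      for (int c = 0; c < nch; ++c) {
        env_mean(c, t) += 0.5 * (upper(c, t) + lower(c, t));
        double half = 0.5 * (upper(c, t) - lower(c, t));
        a2 += half * half;
      }
      amp[t] += std::sqrt(a2);
    }
    ++used;
  }
  if (used == 0) return List::create(Named("used") = 0);
  for (int t = 0; t < n; ++t) {
    for (int c = 0; c < nch; ++c) env_mean(c, t) /= used;
    amp[t] /= used;
  }
  return List::create(Named("mean") = env_mean, Named("amp") = amp,
                      Named("used") = used);
}
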