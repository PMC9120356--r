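#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Natural cubic spline through (t, v), evaluated at 0..n-1.
// Knot positions are strictly increasing (guaranteed by extrema indices).
static void spline_eval(const std::vector<double>& t,
                        const std::vector<double>& v,
                        int n, std::vector<double>& out) {
  int k = (int)t.size();
  if (k == 1) {
    std::fill(out.begin(), out.end(), v[0]);
    return;
  }
  if (k == 2) {
    double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = v[0] + slope * (i - t[0]);
    return;
  }
  // second derivatives m[] from the tridiagonal system (natural BCs)
  std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), m(k);
  for (int i = 0; i < k - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < k - 1; ++i)
    alpha[i] = 3.0 * ((v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < k - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  l[k - 1] = 1.0; z[k - 1] = 0.0; m[k - 1] = 0.0;
  for (int i = k - 2; i >= 0; --i) m[i] = z[i] - mu[i] * m[i + 1];

  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = (double)i;
    while (seg < k - 2 && x > t[seg + 1]) ++seg;
    double dt = t[seg + 1] - t[seg];
    double a = v[seg], b = (v[seg + 1] - v[seg]) / dt - dt * (2.0 * m[seg] + m[seg + 1]) / 3.0;
    double c = m[seg], d = (m[seg + 1] - m[seg]) / (3.0 * dt);
    double dx = x - t[seg];
    out[i] = a + b * dx + c * dx * dx + d * dx * dx * dx;
  }
}

// indices of local maxima / minima (plateaus take their midpoint)
static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& mx, std::vector<int>& mn) {
  int n = (int)x.size();
  mx.clear(); mn.clear();
  int i = 1;
  while (i < n - 1) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) { mx.push_back(i); ++i; continue; }
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) { mn.push_back(i); ++i; continue; }
    if (x[i] == x[i + 1] && i + 1 < n - 1) {   // plateau
      int j = i;
      while (j < n - 1 && x[j] == x[j + 1]) ++j;
      if (j < n - 1) {
        if (x[i] > x[i - 1] && x[j] > x[j + 1]) mx.push_back((i + j) / 2);
        else if (x[i] < x[i - 1] && x[j] < x[j + 1]) mn.push_back((i + j) / 2);
      }
      i = j + 1;
      continue;
    }
    ++i;
  }
}

// envelope through extrema with mirrored boundary extension
static bool envelope(const std::vector<double>& x, const std::vector<int>& ext,
                     int n, std::vector<double>& env) {
  if ((int)ext.size() < 2) return false;
  std::vector<double> t, v;
  int ne = (int)ext.size();
  int nmir = std::min(2, ne);
  // mirror about the first sample
  for (int i = nmir - 1; i >= 0; --i) {
    t.push_back(-(double)ext[i]);
    v.push_back(x[ext[i]]);
  }
  for (int i = 0; i < ne; ++i) { t.push_back((double)ext[i]); v.push_back(x[ext[i]]); }
  // mirror about the last sample
  for (int i = 0; i < nmir; ++i) {
    t.push_back(2.0 * (n - 1) - (double)ext[ne - 1 - i]);
    v.push_back(x[ext[ne - 1 - i]]);
  }
  spline_eval(t, v, n, env);
  return true;
}

// [[Rcpp::export(name = ".emd_c")]]
List emd_c(NumericVector x_, int max_imfs = 10, int max_sifts = 10,
           double sd_tol = 0.2) {
  int n = x_.size();
  std::vector<double> r(x_.begin(), x_.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> mx, mn;
  std::vector<double> upper(n), lower(n), h(n), hprev(n);

  for (int k = 0; k < max_imfs; ++k) {
    find_extrema(r, mx, mn);
    if ((int)mx.size() + (int)mn.size() < 4 || mx.size() < 2 || mn.size() < 2)
      break;
    h = r;
    for (int s = 0; s < max_sifts; ++s) {
      find_extrema(h, mx, mn);
      if (mx.size() < 2 || mn.size() < 2) break;
      if (!envelope(h, mx, n, upper) || !envelope(h, mn, n, lower)) break;
      hprev = h;
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double mloc = 0.5 * (upper[i] + lower[i]);
        h[i] = hprev[i] - mloc;
        double dd = hprev[i] - h[i];
        num += dd * dd;
        den += hprev[i] * hprev[i];
      }
      if (den > 0 && num / den < sd_tol) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) r[i] -= h[i];
  }

  int k = (int)imfs.size();
  NumericMatrix M(k, n);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i) M(j, i) = imfs[j][i];
  return List::create(_["imfs"] = M, _["residual"] = NumericVector(r.begin(), r.end()));
}
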