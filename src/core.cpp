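#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dual SMO solver for the two-class soft-margin C-SVC on a precomputed
// kernel (Gram) matrix. Solves
//   min_a 0.5 a'Qa - e'a,  s.t. y'a = 0, 0 <= a_i <= C,  Q_ij = y_i y_j K_ij
// with maximal-violating-pair working-set selection. Returns alpha and the
// bias b so that decision(x) = sum_i a_i y_i K(x_i, x) + b.
// [[Rcpp::export]]
List smo_train(const NumericMatrix& K, const IntegerVector& y, double C,
               double tol = 1e-8, int max_passes = 0) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("K must be square and match length(y)");
  if (max_passes <= 0) max_passes = 5000 * n;
  std::vector<double> a(n, 0.0), f(n, 0.0); // f_i = sum_j a_j y_j K_ij

  int iter = 0;
  double b_up = 0.0, b_low = 0.0;
  for (; iter < max_passes; ++iter) {
    // maximal violating pair over I_up / I_low
    int i = -1, j = -1;
    double vi = -HUGE_VAL, vj = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double score = y[t] - f[t]; // = -y_t * grad_t
      bool in_up  = (y[t] > 0 && a[t] < C) || (y[t] < 0 && a[t] > 0);
      bool in_low = (y[t] > 0 && a[t] > 0) || (y[t] < 0 && a[t] < C);
      if (in_up && score > vi)  { vi = score; i = t; }
      if (in_low && score < vj) { vj = score; j = t; }
    }
    if (i < 0 || j < 0 || vi - vj < tol) { b_up = vi; b_low = vj; break; }
    b_up = vi; b_low = vj;

    double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double s = (double)y[i] * (double)y[j];
    double L, H;
    if (s < 0) { L = std::max(0.0, a[j] - a[i]); H = std::min(C, C + a[j] - a[i]); }
    else       { L = std::max(0.0, a[i] + a[j] - C); H = std::min(C, a[i] + a[j]); }
    double aj_new = a[j] + y[j] * (Ei - Ej) / eta;
    if (aj_new < L) aj_new = L;
    if (aj_new > H) aj_new = H;
    double ai_new = a[i] + s * (a[j] - aj_new);
    // snap to the box so at-bound multipliers leave the working sets exactly
    const double snap = 1e-10 * C;
    if (aj_new < snap) aj_new = 0; else if (aj_new > C - snap) aj_new = C;
    if (ai_new < snap) ai_new = 0; else if (ai_new > C - snap) ai_new = C;
    double di = (ai_new - a[i]) * y[i], dj = (aj_new - a[j]) * y[j];
    if (std::fabs(di) < 1e-16 && std::fabs(dj) < 1e-16) break; // numerically stalled
    a[i] = ai_new; a[j] = aj_new;
    for (int t = 0; t < n; ++t) f[t] += di * K(i, t) + dj * K(j, t);
  }

  double b;
  if (std::isfinite(b_up) && std::isfinite(b_low)) b = 0.5 * (b_up + b_low);
  else if (std::isfinite(b_up)) b = b_up;
  else b = b_low;

  return List::create(_["alpha"] = NumericVector(a.begin(), a.end()),
                      _["b"] = b, _["iterations"] = iter);
}

// Decision values for test samples given their kernel rows against the
// training set: d = K_test_train %*% (alpha * y) + b.
// [[Rcpp::export]]
NumericVector smo_decision(const NumericMatrix& Ktt, const NumericVector& alpha,
                           const IntegerVector& y, double b) {
  const int m = Ktt.nrow(), n = Ktt.ncol();
  if (alpha.size() != n || y.size() != n)
    stop("alpha/y must match ncol(Ktt)");
  NumericVector d(m);
  for (int r = 0; r < m; ++r) {
    double acc = b;
    for (int t = 0; t < n; ++t)
      if (alpha[t] > 0) acc += alpha[t] * y[t] * Ktt(r, t);
    d[r] = acc;
  }
  return d;
}

static inline void neighbours6(int idx, int nx, int ny, int nz, int* out, int* cnt) {
  int z = idx / (nx * ny), rem = idx % (nx * ny), yy = rem / nx, xx = rem % nx;
  int c = 0;
  if (xx > 0)      out[c++] = idx - 1;
  if (xx < nx - 1) out[c++] = idx + 1;
  if (yy > 0)      out[c++] = idx - nx;
  if (yy < ny - 1) out[c++] = idx + nx;
  if (z > 0)       out[c++] = idx - nx * ny;
  if (z < nz - 1)  out[c++] = idx + nx * ny;
  *cnt = c;
}

// 6-connectivity (faces) component labelling of vol > thresh (strict).
// Returns integer labels, 0 for voxels at or below threshold.
// [[Rcpp::export]]
IntegerVector label_components(const NumericVector& vol, const IntegerVector& dim,
                               double thresh) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2], V = nx * ny * nz;
  if (vol.size() != V) stop("vol length does not match dim");
  IntegerVector lab(V, 0);
  std::vector<int> stack; stack.reserve(256);
  int nb[6], nnb, next = 0;
  for (int s = 0; s < V; ++s) {
    if (lab[s] != 0 || !(vol[s] > thresh)) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      neighbours6(cur, nx, ny, nz, nb, &nnb);
      for (int k = 0; k < nnb; ++k) {
        int t = nb[k];
        if (lab[t] == 0 && vol[t] > thresh) { lab[t] = next; stack.push_back(t); }
      }
    }
  }
  return lab;
}

// Threshold-free cluster enhancement of the positive part of a 3D map:
// TFCE(v) = sum over thresholds h = dh, 2dh, ... <= max of e(h,v)^E h^H dh,
// where e(h,v) is the extent of the 6-connected component containing v at
// height h. Voxels <= 0 score 0.
// [[Rcpp::export]]
NumericVector tfce_enhance(const NumericVector& vol, const IntegerVector& dim,
                           double E, double H, double dh, int nsteps) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nx = dim[0], ny = dim[1], nz = dim[2], V = nx * ny * nz;
  if (vol.size() != V) stop("vol length does not match dim");
  NumericVector out(V, 0.0);
  double hmax = 0.0;
  for (int v = 0; v < V; ++v) {
    if (!std::isfinite(vol[v])) stop("non-finite value in map");
    if (vol[v] > hmax) hmax = vol[v];
  }
  if (hmax <= 0.0) return out;
  if (dh <= 0.0) { if (nsteps < 1) nsteps = 100; dh = hmax / nsteps; }

  std::vector<int> lab(V), stack; stack.reserve(256);
  int nb[6], nnb;
  for (double h = dh; h <= hmax + 1e-12; h += dh) {
    std::fill(lab.begin(), lab.end(), 0);
    std::vector<double> contrib; contrib.push_back(0.0);
    int next = 0;
    for (int s = 0; s < V; ++s) {
      if (lab[s] != 0 || vol[s] < h) continue;
      int size = 0;
      lab[s] = ++next; stack.push_back(s);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back(); ++size;
        neighbours6(cur, nx, ny, nz, nb, &nnb);
        for (int k = 0; k < nnb; ++k) {
          int t = nb[k];
          if (lab[t] == 0 && vol[t] >= h) { lab[t] = next; stack.push_back(t); }
        }
      }
      contrib.push_back(std::pow((double)size, E) * std::pow(h, H) * dh);
    }
    for (int v = 0; v < V; ++v)
      if (lab[v] != 0) out[v] += contrib[lab[v]];
  }
  return out;
}
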