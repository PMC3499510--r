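// Bottom-up knot-adjustment engine for piecewise polynomial curve (PPC)
// models of run-length-encoded tracks.
//
// Conventions used throughout:
//  - a signal is given by run boundaries rb[0..n] (absolute, 0-based,
//    half-open) and run values rv[0..n-1]; run i covers [rb[i], rb[i+1]).
//  - a polynomial piece with start s and coefficients c[0..ord] evaluates
//    to sum_j c[j] * (x - s)^j on its interval.
//  - fits are functional least squares: they minimize the exact integral
//    of the squared difference between the polynomial and the staircase,
//    assembled from closed-form interval moments (never per-base sums),
//    keeping every operation O(local runs).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int MAX_ORD = 2;

// ---------------------------------------------------------------------------
// small dense linear solve, Gaussian elimination with partial pivoting.
// Returns false if effectively singular.
static bool solve_dense(std::vector<double>& M, std::vector<double>& rhs, int n) {
  double mx = 0.0;
  for (int i = 0; i < n * n; i++) mx = std::max(mx, std::fabs(M[i]));
  if (mx <= 0.0) return false;
  const double tol = 1e-12 * mx;
  for (int col = 0; col < n; col++) {
    int piv = col;
    for (int r = col + 1; r < n; r++)
      if (std::fabs(M[r * n + col]) > std::fabs(M[piv * n + col])) piv = r;
    if (std::fabs(M[piv * n + col]) < tol) return false;
    if (piv != col) {
      for (int c = 0; c < n; c++) std::swap(M[piv * n + c], M[col * n + c]);
      std::swap(rhs[piv], rhs[col]);
    }
    for (int r = col + 1; r < n; r++) {
      double f = M[r * n + col] / M[col * n + col];
      if (f == 0.0) continue;
      for (int c = col; c < n; c++) M[r * n + c] -= f * M[col * n + c];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = n - 1; r >= 0; r--) {
    double s = rhs[r];
    for (int c = r + 1; c < n; c++) s -= M[r * n + c] * rhs[c];
    rhs[r] = s / M[r * n + r];
  }
  return true;
}

// ---------------------------------------------------------------------------
// run container shared by the exported helpers and the engine
struct Runs {
  const double* rb;   // boundaries, n+1
  const double* rv;   // values, n
  int n;
  double start() const { return rb[0]; }
  double end() const { return rb[n]; }
  // first run whose interval intersects [a, .): largest i with rb[i] <= a
  int locate(double a) const {
    int lo = 0, hi = n;   // invariant rb[lo] <= a < rb[hi] (a < end assumed)
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (rb[mid] <= a) lo = mid; else hi = mid;
    }
    return lo;
  }
};

// Integral least-squares polynomial fit over window [a,b) of the staircase,
// restricted to runs [rlo, rhi), optionally with point constraints
// poly(cx[k]) == cv[k]. Fit is performed in the scaled basis t = (x-a)/(b-a)
// for conditioning, then converted to the (x-a) monomial basis.
// On singularity the order is reduced (never below the number of
// constraints). Returns achieved order, coefficients in c_out[0..ord].
static int fit_window(const Runs& R, double a, double b, int rlo, int rhi,
                      int order, const double* cx, const double* cv, int ncon,
                      double* c_out) {
  const double h = b - a;
  // data moments m_j = int_a^b t^j f dx, j = 0..MAX_ORD
  double m[MAX_ORD + 1] = {0.0, 0.0, 0.0};
  for (int r = rlo; r < rhi; r++) {
    double u = std::max(R.rb[r], a), w = std::min(R.rb[r + 1], b);
    if (w <= u) continue;
    double tu = (u - a) / h, tw = (w - a) / h;
    double pu = tu, pw = tw; // t^{j+1} accumulators
    for (int j = 0; j <= MAX_ORD; j++) {
      m[j] += R.rv[r] * h / (j + 1) * (pw - pu);
      pw *= tw; pu *= tu;
    }
  }
  const int minord = ncon > 1 ? ncon - 1 : 0;
  for (int ord = order; ord >= minord; ord--) {
    int p = ord + 1, dim = p + ncon;
    std::vector<double> M(dim * dim, 0.0), rhs(dim, 0.0);
    for (int j = 0; j < p; j++) {
      for (int k = 0; k < p; k++) M[j * dim + k] = h / (j + k + 1);
      rhs[j] = m[j];
    }
    for (int k = 0; k < ncon; k++) {
      double t = (cx[k] - a) / h, pj = 1.0;
      for (int j = 0; j < p; j++) {
        M[j * dim + (p + k)] = pj;        // B^T
        M[(p + k) * dim + j] = pj;        // B
        pj *= t;
      }
      rhs[p + k] = cv[k];
    }
    if (!solve_dense(M, rhs, dim)) {
      if (ord == minord) break;           // cannot reduce further
      continue;
    }
    double hp = 1.0;
    for (int j = 0; j < p; j++) { c_out[j] = rhs[j] / hp; hp *= h; }
    for (int j = p; j <= MAX_ORD; j++) c_out[j] = 0.0;
    return ord;
  }
  // full fallback: integral mean (respects a single constraint poorly, but
  // this branch is unreachable for h > 0 since the moment matrix is PD)
  double tot = 0.0;
  for (int r = rlo; r < rhi; r++) {
    double u = std::max(R.rb[r], a), w = std::min(R.rb[r + 1], b);
    if (w > u) tot += R.rv[r] * (w - u);
  }
  c_out[0] = tot / h; c_out[1] = c_out[2] = 0.0;
  return 0;
}

// exact integral of the piece (s, c, ord) over [u, w)
static double piece_area(double s, const double* c, int ord, double u, double w) {
  double acc = 0.0, pu = u - s, pw = w - s;
  double ppu = pu, ppw = pw;
  for (int j = 0; j <= ord; j++) {
    acc += c[j] / (j + 1) * (ppw - ppu);
    ppw *= pw; ppu *= pu;
  }
  return acc;
}

// exact int_u^w (poly - v)^2 dx for one run, via run-local shift (stable)
static double piece_run_sq(double s, const double* c, double v,
                           double u, double w) {
  double y0 = u - s, W = w - u;
  double q0 = c[0] + c[1] * y0 + c[2] * y0 * y0 - v;
  double q1 = c[1] + 2.0 * c[2] * y0;
  double q2 = c[2];
  double W2 = W * W, W3 = W2 * W;
  return q0 * q0 * W + q0 * q1 * W2 +
         (q1 * q1 + 2.0 * q0 * q2) * W3 / 3.0 +
         q1 * q2 * W2 * W2 / 2.0 + q2 * q2 * W3 * W2 / 5.0;
}

// integral squared error of one piece against runs [rlo, rhi) on [a, b)
static double piece_err(const Runs& R, double s, const double* c, int ord,
                        int rlo, int rhi, double a, double b) {
  (void)ord;
  double acc = 0.0;
  for (int r = rlo; r < rhi; r++) {
    double u = std::max(R.rb[r], a), w = std::min(R.rb[r + 1], b);
    if (w > u) acc += piece_run_sq(s, c, R.rv[r], u, w);
  }
  return acc;
}

// ---------------------------------------------------------------------------
// acceptance criteria
enum Method { REL = 0, POIS = 1, TTEST = 2 };

static bool pairs_ok(const Runs& R, int method, double alpha,
                     double s, const double* c, int ord,
                     int rlo, int rhi, double a, double b) {
  for (int r = rlo; r < rhi; r++) {
    double u = std::max(R.rb[r], a), w = std::min(R.rb[r + 1], b);
    if (w <= u) continue;
    double A = R.rv[r] * (w - u);
    double P = piece_area(s, c, ord, u, w);
    double d = std::fabs(A - P);
    if (method == REL) {
      if (d > alpha * std::max(std::fabs(A), 1e-12)) return false;
    } else {
      if (d > alpha * std::sqrt(std::max(A, 1.0))) return false;
    }
  }
  return true;
}

// Welch two-sample t-test p-value from run-weighted observations
// (value repeated length times). Returns 2.0 when either side has fewer
// than 2 observations (caller convention: accept).
static double welch_p(const double* len1, const double* val1, int k1,
                      const double* len2, const double* val2, int k2) {
  double n1 = 0, n2 = 0, s1 = 0, s2 = 0;
  for (int i = 0; i < k1; i++) { n1 += len1[i]; s1 += len1[i] * val1[i]; }
  for (int i = 0; i < k2; i++) { n2 += len2[i]; s2 += len2[i] * val2[i]; }
  if (n1 < 2.0 || n2 < 2.0) return 2.0;
  double m1 = s1 / n1, m2 = s2 / n2, ss1 = 0, ss2 = 0;
  for (int i = 0; i < k1; i++) ss1 += len1[i] * (val1[i] - m1) * (val1[i] - m1);
  for (int i = 0; i < k2; i++) ss2 += len2[i] * (val2[i] - m2) * (val2[i] - m2);
  double v1 = ss1 / (n1 - 1.0), v2 = ss2 / (n2 - 1.0);
  double se2 = v1 / n1 + v2 / n2;
  if (se2 <= 0.0) return std::fabs(m1 - m2) <= 1e-12 ? 1.0 : 0.0;
  double t = (m1 - m2) / std::sqrt(se2);
  double df = se2 * se2 /
    ((v1 / n1) * (v1 / n1) / (n1 - 1.0) + (v2 / n2) * (v2 / n2) / (n2 - 1.0));
  return 2.0 * R::pt(-std::fabs(t), df, 1, 0);
}

// Welch p between run ranges [rlo, rmid) and [rmid, rhi) of the signal,
// with the outer windows clipped to [a, b)
static double welch_runs(const Runs& R, int rlo, int rmid, int rhi) {
  std::vector<double> l1, v1, l2, v2;
  l1.reserve(rmid - rlo); v1.reserve(rmid - rlo);
  l2.reserve(rhi - rmid); v2.reserve(rhi - rmid);
  for (int r = rlo; r < rmid; r++) {
    l1.push_back(R.rb[r + 1] - R.rb[r]); v1.push_back(R.rv[r]);
  }
  for (int r = rmid; r < rhi; r++) {
    l2.push_back(R.rb[r + 1] - R.rb[r]); v2.push_back(R.rv[r]);
  }
  return welch_p(l1.data(), v1.data(), (int)l1.size(),
                 l2.data(), v2.data(), (int)l2.size());
}

// ---------------------------------------------------------------------------
// exported math helpers (shared by the R-level poly_core surface)

// [[Rcpp::export]]
NumericVector cpp_fit_poly(NumericVector rb, NumericVector rv,
                           double a, double b, int order,
                           NumericVector cx, NumericVector cv) {
  Runs R{rb.begin(), rv.begin(), (int)rv.size()};
  double c[MAX_ORD + 1];
  int rlo = R.locate(a), rhi = R.locate(b - 1e-9) + 1;
  int ord = fit_window(R, a, b, rlo, rhi, order,
                       cx.begin(), cv.begin(), (int)cx.size(), c);
  NumericVector out(ord + 1);
  for (int j = 0; j <= ord; j++) out[j] = c[j];
  return out;
}

// [[Rcpp::export]]
double cpp_local_error(NumericVector segStart, NumericVector segLen,
                       IntegerVector segOrd, NumericMatrix segCoef,
                       NumericVector rb, NumericVector rv,
                       double a, double b) {
  Runs R{rb.begin(), rv.begin(), (int)rv.size()};
  double acc = 0.0;
  for (int s = 0; s < segStart.size(); s++) {
    double sa = std::max(segStart[s], a);
    double sb = std::min(segStart[s] + segLen[s], b);
    if (sb <= sa) continue;
    double c[MAX_ORD + 1] = {segCoef(s, 0), segCoef(s, 1), segCoef(s, 2)};
    int rlo = R.locate(sa), rhi = R.locate(sb - 1e-9) + 1;
    acc += piece_err(R, segStart[s], c, segOrd[s], rlo, rhi, sa, sb);
  }
  return acc;
}

// [[Rcpp::export]]
List cpp_area_pairs(NumericVector segStart, NumericVector segLen,
                    IntegerVector segOrd, NumericMatrix segCoef,
                    NumericVector rb, NumericVector rv,
                    double a, double b) {
  Runs R{rb.begin(), rv.begin(), (int)rv.size()};
  int rlo = R.locate(a), rhi = R.locate(b - 1e-9) + 1;
  std::vector<int> idx; std::vector<double> A, P;
  for (int r = rlo; r < rhi; r++) {
    double u = std::max(R.rb[r], a), w = std::min(R.rb[r + 1], b);
    if (w <= u) continue;
    double p = 0.0;
    for (int s = 0; s < segStart.size(); s++) {
      double sa = std::max(segStart[s], u);
      double sb = std::min(segStart[s] + segLen[s], w);
      if (sb <= sa) continue;
      double c[MAX_ORD + 1] = {segCoef(s, 0), segCoef(s, 1), segCoef(s, 2)};
      p += piece_area(segStart[s], c, segOrd[s], sa, sb);
    }
    idx.push_back(r + 1);                 // 1-based run index for R
    A.push_back(R.rv[r] * (w - u));
    P.push_back(p);
  }
  return List::create(_["run"] = idx, _["A"] = A, _["P"] = P);
}

// [[Rcpp::export]]
NumericVector cpp_eval_model(NumericVector segStart, NumericVector segLen,
                             IntegerVector segOrd, NumericMatrix segCoef,
                             NumericVector x) {
  int nseg = segStart.size();
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); i++) {
    // binary search for the containing segment
    int lo = 0, hi = nseg - 1, ans = -1;
    while (lo <= hi) {
      int mid = (lo + hi) / 2;
      if (x[i] < segStart[mid]) hi = mid - 1;
      else if (x[i] >= segStart[mid] + segLen[mid]) lo = mid + 1;
      else { ans = mid; break; }
    }
    if (ans < 0) stop("position %f outside the model extent", x[i]);
    double y = x[i] - segStart[ans], v = 0.0, py = 1.0;
    for (int j = 0; j <= segOrd[ans]; j++) { v += segCoef(ans, j) * py; py *= y; }
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_welch_p(NumericVector len1, NumericVector val1,
                   NumericVector len2, NumericVector val2) {
  return welch_p(len1.begin(), val1.begin(), (int)len1.size(),
                 len2.begin(), val2.begin(), (int)len2.size());
}

// ---------------------------------------------------------------------------
// the smoothing engine

// explained part of int f^2 for the optimal order-p fit on a window of
// width h, from t-basis data moments mt[0..2]: c = G^{-1} m, returns m^T c.
// (G is the scaled Hilbert matrix h/(j+k+1).) Falls back to lower order on
// numerical degeneracy.
static double quad_fit_err(double h, const double* mt, int order) {
  for (int ord = order; ord >= 0; ord--) {
    int p = ord + 1;
    std::vector<double> G(p * p), rhs(p);
    for (int j = 0; j < p; j++) {
      for (int k = 0; k < p; k++) G[j * p + k] = h / (j + k + 1);
      rhs[j] = mt[j];
    }
    std::vector<double> rhs0(rhs);
    if (!solve_dense(G, rhs, p)) continue;
    double acc = 0.0;
    for (int j = 0; j < p; j++) acc += rhs0[j] * rhs[j];
    return acc;
  }
  return 0.0;
}

struct Engine {
  Runs R;
  int method, order;
  double alpha;
  // segment-indexed state; the "knot" of segment k is its left boundary,
  // so interior knots are alive segments with prev >= 0
  std::vector<double> st, ln, c0, c1, c2;
  std::vector<int> ord, prv, nxt, rlo, rhi;
  std::vector<char> alive, cont, mod;
  long removed = 0;

  double endpos(int k) const { return st[k] + ln[k]; }

  void coef_get(int k, double* c) const { c[0] = c0[k]; c[1] = c1[k]; c[2] = c2[k]; }
  void coef_set(int k, const double* c, int o) {
    c0[k] = c[0]; c1[k] = o >= 1 ? c[1] : 0.0; c2[k] = o >= 2 ? c[2] : 0.0;
    ord[k] = o;
  }

  double seg_err(int k) const {
    double c[MAX_ORD + 1] = {c0[k], c1[k], c2[k]};
    return piece_err(R, st[k], c, ord[k], rlo[k], rhi[k], st[k], endpos(k));
  }

  bool criterion(double s, const double* c, int o, int a_run, int b_run,
                 double a, double b) const {
    return pairs_ok(R, method, alpha, s, c, o, a_run, b_run, a, b);
  }

  void mark(int k) { if (k >= 0) mod[k] = 1; }

  bool try_remove(int k) {
    int l = prv[k];
    double a = st[l], b = endpos(k);
    double c[MAX_ORD + 1]; int o;
    if (method == TTEST) {
      double p = welch_runs(R, rlo[l], rlo[k], rhi[k]);
      if (!(p > alpha)) return false;
      o = fit_window(R, a, b, rlo[l], rhi[k], 0, nullptr, nullptr, 0, c);
    } else {
      o = fit_window(R, a, b, rlo[l], rhi[k], order, nullptr, nullptr, 0, c);
      if (!criterion(a, c, o, rlo[l], rhi[k], a, b)) return false;
    }
    // accept: merge k into l
    ln[l] = b - a; rhi[l] = rhi[k];
    coef_set(l, c, o);
    cont[l] = 0; // relation to left neighbor now unknown
    alive[k] = 0;
    int r = nxt[k];
    nxt[l] = r; if (r >= 0) { prv[r] = l; cont[r] = 0; }
    mark(l); mark(r);
    removed++;
    return true;
  }

  // joint constrained refit of (prv[k], k) sharing a free common value at
  // the knot; the optimal value comes from the quadratic dependence of the
  // total error on the constraint value.
  bool try_adjust(int k) {
    int l = prv[k];
    double a = st[l], m = st[k], b = endpos(k);
    double cl[MAX_ORD + 1], cr[MAX_ORD + 1];
    double Ev[3], vs[3] = {0.0, 1.0, -1.0};
    for (int i = 0; i < 3; i++) {
      double v = vs[i];
      int ol = fit_window(R, a, m, rlo[l], rhi[l], order, &m, &v, 1, cl);
      int orr = fit_window(R, m, b, rlo[k], rhi[k], order, &m, &v, 1, cr);
      Ev[i] = piece_err(R, a, cl, ol, rlo[l], rhi[l], a, m) +
              piece_err(R, m, cr, orr, rlo[k], rhi[k], m, b);
    }
    double qa = (Ev[1] + Ev[2]) / 2.0 - Ev[0];
    double qb = (Ev[1] - Ev[2]) / 2.0;
    double vstar = qa > 1e-300 ? -qb / (2.0 * qa) : 0.0;
    int ol = fit_window(R, a, m, rlo[l], rhi[l], order, &m, &vstar, 1, cl);
    int orr = fit_window(R, m, b, rlo[k], rhi[k], order, &m, &vstar, 1, cr);
    double Enew = piece_err(R, a, cl, ol, rlo[l], rhi[l], a, m) +
                  piece_err(R, m, cr, orr, rlo[k], rhi[k], m, b);
    double Eold = seg_err(l) + seg_err(k);
    if (Enew > Eold + 1e-12) return false;
    if (!criterion(a, cl, ol, rlo[l], rhi[l], a, m)) return false;
    if (!criterion(m, cr, orr, rlo[k], rhi[k], m, b)) return false;
    // a no-op "success" (already continuous, no error gain) must not keep
    // the knot active forever
    if (cont[k] && Enew > Eold - 1e-12) return false;
    coef_set(l, cl, ol);
    coef_set(k, cr, orr);
    cont[k] = 1;
    mark(k);
    return true;
  }

  bool try_move(int k) {
    int l = prv[k];
    double a = st[l], b = endpos(k);
    double E0 = seg_err(l) + seg_err(k);
    // one left-to-right and one right-to-left sweep of prefix moments makes
    // the whole candidate scan O(runs in span): for each candidate m the
    // optimal fits on [a,m) and [m,b) and their errors come from moments
    // about fixed origins a and b, rebased in closed form.
    int nq = rhi[k] - rlo[l] - 1;          // interior run boundaries
    if (nq < 1) return false;
    std::vector<double> Ml0(nq), Ml1(nq), Ml2(nq), Fl(nq);
    std::vector<double> Mr0(nq), Mr1(nq), Mr2(nq), Fr(nq);
    {
      double m0 = 0, m1 = 0, m2 = 0, f2 = 0;
      for (int r = rlo[l]; r < rhi[k] - 1; r++) {
        double u = R.rb[r] - a, w = R.rb[r + 1] - a, v = R.rv[r];
        double u2 = u * u, w2 = w * w;
        m0 += v * (w - u);
        m1 += v * (w2 - u2) / 2.0;
        m2 += v * (w2 * w - u2 * u) / 3.0;
        f2 += v * v * (w - u);
        int i = r - rlo[l];
        Ml0[i] = m0; Ml1[i] = m1; Ml2[i] = m2; Fl[i] = f2;
      }
      m0 = m1 = m2 = f2 = 0;
      for (int r = rhi[k] - 1; r > rlo[l]; r--) {
        double u = R.rb[r] - b, w = R.rb[r + 1] - b, v = R.rv[r];
        double u2 = u * u, w2 = w * w;
        m0 += v * (w - u);
        m1 += v * (w2 - u2) / 2.0;
        m2 += v * (w2 * w - u2 * u) / 3.0;
        f2 += v * v * (w - u);
        int i = r - rlo[l] - 1;
        Mr0[i] = m0; Mr1[i] = m1; Mr2[i] = m2; Fr[i] = f2;
      }
    }
    int best_r = -1;
    double best_E = E0 - 1e-12;
    for (int i = 0; i < nq; i++) {
      int r = rlo[l] + 1 + i;
      if (r == rlo[k]) continue;          // current position
      double m = R.rb[r];
      double EL, ER;
      {
        double h = m - a;
        double mt[3] = {Ml0[i], Ml1[i] / h, Ml2[i] / (h * h)};
        EL = Fl[i] - quad_fit_err(h, mt, order);
      }
      {
        double h = b - m;
        // rebase moments about b to origin m: (x-m)^j = ((x-b)+h)^j
        double mt[3] = {Mr0[i],
                        (Mr1[i] + h * Mr0[i]) / h,
                        (Mr2[i] + 2.0 * h * Mr1[i] + h * h * Mr0[i]) / (h * h)};
        ER = Fr[i] - quad_fit_err(h, mt, order);
      }
      double E = EL + ER;
      if (E < best_E) { best_E = E; best_r = r; }
    }
    if (best_r < 0) return false;
    // exact refit and checks for the adopted candidate only
    double m = R.rb[best_r];
    double bcl[MAX_ORD + 1], bcr[MAX_ORD + 1];
    int bol = fit_window(R, a, m, rlo[l], best_r, order, nullptr, nullptr, 0, bcl);
    int bor = fit_window(R, m, b, best_r, rhi[k], order, nullptr, nullptr, 0, bcr);
    double Eex = piece_err(R, a, bcl, bol, rlo[l], best_r, a, m) +
                 piece_err(R, m, bcr, bor, best_r, rhi[k], m, b);
    if (!(Eex < E0 - 1e-12)) return false;
    if (method == TTEST) {
      // a relocated knot must be statistically justified at its new
      // position: the Welch comparison of the candidate sides has to reject
      // equality (tiny sides, p sentinel 2, never block the move)
      double p = welch_runs(R, rlo[l], best_r, rhi[k]);
      if (p <= 1.0 && !(p <= alpha)) return false;
    } else {
      if (!criterion(a, bcl, bol, rlo[l], best_r, a, m)) return false;
      if (!criterion(m, bcr, bor, best_r, rhi[k], m, b)) return false;
    }
    ln[l] = m - a; rhi[l] = best_r;
    st[k] = m; ln[k] = b - m; rlo[k] = best_r;
    coef_set(l, bcl, bol);
    coef_set(k, bcr, bor);
    cont[k] = 0;
    int rgt = nxt[k]; if (rgt >= 0) cont[rgt] = 0;
    mark(l); mark(k); mark(rgt);
    return true;
  }
};

// [[Rcpp::export]]
List cpp_smooth(NumericVector rb, NumericVector rv, int method,
                double alpha, int order, int pass_cap) {
  RNGScope scope;                 // uses R's RNG; seed set by the caller
  int n = rv.size();
  Engine E;
  E.R = Runs{rb.begin(), rv.begin(), n};
  E.method = method; E.alpha = alpha; E.order = order;
  E.st.resize(n); E.ln.resize(n);
  E.c0.resize(n); E.c1.assign(n, 0.0); E.c2.assign(n, 0.0);
  E.ord.assign(n, 0); E.prv.resize(n); E.nxt.resize(n);
  E.rlo.resize(n); E.rhi.resize(n);
  E.alive.assign(n, 1); E.cont.assign(n, 0); E.mod.assign(n, 0);
  for (int i = 0; i < n; i++) {
    E.st[i] = rb[i]; E.ln[i] = rb[i + 1] - rb[i]; E.c0[i] = rv[i];
    E.prv[i] = i - 1; E.nxt[i] = i + 1 < n ? i + 1 : -1;
    E.rlo[i] = i; E.rhi[i] = i + 1;
  }

  std::vector<int> active;
  active.reserve(n);
  for (int i = 1; i < n; i++) active.push_back(i);

  int passes = 0;
  bool capped = false;
  while (!active.empty()) {
    if (passes >= pass_cap) { capped = true; break; }
    passes++;
    // Fisher-Yates shuffle from R's RNG: uniform random visiting order
    for (int i = (int)active.size() - 1; i > 0; i--) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(active[i], active[j]);
    }
    for (int idx = 0; idx < (int)active.size(); idx++) {
      int k = active[idx];
      if (!E.alive[k] || E.prv[k] < 0) continue;
      bool changed = E.try_remove(k);
      if (!changed && order >= 1 && method != TTEST) changed = E.try_adjust(k);
      if (!changed) changed = E.try_move(k);
      (void)changed;
    }
    // next pass: knots modified in this pass or adjacent to one
    active.clear();
    for (int k = 0; k < n; k++) {
      if (!E.alive[k] || E.prv[k] < 0) continue;
      if (E.mod[k] || E.mod[E.prv[k]] || (E.nxt[k] >= 0 && E.mod[E.nxt[k]]))
        active.push_back(k);
    }
    std::fill(E.mod.begin(), E.mod.end(), 0);
  }

  int nseg = 0;
  for (int k = 0; k < n; k++) if (E.alive[k]) nseg++;
  NumericVector ost(nseg), oln(nseg);
  IntegerVector oord(nseg);
  NumericMatrix ocf(nseg, MAX_ORD + 1);
  LogicalVector ocont(nseg);
  int k = 0, i = 0;
  while (k >= 0 && k < n) {
    if (E.alive[k]) {
      ost[i] = E.st[k]; oln[i] = E.ln[k]; oord[i] = E.ord[k];
      ocf(i, 0) = E.c0[k]; ocf(i, 1) = E.c1[k]; ocf(i, 2) = E.c2[k];
      ocont[i] = E.cont[k] != 0;
      i++;
      k = E.nxt[k];
    } else k++;
  }
  return List::create(_["start"] = ost, _["length"] = oln, _["order"] = oord,
                      _["coef"] = ocf, _["continuous"] = ocont,
                      _["passes_used"] = passes,
                      _["knots_removed"] = (double)E.removed,
                      _["capped"] = capped);
}
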