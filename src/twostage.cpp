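// Profiled variable-projection least squares for the two-stage
// Michaelis-Menten influx model
//
//   v(S) = V1*S/(Km1+S)                                   S <  T
//   v(S) = V1*T/(Km1+T) + V2*(S-T)/(Km2+S-T)              S >= T
//
// For fixed (T, Km1, Km2) the model is linear in (V1, V2), so the
// conditional SSE is a nonnegative linear least-squares solve; the
// remaining 2-D problem in (log Km1, log Km2) is minimised by
// Nelder-Mead, and T is profiled over a finite candidate set.
// Compiled because the bootstrap calibration needs ~1e5 profiled fits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double LOG_LB = std::log(1e-6);
static const double LOG_UB = std::log(1e4);

struct LinFit {
  double V1, V2, sse;
};

// nonnegative LS for v ~ V1*f1 + V2*f2 via normal equations, with
// clamped refits when an unconstrained coefficient goes negative
static LinFit solve_linear(const std::vector<double>& f1,
                           const std::vector<double>& f2,
                           const NumericVector& v) {
  const int n = v.size();
  double s11 = 0, s12 = 0, s22 = 0, s1y = 0, s2y = 0, syy = 0;
  bool has2 = false;
  for (int i = 0; i < n; ++i) {
    s11 += f1[i] * f1[i];
    s12 += f1[i] * f2[i];
    s22 += f2[i] * f2[i];
    s1y += f1[i] * v[i];
    s2y += f2[i] * v[i];
    syy += v[i] * v[i];
    if (f2[i] > 0) has2 = true;
  }
  LinFit out{0.0, 0.0, syy};
  double det = s11 * s22 - s12 * s12;
  double b1 = NA_REAL, b2 = NA_REAL;
  if (has2 && det > 1e-12 * s11 * s22 && s11 > 0 && s22 > 0) {
    b1 = (s22 * s1y - s12 * s2y) / det;
    b2 = (s11 * s2y - s12 * s1y) / det;
  }
  if (!has2 || !std::isfinite(b1) || !std::isfinite(b2) || b1 < 0 || b2 < 0) {
    // fall back to single-phase solves on each column, keep the better
    double sse1 = R_PosInf, sse2 = R_PosInf, c1 = 0, c2 = 0;
    if (s11 > 0) {
      c1 = std::max(s1y / s11, 0.0);
      sse1 = syy - 2 * c1 * s1y + c1 * c1 * s11;
    }
    if (has2 && s22 > 0) {
      c2 = std::max(s2y / s22, 0.0);
      sse2 = syy - 2 * c2 * s2y + c2 * c2 * s22;
    }
    if (sse1 <= sse2) {
      out.V1 = c1; out.V2 = 0.0; out.sse = sse1;
    } else {
      out.V1 = 0.0; out.V2 = c2; out.sse = sse2;
    }
    if (!std::isfinite(out.sse)) out.sse = syy;
    if (out.sse < 0) out.sse = 0;
    return out;
  }
  out.V1 = b1;
  out.V2 = b2;
  double sse = syy - 2 * (b1 * s1y + b2 * s2y) + b1 * b1 * s11 +
               2 * b1 * b2 * s12 + b2 * b2 * s22;
  out.sse = sse < 0 ? 0 : sse;
  return out;
}

static void design_cols(const NumericVector& S, double T, double Km1,
                        double Km2, std::vector<double>& f1,
                        std::vector<double>& f2) {
  const int n = S.size();
  const double plateau = T / (Km1 + T);
  for (int i = 0; i < n; ++i) {
    if (S[i] < T) {
      f1[i] = S[i] / (Km1 + S[i]);
      f2[i] = 0.0;
    } else {
      f1[i] = plateau;
      f2[i] = (S[i] - T) / (Km2 + S[i] - T);
    }
  }
}

static double clamp_log(double x) {
  if (!std::isfinite(x)) return LOG_UB;
  return std::min(std::max(x, LOG_LB), LOG_UB);
}

static double objective(const NumericVector& S, const NumericVector& v,
                        double T, double lk1, double lk2,
                        std::vector<double>& f1, std::vector<double>& f2) {
  double Km1 = std::exp(clamp_log(lk1));
  // phase convention Km1 <= Km2 enforced by projection onto the boundary
  double Km2 = std::exp(std::max(clamp_log(lk2), clamp_log(lk1)));
  design_cols(S, T, Km1, Km2, f1, f2);
  return solve_linear(f1, f2, v).sse;
}

// 2-D Nelder-Mead on (log Km1, log Km2); standard reflect/expand/contract
static void nelder_mead(const NumericVector& S, const NumericVector& v,
                        double T, double par[2], double* fmin,
                        double reltol, int maxit,
                        std::vector<double>& f1, std::vector<double>& f2) {
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  double px[3][2], fx[3];
  px[0][0] = par[0]; px[0][1] = par[1];
  px[1][0] = par[0] + 0.5; px[1][1] = par[1];
  px[2][0] = par[0]; px[2][1] = par[1] + 0.5;
  for (int i = 0; i < 3; ++i)
    fx[i] = objective(S, v, T, px[i][0], px[i][1], f1, f2);
  for (int it = 0; it < maxit; ++it) {
    // order vertices
    int lo = 0, hi = 0, mid = 0;
    for (int i = 1; i < 3; ++i) {
      if (fx[i] < fx[lo]) lo = i;
      if (fx[i] > fx[hi]) hi = i;
    }
    mid = 3 - lo - hi;
    if (lo == hi) { mid = 1; hi = 2; }
    if (std::fabs(fx[hi] - fx[lo]) <=
        reltol * (std::fabs(fx[lo]) + std::fabs(fx[hi]) + 1e-300))
      break;
    double cx = (px[lo][0] + px[mid][0]) / 2.0;
    double cy = (px[lo][1] + px[mid][1]) / 2.0;
    double rx = cx + alpha * (cx - px[hi][0]);
    double ry = cy + alpha * (cy - px[hi][1]);
    double fr = objective(S, v, T, rx, ry, f1, f2);
    if (fr < fx[lo]) {
      double ex = cx + gamma * (rx - cx), ey = cy + gamma * (ry - cy);
      double fe = objective(S, v, T, ex, ey, f1, f2);
      if (fe < fr) { px[hi][0] = ex; px[hi][1] = ey; fx[hi] = fe; }
      else { px[hi][0] = rx; px[hi][1] = ry; fx[hi] = fr; }
    } else if (fr < fx[mid]) {
      px[hi][0] = rx; px[hi][1] = ry; fx[hi] = fr;
    } else {
      double kx = cx + rho * (px[hi][0] - cx), ky = cy + rho * (px[hi][1] - cy);
      double fk = objective(S, v, T, kx, ky, f1, f2);
      if (fk < fx[hi]) {
        px[hi][0] = kx; px[hi][1] = ky; fx[hi] = fk;
      } else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i][0] = px[lo][0] + sigma * (px[i][0] - px[lo][0]);
          px[i][1] = px[lo][1] + sigma * (px[i][1] - px[lo][1]);
          fx[i] = objective(S, v, T, px[i][0], px[i][1], f1, f2);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (fx[i] < fx[lo]) lo = i;
  par[0] = clamp_log(px[lo][0]);
  par[1] = clamp_log(px[lo][1]);
  *fmin = fx[lo];
}

// Hanes-Woolf (S/v vs S) initial Km for records below T, and an exact
// two-point solve of V2*(S-T)/(Km2+S-T) on the two largest means for Km2
static void initial_logkm(const NumericVector& S, const NumericVector& v,
                          double T, double init[2]) {
  const int n = S.size();
  double sx = 0, sy = 0, sxx = 0, sxy = 0;
  int m = 0;
  std::vector<double> above;
  for (int i = 0; i < n; ++i) {
    if (S[i] < T && v[i] > 0) {
      double y = S[i] / v[i];
      sx += S[i]; sy += y; sxx += S[i] * S[i]; sxy += S[i] * y;
      ++m;
    }
    if (S[i] > T) above.push_back(S[i]);
  }
  std::sort(above.begin(), above.end());
  above.erase(std::unique(above.begin(), above.end()), above.end());
  double smax1 = above.size() >= 1 ? above.back() : -1;
  double smax2 = above.size() >= 2 ? above[above.size() - 2] : -1;
  double km1 = 0.1, plateau_v = 0.0;
  if (m >= 2) {
    double den = m * sxx - sx * sx;
    if (den > 0) {
      double slope = (m * sxy - sx * sy) / den;
      double icpt = (sy - slope * sx) / m;
      if (slope > 0 && icpt > 0) {
        km1 = icpt / slope;
        plateau_v = (1.0 / slope) * T / (km1 + T);
      }
    }
  }
  double km2 = 1.0;
  bool have_km2 = false;
  if (smax2 > 0) {
    double va = 0, vb = 0; int na = 0, nb = 0;
    for (int i = 0; i < n; ++i) {
      if (S[i] == smax2) { va += v[i]; ++na; }
      if (S[i] == smax1) { vb += v[i]; ++nb; }
    }
    if (na > 0 && nb > 0) {
      double ya = va / na - plateau_v, yb = vb / nb - plateau_v;
      double xa = smax2 - T, xb = smax1 - T;
      if (ya > 0 && yb > 0 && xa > 0 && xb > 0) {
        double K = xa * xb * (yb - ya) / (ya * xb - yb * xa);
        if (std::isfinite(K) && K > 0) { km2 = K; have_km2 = true; }
      }
    }
  }
  if (!have_km2) {
    double smax = 0;
    for (int i = 0; i < n; ++i) smax = std::max(smax, (double)S[i]);
    km2 = std::max(smax, 1e-3);
  }
  init[0] = clamp_log(std::log(km1));
  init[1] = clamp_log(std::log(km2));
}

// [[Rcpp::export(name = ".profile_fit_cpp")]]
List profile_fit_cpp(NumericVector S, NumericVector v,
                     NumericVector t_candidates,
                     Nullable<NumericVector> warm_start = R_NilValue,
                     double reltol = 1e-13, int maxit = 500,
                     int restarts = 1) {
  const int nc = t_candidates.size();
  std::vector<double> f1(S.size()), f2(S.size());
  NumericVector prof_sse(nc);
  double best_sse = R_PosInf, best_par[2] = {0, 0}, best_T = NA_REAL;
  bool warm = warm_start.isNotNull();
  double w[2] = {0, 0};
  if (warm) {
    NumericVector ws(warm_start);
    w[0] = clamp_log(ws[0]); w[1] = clamp_log(ws[1]);
  }
  for (int c = 0; c < nc; ++c) {
    double T = t_candidates[c];
    double par[2], fmin;
    if (warm) { par[0] = w[0]; par[1] = w[1]; }
    else initial_logkm(S, v, T, par);
    nelder_mead(S, v, T, par, &fmin, reltol, maxit, f1, f2);
    for (int r = 0; r < restarts; ++r)
      nelder_mead(S, v, T, par, &fmin, reltol, maxit, f1, f2);
    prof_sse[c] = fmin;
    // strict improvement keeps the smallest T on ties
    if (fmin < best_sse * (1 - 1e-12) ||
        (std::isinf(best_sse) && std::isfinite(fmin))) {
      best_sse = fmin;
      best_par[0] = par[0];
      best_par[1] = par[1];
      best_T = T;
    }
  }
  double Km1 = std::exp(best_par[0]);
  double Km2 = std::exp(std::max(best_par[1], best_par[0]));
  design_cols(S, best_T, Km1, Km2, f1, f2);
  LinFit lin = solve_linear(f1, f2, v);
  return List::create(_["V1"] = lin.V1, _["Km1"] = Km1, _["V2"] = lin.V2,
                      _["Km2"] = Km2, _["T"] = best_T, _["sse"] = lin.sse,
                      _["profile_sse"] = prof_sse);
}

// [[Rcpp::export(name = ".sse_two_stage_cpp")]]
double sse_two_stage_cpp(NumericVector S, NumericVector v, double V1,
                         double Km1, double V2, double Km2, double T) {
  double sse = 0;
  const double plateau = V1 * T / (Km1 + T);
  for (int i = 0; i < S.size(); ++i) {
    double mu = S[i] < T ? V1 * S[i] / (Km1 + S[i])
                         : plateau + V2 * (S[i] - T) / (Km2 + S[i] - T);
    double r = v[i] - mu;
    sse += r * r;
  }
  return sse;
}
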