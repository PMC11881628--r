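#include <Rcpp.h>
using namespace Rcpp;

// Profiled REML machinery for the random-intercept-and-slope model
//   y_ij = x_ij' beta + b0_i + b1_i * t_ij + e_ij,
//   (b0_i, b1_i) ~ N(0, G),  e_ij ~ N(0, sigma2).
// G is parameterized relative to sigma2 through a non-negative Cholesky
// factor L (theta = (l11, l21, l22), G = sigma2 * L L'), as in lme4, so the
// G = 0 boundary is reachable.  Everything is expressed through per-subject
// cross-products, so one likelihood evaluation is O(n_subjects) with 2x2
// closed-form algebra regardless of the number of visits.

// Cholesky factorization of a p x p SPD matrix stored column-major in a.
// Overwrites a with the lower factor. Returns log-determinant of the matrix,
// or NA if not positive definite.
static double chol_in_place(std::vector<double>& a, int p) {
  double logdet = 0.0;
  for (int j = 0; j < p; ++j) {
    double d = a[j + p * j];
    for (int k = 0; k < j; ++k) d -= a[j + p * k] * a[j + p * k];
    if (d <= 0.0) return NA_REAL;
    d = std::sqrt(d);
    a[j + p * j] = d;
    logdet += 2.0 * std::log(d);
    for (int i = j + 1; i < p; ++i) {
      double s = a[i + p * j];
      for (int k = 0; k < j; ++k) s -= a[i + p * k] * a[j + p * k];
      a[i + p * j] = s / d;
    }
  }
  return logdet;
}

// Solve L L' x = b given the lower Cholesky factor in a.
static void chol_solve(const std::vector<double>& a, int p,
                       std::vector<double>& b) {
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= a[i + p * k] * b[k];
    b[i] = s / a[i + p * i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < p; ++k) s -= a[k + p * i] * b[k];
    b[i] = s / a[i + p * i];
  }
}

// Per-subject sufficient statistics. subj is 1-based and need not be sorted.
// [[Rcpp::export]]
List cdr_suffstats(NumericMatrix X, NumericVector y, NumericVector t,
                   IntegerVector subj, int nsub) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix K(nsub, 3);      // n_i, sum t, sum t^2
  NumericMatrix Sx(nsub, p);     // sum x
  NumericMatrix Stx(nsub, p);    // sum t x
  NumericVector Sy(nsub), Sty(nsub);
  for (int i = 0; i < n; ++i) {
    const int s = subj[i] - 1;
    const double ti = t[i], yi = y[i];
    K(s, 0) += 1.0;
    K(s, 1) += ti;
    K(s, 2) += ti * ti;
    Sy[s] += yi;
    Sty[s] += ti * yi;
    for (int j = 0; j < p; ++j) {
      const double xij = X(i, j);
      Sx(s, j) += xij;
      Stx(s, j) += ti * xij;
    }
  }
  return List::create(_["K"] = K, _["Sx"] = Sx, _["Stx"] = Stx,
                      _["Sy"] = Sy, _["Sty"] = Sty,
                      _["n"] = n, _["p"] = p, _["nsub"] = nsub);
}

struct TMat { double t11, t12, t22, logdet; };

// A = I + L' K_i L; T = L A^{-1} L'  (all 2x2, K_i = Z_i'Z_i).
static inline TMat t_matrix(double l11, double l21, double l22,
                            double k11, double k12, double k22) {
  // M = L' K L with L = [[l11, 0], [l21, l22]]
  const double kl11 = k11 * l11 + k12 * l21, kl12 = k12 * l22;
  const double kl21 = k12 * l11 + k22 * l21, kl22 = k22 * l22;
  const double a11 = 1.0 + l11 * kl11 + l21 * kl21;
  const double a12 = l11 * kl12 + l21 * kl22;
  const double a22 = 1.0 + l22 * kl22;
  const double det = a11 * a22 - a12 * a12;  // >= 1: A = I + PSD
  const double i11 = a22 / det, i12 = -a12 / det, i22 = a11 / det;
  // T = L Ainv L'
  const double b11 = l11 * i11, b12 = l11 * i12;
  const double b21 = l21 * i11 + l22 * i12, b22 = l21 * i12 + l22 * i22;
  TMat T;
  T.t11 = b11 * l11;
  T.t12 = b11 * l21 + b12 * l22;
  T.t22 = b21 * l21 + b22 * l22;
  T.logdet = std::log(det);
  return T;
}

// Profiled -2 * REML log-likelihood at theta, with GLS beta and sigma2.
// XtX (p x p) and Xty are totals over all rows; yty = y'y.
// [[Rcpp::export]]
List cdr_reml_eval(NumericVector theta, List ss, NumericMatrix XtX,
                   NumericVector Xty, double yty) {
  const double l11 = theta[0], l21 = theta[1], l22 = theta[2];
  NumericMatrix K = ss["K"], Sx = ss["Sx"], Stx = ss["Stx"];
  NumericVector Sy = ss["Sy"], Sty = ss["Sty"];
  const int p = as<int>(ss["p"]), nsub = as<int>(ss["nsub"]);
  const int N = as<int>(ss["n"]);

  std::vector<double> Mxx(p * p), Mxy(p), w(p), v(p);
  for (int j = 0; j < p; ++j) {
    Mxy[j] = Xty[j];
    for (int i = 0; i < p; ++i) Mxx[i + p * j] = XtX(i, j);
  }
  double myy = yty, sumlog = 0.0;

  for (int s = 0; s < nsub; ++s) {
    const TMat T = t_matrix(l11, l21, l22, K(s, 0), K(s, 1), K(s, 2));
    sumlog += T.logdet;
    const double uy1 = Sy[s], uy2 = Sty[s];
    const double ty1 = T.t11 * uy1 + T.t12 * uy2;
    const double ty2 = T.t12 * uy1 + T.t22 * uy2;
    myy -= uy1 * ty1 + uy2 * ty2;
    for (int j = 0; j < p; ++j) {
      const double x1 = Sx(s, j), x2 = Stx(s, j);
      w[j] = T.t11 * x1 + T.t12 * x2;  // (T u_x)_1 for column j
      v[j] = T.t12 * x1 + T.t22 * x2;
      Mxy[j] -= x1 * ty1 + x2 * ty2;
    }
    for (int j = 0; j < p; ++j) {
      const double x1 = Sx(s, j), x2 = Stx(s, j);
      for (int i = 0; i <= j; ++i) {
        const double c = x1 * w[i] + x2 * v[i];
        Mxx[i + p * j] -= c;
        if (i != j) Mxx[j + p * i] -= c;
      }
    }
  }

  std::vector<double> chol = Mxx;
  const double logdetXWX = chol_in_place(chol, p);
  if (!R_finite(logdetXWX))
    return List::create(_["objective"] = 1e10, _["ok"] = false);
  std::vector<double> beta = Mxy;
  chol_solve(chol, p, beta);
  double rss = myy;
  for (int j = 0; j < p; ++j) rss -= beta[j] * Mxy[j];
  if (rss < 0.0) rss = 0.0;  // exact-fit boundary
  const double df = (double)(N - p);
  const double s2 = rss / df;
  const double logs2 = std::log(std::max(s2, 1e-300));
  const double obj =
      df * (1.0 + logs2 + std::log(2.0 * M_PI)) + sumlog + logdetXWX;

  // Asymptotic covariance of beta: s2 * (X'WX)^{-1}
  NumericMatrix vcov(p, p);
  for (int j = 0; j < p; ++j) {
    std::vector<double> e(p, 0.0);
    e[j] = 1.0;
    chol_solve(chol, p, e);
    for (int i = 0; i < p; ++i) vcov(i, j) = s2 * e[i];
  }
  return List::create(_["objective"] = obj, _["ok"] = true,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["sigma2"] = s2, _["vcov_beta"] = vcov,
                      _["sumlogA"] = sumlog, _["logdetXWX"] = logdetXWX);
}

// EBLUPs for all subjects: b_i = Lambda (u_i - K_i T u_i), Lambda = L L',
// u_i = Z_i'(y_i - X_i beta). Equals G Z_i' V_i^{-1} (y_i - X_i beta).
// [[Rcpp::export]]
NumericMatrix cdr_eblup_all(NumericVector theta, NumericVector beta, List ss) {
  const double l11 = theta[0], l21 = theta[1], l22 = theta[2];
  const double lam11 = l11 * l11, lam12 = l11 * l21,
               lam22 = l21 * l21 + l22 * l22;
  NumericMatrix K = ss["K"], Sx = ss["Sx"], Stx = ss["Stx"];
  NumericVector Sy = ss["Sy"], Sty = ss["Sty"];
  const int p = as<int>(ss["p"]), nsub = as<int>(ss["nsub"]);
  NumericMatrix out(nsub, 2);
  for (int s = 0; s < nsub; ++s) {
    double u1 = Sy[s], u2 = Sty[s];
    for (int j = 0; j < p; ++j) {
      u1 -= Sx(s, j) * beta[j];
      u2 -= Stx(s, j) * beta[j];
    }
    const double k11 = K(s, 0), k12 = K(s, 1), k22 = K(s, 2);
    const TMat T = t_matrix(l11, l21, l22, k11, k12, k22);
    const double tu1 = T.t11 * u1 + T.t12 * u2;
    const double tu2 = T.t12 * u1 + T.t22 * u2;
    const double w1 = u1 - (k11 * tu1 + k12 * tu2);
    const double w2 = u2 - (k12 * tu1 + k22 * tu2);
    out(s, 0) = lam11 * w1 + lam12 * w2;
    out(s, 1) = lam12 * w1 + lam22 * w2;
  }
  return out;
}

// ---- aggregated (grouped) REML path ---------------------------------------
// Subjects with identical Z_i'Z_i share the same 2x2 whitening matrix T, so
// the profiled REML objective only needs group-level aggregates of the
// per-subject cross-products.  The aggregates are independent of theta and,
// under subject-level bootstrap resampling, depend on the resample only
// through multiplicity weights — one O(n) reweighting pass per resample,
// after which each objective evaluation is O(#groups).

static inline int pp_of(int p) { return p * (p + 1) / 2; }

// [[Rcpp::export]]
List cdr_lmm_precompute(NumericMatrix X, NumericVector y, NumericVector t,
                        IntegerVector subj, int nsub) {
  const int n = X.nrow(), p = X.ncol(), pp = pp_of(p);
  NumericMatrix K(nsub, 3), Sx(nsub, p), Stx(nsub, p);
  NumericVector Sy(nsub), Sty(nsub), ytys(nsub);
  NumericMatrix XtXs(nsub, pp), Xtys(nsub, p);
  for (int i = 0; i < n; ++i) {
    const int s = subj[i] - 1;
    const double ti = t[i], yi = y[i];
    K(s, 0) += 1.0; K(s, 1) += ti; K(s, 2) += ti * ti;
    Sy[s] += yi; Sty[s] += ti * yi; ytys[s] += yi * yi;
    int m = 0;
    for (int j = 0; j < p; ++j) {
      const double xij = X(i, j);
      Sx(s, j) += xij;
      Stx(s, j) += ti * xij;
      Xtys(s, j) += xij * yi;
      for (int k = 0; k <= j; ++k, ++m) XtXs(s, m) += xij * X(i, k);
    }
  }
  // group subjects by identical K rows
  std::map<std::tuple<double, double, double>, int> seen;
  IntegerVector group(nsub);
  std::vector<double> kg;
  int G = 0;
  for (int s = 0; s < nsub; ++s) {
    auto key = std::make_tuple(K(s, 0), K(s, 1), K(s, 2));
    auto it = seen.find(key);
    if (it == seen.end()) {
      seen[key] = G;
      kg.push_back(K(s, 0)); kg.push_back(K(s, 1)); kg.push_back(K(s, 2));
      group[s] = G++;
    } else {
      group[s] = it->second;
    }
  }
  NumericMatrix Kg(G, 3);
  for (int g = 0; g < G; ++g)
    for (int j = 0; j < 3; ++j) Kg(g, j) = kg[3 * g + j];
  return List::create(_["K"] = K, _["Sx"] = Sx, _["Stx"] = Stx,
                      _["Sy"] = Sy, _["Sty"] = Sty,
                      _["XtXs"] = XtXs, _["Xtys"] = Xtys, _["ytys"] = ytys,
                      _["group"] = group, _["Kg"] = Kg, _["G"] = G,
                      _["n"] = n, _["p"] = p, _["nsub"] = nsub);
}

// [[Rcpp::export]]
List cdr_lmm_aggregate(List pre, NumericVector w) {
  NumericMatrix K = pre["K"], Sx = pre["Sx"], Stx = pre["Stx"];
  NumericVector Sy = pre["Sy"], Sty = pre["Sty"], ytys = pre["ytys"];
  NumericMatrix XtXs = pre["XtXs"], Xtys = pre["Xtys"];
  IntegerVector group = pre["group"];
  NumericMatrix Kg = pre["Kg"];
  const int G = as<int>(pre["G"]), p = as<int>(pre["p"]),
            nsub = as<int>(pre["nsub"]);
  const int pp = pp_of(p);
  NumericMatrix AG11(G, pp), AG12(G, pp), AG22(G, pp);
  NumericMatrix AQ11(G, p), AQ12(G, p), AQ22(G, p);
  NumericMatrix AR(G, 3);
  NumericVector wg(G), XtXw(pp), Xtyw(p);
  double ytyw = 0.0, Nw = 0.0;
  // raw column pointers (all accumulators are column-major, G rows)
  double *ag11 = AG11.begin(), *ag12 = AG12.begin(), *ag22 = AG22.begin();
  double *aq11 = AQ11.begin(), *aq12 = AQ12.begin(), *aq22 = AQ22.begin();
  double *ar = AR.begin(), *xtxw = XtXw.begin(), *xtyw = Xtyw.begin();
  const double *sx = Sx.begin(), *stx = Stx.begin();
  const double *xtxs = XtXs.begin(), *xtys = Xtys.begin();
  const double *kk = K.begin();
  for (int s = 0; s < nsub; ++s) {
    const double ws = w[s];
    if (ws == 0.0) continue;
    const int g = group[s];
    wg[g] += ws;
    Nw += ws * kk[s];
    ytyw += ws * ytys[s];
    const double sy = Sy[s], sty = Sty[s];
    ar[g] += ws * sy * sy;
    ar[g + G] += ws * 2.0 * sy * sty;
    ar[g + 2 * G] += ws * sty * sty;
    int m = 0;
    for (int j = 0; j < p; ++j) {
      const double xj = sx[s + j * nsub], txj = stx[s + j * nsub];
      aq11[g + j * G] += ws * sy * xj;
      aq12[g + j * G] += ws * (sty * xj + sy * txj);
      aq22[g + j * G] += ws * sty * txj;
      xtyw[j] += ws * xtys[s + j * nsub];
      for (int k = 0; k <= j; ++k, ++m) {
        const double xk = sx[s + k * nsub], txk = stx[s + k * nsub];
        ag11[g + m * G] += ws * xj * xk;
        ag12[g + m * G] += ws * (xj * txk + txj * xk);
        ag22[g + m * G] += ws * txj * txk;
        xtxw[m] += ws * xtxs[s + m * nsub];
      }
    }
  }
  return List::create(_["AG11"] = AG11, _["AG12"] = AG12, _["AG22"] = AG22,
                      _["AQ11"] = AQ11, _["AQ12"] = AQ12, _["AQ22"] = AQ22,
                      _["AR"] = AR, _["wg"] = wg, _["Kg"] = Kg,
                      _["XtXw"] = XtXw, _["Xtyw"] = Xtyw, _["ytyw"] = ytyw,
                      _["Nw"] = Nw, _["G"] = G, _["p"] = p);
}

// Profiled -2 REML log-likelihood from group aggregates; with details = true
// also returns beta, sigma2 and the covariance of beta.
// [[Rcpp::export]]
List cdr_reml_eval_agg(NumericVector theta, List agg, bool details) {
  const double l11 = theta[0], l21 = theta[1], l22 = theta[2];
  NumericMatrix AG11 = agg["AG11"], AG12 = agg["AG12"], AG22 = agg["AG22"];
  NumericMatrix AQ11 = agg["AQ11"], AQ12 = agg["AQ12"], AQ22 = agg["AQ22"];
  NumericMatrix AR = agg["AR"], Kg = agg["Kg"];
  NumericVector wg = agg["wg"], XtXw = agg["XtXw"], Xtyw = agg["Xtyw"];
  const double ytyw = as<double>(agg["ytyw"]), Nw = as<double>(agg["Nw"]);
  const int G = as<int>(agg["G"]), p = as<int>(agg["p"]);
  const int pp = pp_of(p);

  std::vector<double> Mp(XtXw.begin(), XtXw.end());  // packed X'WX
  std::vector<double> Mxy(Xtyw.begin(), Xtyw.end());
  double myy = ytyw, sumlog = 0.0;
  for (int g = 0; g < G; ++g) {
    if (wg[g] == 0.0) continue;
    const TMat T = t_matrix(l11, l21, l22, Kg(g, 0), Kg(g, 1), Kg(g, 2));
    sumlog += wg[g] * T.logdet;
    for (int m = 0; m < pp; ++m)
      Mp[m] -= T.t11 * AG11(g, m) + T.t12 * AG12(g, m) + T.t22 * AG22(g, m);
    for (int j = 0; j < p; ++j)
      Mxy[j] -= T.t11 * AQ11(g, j) + T.t12 * AQ12(g, j) + T.t22 * AQ22(g, j);
    myy -= T.t11 * AR(g, 0) + T.t12 * AR(g, 1) + T.t22 * AR(g, 2);
  }
  // expand packed lower triangle to full column-major
  std::vector<double> Mxx(p * p);
  int m = 0;
  for (int j = 0; j < p; ++j)
    for (int k = 0; k <= j; ++k, ++m) {
      Mxx[j + p * k] = Mp[m];
      Mxx[k + p * j] = Mp[m];
    }
  std::vector<double> chol = Mxx;
  const double logdetXWX = chol_in_place(chol, p);
  if (!R_finite(logdetXWX))
    return List::create(_["objective"] = 1e10, _["ok"] = false);
  std::vector<double> beta = Mxy;
  chol_solve(chol, p, beta);
  double rss = myy;
  for (int j = 0; j < p; ++j) rss -= beta[j] * Mxy[j];
  if (rss < 0.0) rss = 0.0;
  const double df = Nw - p;
  const double s2 = rss / df;
  const double obj = df * (1.0 + std::log(std::max(s2, 1e-300)) +
                           std::log(2.0 * M_PI)) + sumlog + logdetXWX;
  if (!details)
    return List::create(_["objective"] = obj, _["ok"] = true);
  NumericMatrix vcov(p, p);
  for (int j = 0; j < p; ++j) {
    std::vector<double> e(p, 0.0);
    e[j] = 1.0;
    chol_solve(chol, p, e);
    for (int i = 0; i < p; ++i) vcov(i, j) = s2 * e[i];
  }
  return List::create(_["objective"] = obj, _["ok"] = true,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["sigma2"] = s2, _["vcov_beta"] = vcov);
}

// Objective-only entry point (no list allocation) for optimizer loops.
// [[Rcpp::export]]
double cdr_reml_obj_agg(NumericVector theta, List agg) {
  List r = cdr_reml_eval_agg(theta, agg, false);
  return as<double>(r["objective"]);
}
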