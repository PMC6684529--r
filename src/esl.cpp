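// Compiled core for exponential-squared-loss (ESL) regression.
//
// Hot paths only: the fixed-gamma IRLS maximizer, the elemental-subsample
// MM initial estimator, the gamma-grid determinant scan, and the outer
// fixed-point loop.  R-level counterparts in R/ define the user surface and
// serve as an independently coded path for the double-entry tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

static inline double esl_objective_cpp(const vec& r, double gamma) {
  return accu(exp(-square(r) / gamma));
}

// gradient of the objective wrt beta: X' * ((2 r / gamma) .* exp(-r^2/gamma))
static inline vec esl_grad_cpp(const mat& X, const vec& r, double gamma) {
  vec w = exp(-square(r) / gamma);
  return X.t() * ((2.0 / gamma) * (r % w));
}

// weighted least squares: solve (X'WX) b = X'Wy; false if near-singular
static bool wls_solve(const mat& X, const vec& y, const vec& w, vec& beta) {
  mat Xw = X.each_col() % w;
  mat A = X.t() * Xw;
  vec b = Xw.t() * y;
  if (!A.is_finite() || rcond(A) < 1e-13) return false;
  bool ok = solve(beta, A, b, solve_opts::likely_sympd + solve_opts::no_approx);
  return ok && beta.is_finite();
}

// [[Rcpp::export]]
List cpp_irls_esl(const arma::mat& X, const arma::vec& y, double gamma,
                  const arma::vec& beta0, double tol_grad, double tol_step,
                  int max_iter, int max_halvings) {
  vec beta = beta0;
  vec r = y - X * beta;
  double obj = esl_objective_cpp(r, gamma);
  bool converged = false;
  std::string status = "ok";
  int it = 0;
  std::vector<double> step_trace;
  std::vector<double> obj_trace;
  obj_trace.push_back(obj);

  // already stationary?
  if (norm(esl_grad_cpp(X, r, gamma), "inf") <= tol_grad) converged = true;

  while (!converged && it < max_iter) {
    ++it;
    vec w = exp(-square(r) / gamma);
    vec bnew;
    if (!wls_solve(X, y, w, bnew)) { status = "degenerate"; break; }
    vec step = bnew - beta;
    // step halving: never accept a step that decreases the objective
    vec btry = bnew;
    vec rtry = y - X * btry;
    double objtry = esl_objective_cpp(rtry, gamma);
    int h = 0;
    while (objtry < obj - 1e-12 && h < max_halvings) {
      ++h;
      step *= 0.5;
      btry = beta + step;
      rtry = y - X * btry;
      objtry = esl_objective_cpp(rtry, gamma);
    }
    if (objtry < obj - 1e-12) { // no ascent direction left: stationary
      converged = true;
      break;
    }
    beta = btry; r = rtry; obj = objtry;
    double snorm = norm(step, 2);
    step_trace.push_back(snorm);
    obj_trace.push_back(obj);
    if (norm(esl_grad_cpp(X, r, gamma), "inf") <= tol_grad ||
        snorm <= tol_step) {
      converged = true;
    }
  }

  return List::create(
    _["beta"] = beta, _["residuals"] = r,
    _["objective"] = esl_objective_cpp(r, gamma),
    _["converged"] = converged, _["iterations"] = it,
    _["step_trace"] = step_trace, _["obj_trace"] = obj_trace,
    _["status"] = status);
}

// Tukey bisquare rho standardized to [0, 1]; t = (u/c)^2
static inline double rho_bisq_std(double u, double c) {
  double t = (u / c) * (u / c);
  if (t >= 1.0) return 1.0;
  return t * (3.0 + t * (-3.0 + t));
}

// M-scale: solve mean(rho_std(r/s, c)) = b; returns 0 for exact fits
static double mscale_bisq(const vec& r, double c, double b) {
  const uword n = r.n_elem;
  vec a = abs(r);
  double s = median(a) / 0.6745;
  if (s < 1e-300) return 0.0;
  for (int it = 0; it < 100; ++it) {
    double m = 0.0;
    for (uword i = 0; i < n; ++i) m += rho_bisq_std(a(i), c * s);
    m /= n;
    if (m < 1e-300) return 0.0;
    double snew = s * std::sqrt(m / b);
    if (std::abs(snew - s) <= 1e-10 * s) return snew;
    s = snew;
  }
  return s;
}

static inline vec bisq_weights(const vec& r, double s, double c) {
  vec u = r / (s * c);
  vec w(r.n_elem);
  for (uword i = 0; i < r.n_elem; ++i) {
    double t = 1.0 - u(i) * u(i);
    w(i) = (t > 0.0) ? t * t : 0.0;
  }
  return w;
}

// MM estimator: elemental-subsample S-stage (bisquare, c0, b = 0.5) refined
// by I-steps, then an efficiency M-step (bisquare, c1) at fixed S-scale.
// Uses R's RNG so set.seed() governs the subsample sequence.
// [[Rcpp::export]]
List cpp_mm(const arma::mat& X, const arma::vec& y, int n_subsamples,
            double c0, double c1) {
  const uword n = X.n_rows, p = X.n_cols;
  const double b = 0.5;
  RNGScope scope;

  vec best_beta(p, fill::zeros);
  double best_s = datum::inf;
  int n_singular = 0;
  bool exact = false;
  std::vector<int> pool(n);

  for (int k = 0; k < n_subsamples && !exact; ++k) {
    // partial Fisher-Yates draw of p distinct row indices
    for (uword i = 0; i < n; ++i) pool[i] = i;
    uvec idx(p);
    for (uword j = 0; j < p; ++j) {
      uword pick = j + (uword)std::floor(unif_rand() * (n - j));
      if (pick >= n) pick = n - 1;
      std::swap(pool[j], pool[pick]);
      idx(j) = pool[j];
    }
    mat Xs = X.rows(idx);
    if (rcond(Xs) < 1e-10) { ++n_singular; continue; }
    vec bcand;
    if (!solve(bcand, Xs, y.elem(idx), solve_opts::no_approx) ||
        !bcand.is_finite()) { ++n_singular; continue; }
    vec r = y - X * bcand;
    double s = mscale_bisq(r, c0, b);
    if (s == 0.0) { best_beta = bcand; best_s = 0.0; exact = true; break; }
    if (s < best_s) { best_s = s; best_beta = bcand; }
  }

  if (!std::isfinite(best_s))
    return List::create(_["status"] = "all_subsamples_singular");

  vec beta = best_beta;
  double s = best_s;
  if (s > 0.0) {
    // I-steps: refine the best elemental candidate to the local S-estimate
    vec r = y - X * beta;
    for (int it = 0; it < 50; ++it) {
      vec w = bisq_weights(r, s, c0);
      vec bnew;
      if (!wls_solve(X, y, w, bnew)) break;
      double stepnorm = norm(bnew - beta, 2);
      beta = bnew;
      r = y - X * beta;
      s = mscale_bisq(r, c0, b);
      if (s == 0.0 || stepnorm <= 1e-8) break;
    }
    // M-step at fixed scale, 95% efficiency tuning, with step halving on
    // the bisquare objective so the refinement never degrades the fit
    if (s > 0.0) {
      double obj = 0.0;
      for (uword i = 0; i < n; ++i) obj += rho_bisq_std(r(i), c1 * s);
      for (int it = 0; it < 50; ++it) {
        vec w = bisq_weights(r, s, c1);
        vec bnew;
        if (!wls_solve(X, y, w, bnew)) break;
        vec step = bnew - beta;
        vec btry = bnew;
        vec rtry = y - X * btry;
        double objtry = 0.0;
        for (uword i = 0; i < n; ++i) objtry += rho_bisq_std(rtry(i), c1 * s);
        int h = 0;
        while (objtry > obj + 1e-12 && h < 30) {
          ++h;
          step *= 0.5;
          btry = beta + step;
          rtry = y - X * btry;
          objtry = 0.0;
          for (uword i = 0; i < n; ++i)
            objtry += rho_bisq_std(rtry(i), c1 * s);
        }
        if (objtry > obj + 1e-12) break;
        double stepnorm = norm(step, 2);
        beta = btry; r = rtry; obj = objtry;
        if (stepnorm <= 1e-8) break;
      }
    }
  }

  return List::create(_["beta"] = beta, _["scale"] = s,
                      _["n_singular"] = n_singular, _["status"] = "ok");
}

static inline double median_cpp(vec v) { return median(v); }

// MAD residual scale with the Gaussian consistency factor
static double sn_scale(const vec& r) {
  double med = median_cpp(r);
  return 1.4826 * median_cpp(abs(r - med));
}

// Determinant of V(gamma) via the separable identity
//   V = a^{-2} Mxx^{-1} Sigma Mxx^{-1},  det V = det(Sigma) / (a^{2p} det(Mxx)^2)
// where a = -mean[(2/g) e^{-r^2/g} (2 r^2/g - 1)] (positive near a maximum)
// and Sigma is the 1/n covariance of the score contributions.
struct GammaScan {
  vec zeta, detV;
  uvec feasible;
};

static GammaScan gamma_scan(const mat& X, const vec& r, const uvec& out_idx,
                            const vec& grid, double det_mxx, uword p,
                            double n) {
  GammaScan gs;
  const uword G = grid.n_elem;
  gs.zeta.set_size(G); gs.detV.set_size(G); gs.feasible.set_size(G);
  const double m = out_idx.n_elem;

  // residuals not flagged as pseudo-outliers
  uvec keep = regspace<uvec>(0, r.n_elem - 1);
  if (m > 0) {
    std::vector<uword> kp;
    uvec mark(r.n_elem, fill::zeros);
    for (uword i = 0; i < out_idx.n_elem; ++i) mark(out_idx(i)) = 1;
    for (uword i = 0; i < r.n_elem; ++i) if (!mark(i)) kp.push_back(i);
    keep = uvec(kp);
  }
  vec r_in = r.elem(keep);

  for (uword g = 0; g < G; ++g) {
    double gamma = grid(g);
    vec u = square(r) / gamma;
    vec e = exp(-u);
    // feasibility functional
    double z = 2.0 * m / n +
      (2.0 / n) * accu(1.0 - exp(-square(r_in) / gamma));
    gs.zeta(g) = z;
    // scalar curvature factor (negated Hessian scalar)
    double a = mean((2.0 / gamma) * e % (1.0 - 2.0 * u));
    bool ok = (z > 0.0 && z <= 1.0 && a > 0.0);
    double dv = datum::nan;
    if (ok) {
      mat S = X.each_col() % ((2.0 / gamma) * (r % e));
      rowvec sbar = mean(S, 0);
      mat Sigma = S.t() * S / n - sbar.t() * sbar;
      double dS = det(Sigma);
      dv = dS / (std::pow(a, 2.0 * p) * det_mxx * det_mxx);
      if (!std::isfinite(dv) || dv < 0.0) ok = false;
    }
    gs.detV(g) = dv;
    gs.feasible(g) = ok ? 1 : 0;
  }
  return gs;
}

// [[Rcpp::export]]
List cpp_gamma_table(const arma::mat& X, const arma::vec& y,
                     const arma::vec& beta, const arma::vec& grid) {
  const double n = X.n_rows;
  vec r = y - X * beta;
  double sn = sn_scale(r);
  uvec out_idx;
  if (sn > 0.0) out_idx = find(abs(r) >= 2.5 * sn);
  mat Mxx = X.t() * X / n;
  GammaScan gs = gamma_scan(X, r, out_idx, grid, det(Mxx), X.n_cols, n);
  return List::create(
    _["gamma"] = grid, _["zeta"] = gs.zeta, _["detV"] = gs.detV,
    _["feasible"] = LogicalVector(gs.feasible.begin(), gs.feasible.end()),
    _["S_n"] = sn, _["m"] = (double)out_idx.n_elem);
}

// pick the feasible gamma with smallest detV; ties go to the larger gamma
static int pick_gamma(const vec& grid, const GammaScan& gs) {
  int best = -1;
  for (uword g = 0; g < grid.n_elem; ++g) {
    if (!gs.feasible(g)) continue;
    if (best < 0 || gs.detV(g) < gs.detV(best) ||
        (gs.detV(g) == gs.detV(best) && grid(g) > grid(best)))
      best = (int)g;
  }
  return best;
}

// Full outer loop: pseudo-outlier set -> gamma by det(V) -> IRLS refit,
// iterated until ||beta_old - beta_new|| < outer_tol (Euclidean).
// [[Rcpp::export]]
List cpp_fit_esl(const arma::mat& X, const arma::vec& y,
                 const arma::vec& beta0, double outer_tol, int max_outer,
                 int n_grid, double grid_lo, double grid_hi,
                 double tol_grad, double tol_step, int max_inner,
                 int max_halvings) {
  const double n = X.n_rows;
  const uword p = X.n_cols;
  vec beta = beta0;
  double gamma = NA_REAL;
  bool converged = false;
  std::string status = "ok";
  int outer = 0;
  std::vector<double> trace, gamma_trace, m_trace;
  mat Mxx = X.t() * X / n;
  double det_mxx = det(Mxx);
  List bad_table;

  while (outer < max_outer) {
    ++outer;
    vec r = y - X * beta;
    double sn = sn_scale(r);
    if (sn == 0.0 && max(abs(r)) < 1e-10) {
      // exact fit: no feasible gamma exists (zeta = 0); fit is already final
      if (!std::isfinite(gamma)) gamma = 1.0;
      converged = true;
      trace.push_back(0.0); gamma_trace.push_back(gamma); m_trace.push_back(0);
      break;
    }
    double s2 = (sn > 0.0) ? sn * sn : var(r);  // scale fallback when MAD = 0
    uvec out_idx;
    if (sn > 0.0) out_idx = find(abs(r) >= 2.5 * sn);
    vec grid = exp(linspace<vec>(std::log(s2 * grid_lo),
                                 std::log(s2 * grid_hi), n_grid));
    GammaScan gs = gamma_scan(X, r, out_idx, grid, det_mxx, p, n);
    int sel = pick_gamma(grid, gs);
    if (sel < 0) {
      status = "no_feasible_gamma";
      bad_table = List::create(
        _["gamma"] = grid, _["zeta"] = gs.zeta, _["detV"] = gs.detV,
        _["feasible"] = LogicalVector(gs.feasible.begin(),
                                      gs.feasible.end()));
      break;
    }
    gamma = grid(sel);
    vec w = exp(-square(r) / gamma);
    List inner = cpp_irls_esl(X, y, gamma, beta, tol_grad, tol_step,
                              max_inner, max_halvings);
    if (as<std::string>(inner["status"]) != "ok") {
      status = as<std::string>(inner["status"]);
      break;
    }
    vec bnew = as<vec>(inner["beta"]);
    double step = norm(bnew - beta, 2);
    beta = bnew;
    trace.push_back(step);
    gamma_trace.push_back(gamma);
    m_trace.push_back((double)out_idx.n_elem);
    if (step < outer_tol) { converged = true; break; }
  }

  vec r = y - X * beta;
  double sn = sn_scale(r);
  double m_final = (sn > 0.0) ? (double)find(abs(r) >= 2.5 * sn).eval().n_elem
                              : 0.0;
  return List::create(
    _["beta"] = beta, _["gamma"] = gamma, _["residuals"] = r,
    _["m"] = m_final, _["converged"] = converged, _["n_outer"] = outer,
    _["trace"] = trace, _["gamma_trace"] = gamma_trace,
    _["m_trace"] = m_trace, _["status"] = status,
    _["diagnostics"] = bad_table);
}
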