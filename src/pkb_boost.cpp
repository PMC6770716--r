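// Core numerics for pathway kernel boosting.
//
// Second-order boosting on the empirical log loss: at iteration t the
// quadratic expansion gives per-sample working responses eta = h/q and
// curvature weights W; each pathway's base learner solves a penalized
// weighted least-squares problem in its kernel expansion coefficients.
// After a W-weighted centering projection P = I - 1 w' / tr(W), the problem
// is a LASSO (L1) or ridge (L2) without intercept with design
// Ktilde = W^{1/2} P K and response -etatilde = -W^{1/2} P eta.
//
// For ridge, the hot loop uses the push-through identity
//   beta = -(K'K~ + N lam I)^{-1} K~' etat = -K~' (K~K~' + N lam I)^{-1} etat
// with K~K~' = W^{1/2} P K^2 P' W^{1/2} assembled in O(N^2) from a cached
// K^2, so each pathway costs one SPD solve instead of a gram product.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double softplus(double z) {
  // log(1 + e^z), overflow-safe
  return z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
}

// [[Rcpp::export]]
double cpp_logloss(const arma::vec& y, const arma::vec& F) {
  double s = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) s += softplus(-y[i] * F[i]);
  return s / y.n_elem;
}

// First and second derivatives of the empirical log loss wrt F(x_i):
// h_i = -y_i / (1 + exp(y_i F_i)), q_i = exp(y_i F_i) / (1 + exp(y_i F_i))^2
// [[Rcpp::export]]
List cpp_derivatives(const arma::vec& y, const arma::vec& F) {
  arma::uword n = y.n_elem;
  arma::vec h(n), q(n);
  for (arma::uword i = 0; i < n; ++i) {
    double z = y[i] * F[i];
    // sigma(-z) = 1/(1+e^z), computed stably on both sides
    double sm = z > 0 ? std::exp(-z) / (1.0 + std::exp(-z))
                      : 1.0 / (1.0 + std::exp(z));
    h[i] = -y[i] * sm;
    q[i] = sm * (1.0 - sm);
  }
  return List::create(_["h"] = h, _["q"] = q);
}

// LASSO without intercept by cyclic coordinate descent:
//   min_beta (1/N) || y - X beta ||^2 + lambda ||beta||_1
// [[Rcpp::export]]
arma::vec cpp_lasso_cd(const arma::mat& X, const arma::vec& y, double lambda,
                       double tol = 1e-7, int maxit = 100000,
                       bool strict = true) {
  arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::vec cn(p);
  for (arma::uword j = 0; j < p; ++j) cn[j] = arma::dot(X.col(j), X.col(j));
  // KKT at zero: lambda >= (2/N) ||X'y||_inf  =>  beta = 0 exactly
  double gmax = arma::abs(X.t() * y).max();
  if (lambda >= 2.0 * gmax / n) return beta;
  arma::vec r = y;  // residual y - X beta
  double thr = n * lambda / 2.0;
  std::vector<arma::uword> active;
  auto sweep = [&](double th, bool full) {
    double maxdel = 0.0;
    if (full) active.clear();
    arma::uword nj = full ? p : active.size();
    for (arma::uword k = 0; k < nj; ++k) {
      arma::uword j = full ? k : active[k];
      if (cn[j] <= 0) continue;
      double rho = arma::dot(X.col(j), r) + cn[j] * beta[j];
      double bnew = 0.0;
      if (rho > th) bnew = (rho - th) / cn[j];
      else if (rho < -th) bnew = (rho + th) / cn[j];
      double del = bnew - beta[j];
      if (del != 0.0) {
        r -= X.col(j) * del;
        beta[j] = bnew;
        double sc = cn[j] * del * del;
        if (sc > maxdel) maxdel = sc;
      }
      if (full && beta[j] != 0.0) active.push_back(j);
    }
    return maxdel;
  };
  // glmnet-style: pathwise warm starts from near lambdaMax down to the
  // target; at each path stop, iterate on the active set until stable, then
  // re-check all coordinates — converged when a full sweep moves nothing
  // beyond tol
  int it = 0;
  double yty = std::max(arma::dot(y, y), 1e-300);
  double lamMax = 2.0 * gmax / n;
  int nPath = std::max(1, (int)std::ceil(std::log(lamMax / lambda) /
                                         std::log(3.0)));
  nPath = std::min(nPath, 20);
  bool capped = false;
  auto solve_at = [&](double th, double tl) {
    while (!capped) {
      if (it >= maxit) {
        if (strict)
          stop("L1 coordinate descent did not converge within %d sweeps",
               maxit);
        capped = true;  // best-effort solution is still a descent direction
        break;
      }
      double d0 = sweep(th, true);
      ++it;
      if (d0 < tl * yty) break;
      while (true) {
        if (it >= maxit) break;
        double d1 = sweep(th, false);
        ++it;
        if (d1 < tl * yty) break;
      }
    }
  };
  for (int k = 1; k <= nPath; ++k) {
    double lam = lamMax * std::pow(lambda / lamMax, (double)k / nPath);
    double th = n * lam / 2.0;
    // intermediate path stops only need a loose solve
    solve_at(th, k == nPath ? tol : std::max(tol, 1e-4));
  }
  (void)thr;
  return beta;
}

struct PathFit {
  double obj;       // transformed regularized objective at the minimizer
  arma::vec beta;
  bool haveBeta;
};

// Fit one pathway's penalized base learner in the transformed space.
// For selection only the objective is needed; beta is computed on demand.
static PathFit fit_pathway(const arma::mat& K, const arma::mat* K2,
                           const arma::vec& s, const arma::vec& w,
                           double tau, const arma::vec& etat,
                           double lambda, int penalty, bool wantBeta,
                           double lassoTol, int lassoMaxit) {
  arma::uword n = K.n_rows;
  PathFit out;
  out.haveBeta = false;
  if (penalty == 2) {
    // B = W^{1/2} P K^2 P' W^{1/2} assembled from cached K^2 by rank-1 terms
    const arma::mat& A = *K2;
    arma::vec r = A * w;
    arma::vec rt = r / tau;
    double c0 = arma::dot(r, w) / (tau * tau);
    arma::mat B(n, n);
    for (arma::uword j = 0; j < n; ++j) {
      const double sj = s[j], rtj = rt[j] - c0;
      const double* Aj = A.colptr(j);
      double* Bj = B.colptr(j);
      for (arma::uword i = 0; i < n; ++i)
        Bj[i] = s[i] * sj * (Aj[i] - rtj - rt[i]);
      Bj[j] += n * lambda;
    }
    arma::vec z = arma::solve(B, etat, arma::solve_opts::likely_sympd);
    out.obj = lambda * arma::dot(etat, z);
    if (wantBeta) {
      arma::vec u = s % z;
      arma::vec v = u - w * (arma::accu(u) / tau);
      out.beta = -(K * v);
      out.haveBeta = true;
    }
  } else {
    // explicit Ktilde = diag(s) (K - 1 m') with m = K' w / tau
    arma::rowvec m = (w.t() * K) / tau;
    arma::mat Kt = K;
    Kt.each_row() -= m;
    Kt.each_col() %= s;
    arma::vec beta = cpp_lasso_cd(Kt, -etat, lambda, lassoTol, lassoMaxit,
                                  false);
    arma::vec resid = etat + Kt * beta;
    out.obj = arma::dot(resid, resid) / n + lambda * arma::accu(arma::abs(beta));
    out.beta = beta;
    out.haveBeta = true;
  }
  return out;
}

// Curvature weights, their sqrt, trace and working response transform.
static void working_quantities(const arma::vec& h, const arma::vec& q,
                               int wvariant, arma::vec& w, arma::vec& s,
                               double& tau, arma::vec& eta, arma::vec& etat) {
  arma::vec qf = arma::clamp(q, 1e-8, arma::datum::inf);
  w = (wvariant == 1) ? arma::vec(arma::square(qf)) : arma::vec(qf / 2.0);
  tau = arma::accu(w);
  s = arma::sqrt(w);
  eta = h / qf;
  double a = arma::dot(w, eta) / tau;
  etat = s % (eta - a);
}

// Evaluate every pathway's minimized regularized objective at the current
// (h, q); returns objectives, the selected (lowest-objective, ties to the
// lowest index) pathway, its beta and recovered intercept.
// [[Rcpp::export]]
List cpp_eval_pathways(List Klist, List K2list, const arma::vec& h,
                       const arma::vec& q, double lambda, int penalty,
                       int wvariant, double lassoTol = 1e-7,
                       int lassoMaxit = 100000) {
  int M = Klist.size();
  arma::vec w, s, eta, etat;
  double tau;
  working_quantities(h, q, wvariant, w, s, tau, eta, etat);
  arma::vec objs(M);
  int best = -1;
  double bestObj = arma::datum::inf;
  for (int m = 0; m < M; ++m) {
    NumericMatrix Km = Klist[m];
    arma::mat K(Km.begin(), Km.nrow(), Km.ncol(), false);
    arma::mat K2;
    const arma::mat* K2p = nullptr;
    if (penalty == 2) {
      NumericMatrix K2m = K2list[m];
      K2 = arma::mat(K2m.begin(), K2m.nrow(), K2m.ncol(), false);
      K2p = &K2;
    }
    PathFit f = fit_pathway(K, K2p, s, w, tau, etat, lambda, penalty, false,
                            lassoTol, lassoMaxit);
    objs[m] = f.obj;
    if (f.obj < bestObj) { bestObj = f.obj; best = m; }
  }
  // refit the winner with coefficients
  NumericMatrix Km = Klist[best];
  arma::mat K(Km.begin(), Km.nrow(), Km.ncol(), false);
  arma::mat K2;
  const arma::mat* K2p = nullptr;
  if (penalty == 2) {
    NumericMatrix K2m = K2list[best];
    K2 = arma::mat(K2m.begin(), K2m.nrow(), K2m.ncol(), false);
    K2p = &K2;
  }
  PathFit f = fit_pathway(K, K2p, s, w, tau, etat, lambda, penalty, true,
                          lassoTol, lassoMaxit);
  arma::vec Kb = K * f.beta;
  double c = -arma::dot(w, eta + Kb) / tau;
  return List::create(_["objectives"] = objs, _["selected"] = best + 1,
                      _["beta"] = f.beta, _["intercept"] = c,
                      _["fhat"] = Kb + c);
}

// Golden-section minimization of the exact empirical log loss over the step
// length d in [0, dmax].
// [[Rcpp::export]]
double cpp_line_search(const arma::vec& y, const arma::vec& F,
                       const arma::vec& f, double dmax = 100.0,
                       double tol = 1e-8) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = 0.0, b = dmax;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = cpp_logloss(y, F + x1 * f), f2 = cpp_logloss(y, F + x2 * f);
  while (b - a > tol) {
    if (f1 <= f2) {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = cpp_logloss(y, F + x1 * f);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = cpp_logloss(y, F + x2 * f);
    }
  }
  double d = (a + b) / 2.0;
  // d = 0 must remain feasible: never return a step that increases the loss
  if (cpp_logloss(y, F + d * f) > cpp_logloss(y, F)) d = 0.0;
  return d;
}

// Full boosting loop. Klist: per-pathway N x N training kernels; K2list:
// their squares (L2 only, else empty); Kvallist: optional cross-kernels
// (n_val x N) for per-iteration validation-loss monitoring.
// [[Rcpp::export]]
List cpp_boost(List Klist, List K2list, const arma::vec& y, double F0,
               double lambda, double nu, int T, int penalty, int wvariant,
               List Kvallist, const arma::vec& yval, bool monitor,
               double dmax = 100.0, double lassoTol = 1e-7,
               int lassoMaxit = 100000, double zeroTol = 1e-10,
               int patience = -1) {
  int M = Klist.size();
  arma::uword n = y.n_elem;
  arma::vec F(n, arma::fill::value(F0));
  arma::vec Fval;
  if (monitor) Fval.set_size(yval.n_elem), Fval.fill(F0);

  arma::mat betaAgg(n, M, arma::fill::zeros);
  double cAgg = 0.0;
  std::vector<int> sel;
  std::vector<double> dvec, cvec, objvec, trainLoss, valLoss, valErr;
  trainLoss.push_back(cpp_logloss(y, F));
  bool earlyStopped = false;
  double bestVal = arma::datum::inf;
  int sinceBest = 0;

  for (int t = 0; t < T; ++t) {
    arma::vec w, s, eta, etat;
    double tau;
    List drv = cpp_derivatives(y, F);
    arma::vec h = drv["h"], q = drv["q"];
    working_quantities(h, q, wvariant, w, s, tau, eta, etat);

    int best = -1;
    double bestObj = arma::datum::inf;
    arma::vec bestBeta;
    for (int m = 0; m < M; ++m) {
      NumericMatrix Km = Klist[m];
      arma::mat K(Km.begin(), Km.nrow(), Km.ncol(), false);
      arma::mat K2;
      const arma::mat* K2p = nullptr;
      if (penalty == 2) {
        NumericMatrix K2m = K2list[m];
        K2 = arma::mat(K2m.begin(), K2m.nrow(), K2m.ncol(), false);
        K2p = &K2;
      }
      PathFit f = fit_pathway(K, K2p, s, w, tau, etat, lambda, penalty,
                              penalty == 1, lassoTol,
                              penalty == 1 ? std::min(lassoMaxit, 300)
                                           : lassoMaxit);
      if (f.obj < bestObj) {
        bestObj = f.obj;
        best = m;
        if (f.haveBeta) bestBeta = f.beta;
      }
    }
    NumericMatrix Km = Klist[best];
    arma::mat K(Km.begin(), Km.nrow(), Km.ncol(), false);
    if (penalty == 2) {
      NumericMatrix K2m = K2list[best];
      arma::mat K2(K2m.begin(), K2m.nrow(), K2m.ncol(), false);
      PathFit f = fit_pathway(K, &K2, s, w, tau, etat, lambda, 2, true,
                              lassoTol, lassoMaxit);
      bestBeta = f.beta;
    } else {
      // refit the winning pathway with a larger sweep budget
      PathFit f = fit_pathway(K, nullptr, s, w, tau, etat, lambda, 1, true,
                              lassoTol, std::min(lassoMaxit, 2000));
      bestBeta = f.beta;
    }
    arma::vec Kb = K * bestBeta;
    double c = -arma::dot(w, eta + Kb) / tau;

    // L1 no-descent: an all-zero learner makes no change to the model
    if (penalty == 1 && arma::abs(bestBeta).max() < zeroTol &&
        std::abs(c) < zeroTol) {
      earlyStopped = true;
      break;
    }

    arma::vec fhat = Kb + c;
    double d = cpp_line_search(y, F, fhat, dmax, 1e-9);
    F += (nu * d) * fhat;
    betaAgg.col(best) += (nu * d) * bestBeta;
    cAgg += nu * d * c;

    sel.push_back(best + 1);
    dvec.push_back(d);
    cvec.push_back(c);
    objvec.push_back(bestObj);
    trainLoss.push_back(cpp_logloss(y, F));
    // training data (numerically) separated: no meaningful descent remains
    // and the working responses become arbitrarily stiff; stop here
    if (trainLoss.back() < 1e-5) {
      earlyStopped = true;
      if (monitor) {
        NumericMatrix Kvm = Kvallist[best];
        arma::mat Kv(Kvm.begin(), Kvm.nrow(), Kvm.ncol(), false);
        Fval += (nu * d) * (Kv * bestBeta + c);
        valLoss.push_back(cpp_logloss(yval, Fval));
        double ne = 0;
        for (arma::uword i = 0; i < yval.n_elem; ++i)
          if ((Fval[i] >= 0 ? 1.0 : -1.0) != yval[i]) ne += 1.0;
        valErr.push_back(ne / yval.n_elem);
      }
      break;
    }
    if (monitor) {
      NumericMatrix Kvm = Kvallist[best];
      arma::mat Kv(Kvm.begin(), Kvm.nrow(), Kvm.ncol(), false);
      Fval += (nu * d) * (Kv * bestBeta + c);
      double vl = cpp_logloss(yval, Fval);
      valLoss.push_back(vl);
      double ne = 0;
      for (arma::uword i = 0; i < yval.n_elem; ++i)
        if ((Fval[i] >= 0 ? 1.0 : -1.0) != yval[i]) ne += 1.0;
      valErr.push_back(ne / yval.n_elem);
      // optional stop when the held-out loss has not improved for
      // `patience` iterations (the recorded curve is padded by the caller)
      if (vl < bestVal - 1e-10) { bestVal = vl; sinceBest = 0; }
      else if (patience >= 0 && ++sinceBest >= patience) { break; }
    }
  }

  return List::create(_["selected"] = sel, _["d"] = dvec, _["intercept"] = cvec,
                      _["objective"] = objvec, _["trainLoss"] = trainLoss,
                      _["valLoss"] = valLoss, _["valErr"] = valErr,
                      _["betaAgg"] = betaAgg,
                      _["cAgg"] = cAgg, _["earlyStopped"] = earlyStopped,
                      _["F"] = F);
}
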