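#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Covariance-form lasso and graphical lasso solvers.
//
// Both engines below work on a p x p (correlation) matrix, never on the raw
// n x p data, so the cost of a whole regularization path is independent of n.
// The inner problem shared by both is the Gram-form lasso
//   min_beta 1/2 beta' G beta - c' beta + lambda ||beta||_1
// solved by cyclic coordinate descent with a cached gradient residual and an
// active-set strategy (sweeps over the nonzero set until stable, then one
// full sweep to admit violators), warm-started along the penalty path.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

struct CDWork {
  std::vector<double> r;  // residual gradient c - G beta (coordinate "skip" ignored)
};

// One coordinate-descent sweep over the given index set; returns max |change|.
static double cd_sweep(const double* G, double* beta, double* r, int p,
                       int skip, double lambda, const int* idx, int nidx) {
  double dmax = 0.0;
  for (int t = 0; t < nidx; ++t) {
    const int i = idx[t];
    const double gii = G[(R_xlen_t)i * p + i];
    const double bnew = soft(r[i] + gii * beta[i], lambda) / gii;
    const double d = bnew - beta[i];
    if (d != 0.0) {
      const double* Gi = G + (R_xlen_t)i * p;
      for (int k = 0; k < p; ++k) r[k] -= Gi[k] * d;
      beta[i] = bnew;
      const double ad = std::fabs(d);
      if (ad > dmax) dmax = ad;
    }
  }
  return dmax;
}

// Solve the Gram-form lasso restricted to indices != skip, beta[skip] == 0.
static void cd_lasso(const double* G, const double* c, double* beta,
                     double* r, int p, int skip, double lambda,
                     double tol, int maxit) {
  // fresh residual r = c - G beta over all coords
  for (int k = 0; k < p; ++k) r[k] = c[k];
  for (int i = 0; i < p; ++i) {
    if (i == skip || beta[i] == 0.0) continue;
    const double* Gi = G + (R_xlen_t)i * p;
    const double bi = beta[i];
    for (int k = 0; k < p; ++k) r[k] -= Gi[k] * bi;
  }
  std::vector<int> full, active;
  full.reserve(p - 1);
  for (int i = 0; i < p; ++i) if (i != skip) full.push_back(i);

  int it = 0;
  while (it < maxit) {
    // full sweep (admits new nonzeros)
    double dmax = cd_sweep(G, beta, r, p, skip, lambda, full.data(),
                           (int)full.size());
    ++it;
    if (dmax < tol) break;
    // active-set sweeps
    active.clear();
    for (int i = 0; i < p; ++i)
      if (i != skip && beta[i] != 0.0) active.push_back(i);
    while (it < maxit && !active.empty()) {
      dmax = cd_sweep(G, beta, r, p, skip, lambda, active.data(),
                      (int)active.size());
      ++it;
      if (dmax < tol) break;
    }
  }
}

static inline R_xlen_t edge_id(int i, int j, int p) {
  // i < j, 0-based; lower-triangle column-major order, matching lower.tri()
  return (R_xlen_t)i * p - (R_xlen_t)i * (i + 1) / 2 + (j - i - 1);
}

//' @noRd
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(NumericMatrix S, NumericVector lambdas,
                     double tol = 1e-4, int maxit = 100,
                     double inner_tol = 1e-4, int inner_maxit = 100,
                     bool return_theta = false) {
  const int p = S.nrow();
  const int K = lambdas.size();
  const R_xlen_t q = (R_xlen_t)p * (p - 1) / 2;
  IntegerMatrix support(q, K);
  LogicalVector converged(K);

  // W: current working covariance; B: column j = regression coefs for node j
  std::vector<double> W(S.begin(), S.end());
  std::vector<double> B((R_xlen_t)p * p, 0.0);
  std::vector<double> r(p);

  double s_off = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) s_off += std::fabs(S(i, j));
  s_off /= (double)p * (p - 1);
  if (s_off <= 0) s_off = 1.0;

  List thetas(return_theta ? K : 0);

  for (int k = 0; k < K; ++k) {
    const double lambda = lambdas[k];
    for (int i = 0; i < p; ++i) W[(R_xlen_t)i * p + i] = S(i, i) + lambda;

    bool ok = false;
    for (int outer = 0; outer < maxit; ++outer) {
      // classical criterion: average absolute change of the working
      // covariance below tol times the average absolute off-diagonal of S
      double wsum = 0.0;
      for (int j = 0; j < p; ++j) {
        double* beta = &B[(R_xlen_t)j * p];
        cd_lasso(W.data(), &S[(R_xlen_t)j * p], beta, r.data(), p, j, lambda,
                 inner_tol, inner_maxit);
        // w12 = W11 beta = (S_.j - r) restricted to i != j
        for (int i = 0; i < p; ++i) {
          if (i == j) continue;
          const double v = S[(R_xlen_t)j * p + i] - r[i];
          wsum += std::fabs(v - W[(R_xlen_t)j * p + i]);
          W[(R_xlen_t)j * p + i] = v;
          W[(R_xlen_t)i * p + j] = v;
        }
      }
      if (wsum / ((double)p * (p - 1)) < tol * s_off) { ok = true; break; }
    }
    converged[k] = ok;

    // Theta support: theta_12 = -beta * theta_22 with theta_22 > 0, so the
    // sparsity pattern of Theta is the (OR-symmetrized) pattern of B.
    for (int i = 0; i < p - 1; ++i)
      for (int j = i + 1; j < p; ++j)
        if (B[(R_xlen_t)j * p + i] != 0.0 || B[(R_xlen_t)i * p + j] != 0.0)
          support(edge_id(i, j, p), k) = 1;

    if (return_theta) {
      // theta_22 = 1 / (w_22 - w_12' beta); theta_12 = -beta theta_22
      NumericMatrix Theta(p, p);
      for (int j = 0; j < p; ++j) {
        const double* beta = &B[(R_xlen_t)j * p];
        double dot = 0.0;
        for (int i = 0; i < p; ++i)
          if (i != j && beta[i] != 0.0) dot += W[(R_xlen_t)j * p + i] * beta[i];
        const double t22 = 1.0 / (W[(R_xlen_t)j * p + j] - dot);
        Theta(j, j) = t22;
        for (int i = 0; i < p; ++i)
          if (i != j) Theta(i, j) = -beta[i] * t22;
      }
      // symmetrize (columns agree up to numerical error at convergence)
      for (int i = 0; i < p - 1; ++i)
        for (int j = i + 1; j < p; ++j) {
          const double v = 0.5 * (Theta(i, j) + Theta(j, i));
          Theta(i, j) = v;
          Theta(j, i) = v;
        }
      thetas[k] = Theta;
    }
  }
  if (return_theta)
    return List::create(_["support"] = support, _["converged"] = converged,
                        _["theta"] = thetas);
  return List::create(_["support"] = support, _["converged"] = converged);
}

//' @noRd
// [[Rcpp::export(name = ".mb_path_cpp")]]
IntegerMatrix mb_path_cpp(NumericMatrix S, NumericVector lambdas,
                          double inner_tol = 1e-4, int inner_maxit = 200) {
  const int p = S.nrow();
  const int K = lambdas.size();
  const R_xlen_t q = (R_xlen_t)p * (p - 1) / 2;
  // entry (e, k) = number of node-wise regressions (0, 1 or 2) selecting e
  IntegerMatrix votes(q, K);

  std::vector<double> beta(p), r(p);
  for (int j = 0; j < p; ++j) {
    std::fill(beta.begin(), beta.end(), 0.0);
    for (int k = 0; k < K; ++k) {  // warm start down the path
      cd_lasso(&S[0], &S[(R_xlen_t)j * p], beta.data(), r.data(), p, j,
               lambdas[k], inner_tol, inner_maxit);
      for (int i = 0; i < p; ++i) {
        if (i == j || beta[i] == 0.0) continue;
        R_xlen_t e = i < j ? edge_id(i, j, p) : edge_id(j, i, p);
        votes(e, k) += 1;
      }
    }
  }
  return votes;
}
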