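#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic-net objective
//   (1/(2n)) * ||y - X b||^2 + lambda * (alpha * |b|_1 + (1-alpha)/2 * |b|_2^2)
// in Gram ("covariance updating") form: G = X'X / n, c = X'y / n, with X
// standardized so diag(G) = 1.  Solves a descending lambda path with warm
// starts and an active-set strategy (sweeps over the current active set until
// convergence, then one full sweep as a KKT check).
//
// Returns the p x nlambda coefficient matrix, and optionally the per-sweep
// objective trace (to assert monotone descent).

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Convergence: a sweep converges when max_j (delta beta_j)^2 < tol * yty_n
// (relative to the response variance, as X is standardized) - the glmnet
// convention, so `tol` is comparable to glmnet's `thresh`.
// [[Rcpp::export(name = ".enet_path_gram")]]
List enet_path_gram(NumericMatrix G, NumericVector c, double yty_n,
                    NumericVector lambda, double alpha,
                    int maxit = 100000, double tol = 1e-7,
                    bool trace_objective = false) {
  const int p = c.size();
  const int nl = lambda.size();
  if (G.nrow() != p || G.ncol() != p) stop("G must be p x p");
  for (int j = 0; j < p; ++j) {
    if (!std::isfinite(c[j])) stop("non-finite values in the design");
  }

  const double tol_abs = tol * (yty_n > 0 ? yty_n : 1.0);
  NumericMatrix beta_out(p, nl);
  std::vector<double> beta(p, 0.0), q(p, 0.0); // q = G %*% beta
  std::vector<bool> active(p, false);
  std::vector<double> obj_trace;
  IntegerVector iters(nl);

  auto objective = [&]() {
    double fit = yty_n;
    double bq = 0.0, l1 = 0.0, l2 = 0.0;
    for (int j = 0; j < p; ++j) {
      fit -= 2.0 * c[j] * beta[j];
      bq += beta[j] * q[j];
      l1 += std::fabs(beta[j]);
      l2 += beta[j] * beta[j];
    }
    return 0.5 * (fit + bq);
  };

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    const double l1pen = lam * alpha;
    const double denom = 1.0 + lam * (1.0 - alpha);
    int it = 0;
    bool converged_path = false;

    while (it < maxit && !converged_path) {
      // full sweep over all coordinates (also refreshes the active set)
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        const double rho = c[j] - q[j] + beta[j]; // G[j][j] == 1
        const double bnew = soft(rho, l1pen) / denom;
        const double del = bnew - beta[j];
        if (del != 0.0) {
          beta[j] = bnew;
          const double* gj = &G(0, j);
          for (int k = 0; k < p; ++k) q[k] += gj[k] * del;
          if (del * del > maxdel) maxdel = del * del;
        }
        active[j] = beta[j] != 0.0;
      }
      ++it;
      if (trace_objective) {
        double o = objective();
        double pen = 0.0;
        for (int j = 0; j < p; ++j)
          pen += lam * (alpha * std::fabs(beta[j]) +
                        0.5 * (1.0 - alpha) * beta[j] * beta[j]);
        obj_trace.push_back(o + pen);
      }
      if (maxdel < tol_abs) {
        converged_path = true;
        break;
      }
      // inner sweeps restricted to the active set
      while (it < maxit) {
        double maxdel_a = 0.0;
        for (int j = 0; j < p; ++j) {
          if (!active[j]) continue;
          const double rho = c[j] - q[j] + beta[j];
          const double bnew = soft(rho, l1pen) / denom;
          const double del = bnew - beta[j];
          if (del != 0.0) {
            beta[j] = bnew;
            const double* gj = &G(0, j);
            for (int k = 0; k < p; ++k) q[k] += gj[k] * del;
            if (del * del > maxdel_a) maxdel_a = del * del;
          }
        }
        ++it;
        if (trace_objective) {
          double o = objective();
          double pen = 0.0;
          for (int j = 0; j < p; ++j)
            pen += lam * (alpha * std::fabs(beta[j]) +
                          0.5 * (1.0 - alpha) * beta[j] * beta[j]);
          obj_trace.push_back(o + pen);
        }
        if (maxdel_a < tol_abs) break;
      }
      // loop back for a full KKT-checking sweep
    }
    iters[l] = it;
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
  }

  List out = List::create(_["beta"] = beta_out, _["iterations"] = iters);
  if (trace_objective) out["objective"] = NumericVector(obj_trace.begin(), obj_trace.end());
  return out;
}
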