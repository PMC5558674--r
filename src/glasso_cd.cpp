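#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cyclic coordinate descent for the column lasso subproblem
//   min_b 0.5 * b' V b - s' b + rho * ||b||_1
// V is positive definite (a principal submatrix of the current W).
// b is updated in place; V*b is maintained incrementally.
static void lasso_cd(const mat& V, const vec& s, vec& b, double rho,
                     double tol, int max_iter) {
  const uword p = b.n_elem;
  vec Vb = V * b;
  for (int it = 0; it < max_iter; ++it) {
    double dmax = 0.0;
    for (uword k = 0; k < p; ++k) {
      const double bk = s[k] - (Vb[k] - V(k, k) * b[k]);
      double bnew = 0.0;
      if (bk > rho) {
        bnew = (bk - rho) / V(k, k);
      } else if (bk < -rho) {
        bnew = (bk + rho) / V(k, k);
      }
      const double diff = bnew - b[k];
      if (diff != 0.0) {
        Vb += V.col(k) * diff;
        b[k] = bnew;
        const double ad = std::abs(diff);
        if (ad > dmax) dmax = ad;
      }
    }
    if (dmax < tol) break;
  }
}

// Block coordinate descent for the graphical lasso:
// maximize log det(theta) - tr(S theta) - rho * sum(|theta_ij|).
// Maintains the dual/covariance iterate W (W diag = S diag + rho) and the
// per-column lasso coefficients B; cycles over columns in input order.
// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double rho, double tol, int max_iter,
                     double inner_tol, int inner_max_iter,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const uword m = S.n_rows;

  mat W = S;
  W.diag() += rho;
  mat B(m, m, fill::zeros);  // B(i, j): coefficient of feature i in column j's lasso
  if (W_init.isNotNull()) {
    W = Rcpp::as<mat>(W_init.get());
    W.diag() = S.diag() + rho;  // the diagonal is fixed by the KKT conditions
  }
  if (B_init.isNotNull()) B = Rcpp::as<mat>(B_init.get());

  // Convergence scale: mean |off-diagonal of S| (diagonal scale if S diagonal)
  double denom = 0.0;
  if (m > 1) {
    denom = (accu(abs(S)) - accu(abs(S.diag()))) / (double)(m * (m - 1));
  }
  if (denom <= 0.0) denom = mean(abs(S.diag()));
  if (denom <= 0.0) denom = 1.0;

  bool converged = (m == 1);
  int iters = 0;
  double last_delta = 0.0;

  if (m > 1) {
    uvec all = regspace<uvec>(0, m - 1);
    for (int sweep = 0; sweep < max_iter; ++sweep) {
      double dsum = 0.0;
      for (uword j = 0; j < m; ++j) {
        uvec idx = find(all != j);
        mat W11 = W(idx, idx);
        vec s12 = S.col(j);
        s12 = s12(idx);
        vec b = B.col(j);
        b = b(idx);
        lasso_cd(W11, s12, b, rho, inner_tol, inner_max_iter);
        vec w12 = W11 * b;
        vec w_old = W.col(j);
        w_old = w_old(idx);
        dsum += accu(abs(w12 - w_old));
        for (uword t = 0; t < idx.n_elem; ++t) {
          W(idx[t], j) = w12[t];
          W(j, idx[t]) = w12[t];
          B(idx[t], j) = b[t];
        }
      }
      iters = sweep + 1;
      last_delta = dsum / (double)(m * (m - 1));
      if (last_delta < tol * denom) {
        converged = true;
        break;
      }
    }
  } else {
    iters = 1;
  }

  // Recover theta from (W, B): theta_jj = 1 / (w_jj - w12' b), theta_.j = -b theta_jj
  mat Theta(m, m, fill::zeros);
  if (m == 1) {
    Theta(0, 0) = 1.0 / W(0, 0);
  } else {
    uvec all = regspace<uvec>(0, m - 1);
    for (uword j = 0; j < m; ++j) {
      uvec idx = find(all != j);
      vec b = B.col(j);
      b = b(idx);
      vec w12 = W.col(j);
      w12 = w12(idx);
      const double tjj = 1.0 / (W(j, j) - dot(w12, b));
      Theta(j, j) = tjj;
      for (uword t = 0; t < idx.n_elem; ++t) {
        Theta(idx[t], j) = -b[t] * tjj;
      }
    }
    Theta = 0.5 * (Theta + Theta.t());
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta, Rcpp::Named("W") = W,
      Rcpp::Named("B") = B, Rcpp::Named("iterations") = iters,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("delta") = last_delta);
}
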