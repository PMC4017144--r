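// Streaming Rauch-Tung-Striebel smoother for the companion-form latent VAR.
// The transition matrix is stored only through its dense top block
// [A^(1) ... A^(P)]; the identity shift blocks are applied structurally.
// Time-invariant covariance recursions are frozen once converged (relative
// steady-state tolerance), so long series cost O(T) only in the mean
// recursions and O(k (PN)^3) in the covariance recursions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [A_top * S; S.rows(0, PN-N-1)]  ==  A_tilde * S
static mat comp_lmult(const mat& Atop, const mat& S) {
  const uword N = Atop.n_rows, PN = Atop.n_cols;
  if (PN == N) return Atop * S;
  mat out(PN, S.n_cols);
  out.rows(0, N - 1) = Atop * S;
  out.rows(N, PN - 1) = S.rows(0, PN - N - 1);
  return out;
}

// A_tilde * S * A_tilde'
static mat comp_sandwich(const mat& Atop, const mat& S) {
  const uword N = Atop.n_rows, PN = Atop.n_cols;
  mat TS = comp_lmult(Atop, S);
  if (PN == N) return TS * Atop.t();
  mat out(PN, PN);
  out.cols(0, N - 1) = TS * Atop.t();
  out.cols(N, PN - 1) = TS.cols(0, PN - N - 1);
  return out;
}

static vec comp_lmult_vec(const mat& Atop, const vec& x) {
  const uword N = Atop.n_rows, PN = Atop.n_cols;
  vec out(PN);
  out.head(N) = Atop * x;
  if (PN > N) out.subvec(N, PN - 1) = x.head(PN - N);
  return out;
}

static double rel_diff(const mat& A, const mat& B) {
  const double d = abs(A - B).max();
  const double s = std::max(abs(A).max(), abs(B).max());
  return d / (1.0 + s);
}

// solve A X = B for symmetric positive-definite A, with a jitter fallback
static mat sympd_solve(const mat& A, const mat& B, const char* where) {
  mat X;
  if (solve(X, A, B, solve_opts::likely_sympd + solve_opts::no_approx))
    return X;
  mat Aj = A + eye(size(A)) * (1e-10 * (trace(A) / A.n_rows) + 1e-300);
  if (solve(X, Aj, B)) return X;
  Rcpp::stop(std::string("singular covariance in smoother (") + where + ")");
  return X;  // unreached
}

// [[Rcpp::export(rng = false)]]
Rcpp::List kalman_smoother_cpp(const arma::mat& Atop, const arma::mat& Qtop,
                               const arma::mat& Z, double theta,
                               double freeze_tol) {
  const uword N = Atop.n_rows, PN = Atop.n_cols, T = Z.n_rows;
  const mat Robs = eye(N, N) / theta;

  // ---- forward pass -------------------------------------------------
  mat mf(T + 1, PN, fill::zeros);          // filtered means, row t
  std::vector<mat> Sf_store, Sp_store, K_store;
  Sf_store.push_back(eye(PN, PN));         // Sf at t = 0
  mat Sf_cur = Sf_store[0], Sp_cur, K_cur;
  bool frozen = false;
  uword kf = 0;                            // last step with stored covariances
  vec m(PN, fill::zeros);

  for (uword t = 1; t <= T; ++t) {
    vec mpred = comp_lmult_vec(Atop, m);
    if (!frozen) {
      mat Sp = comp_sandwich(Atop, Sf_cur);
      Sp.submat(0, 0, N - 1, N - 1) += Qtop;
      Sp = 0.5 * (Sp + Sp.t());
      mat Sobs = Sp.submat(0, 0, N - 1, N - 1) + Robs;
      mat K = Sp.cols(0, N - 1) * sympd_solve(Sobs, eye(N, N), "gain");
      mat Sf_new = Sp - K * Sp.rows(0, N - 1);
      Sf_new = 0.5 * (Sf_new + Sf_new.t());
      if (freeze_tol > 0 && t > 1 &&
          rel_diff(Sf_new, Sf_cur) < freeze_tol)
        frozen = true;
      Sf_cur = Sf_new;
      Sp_cur = Sp;
      K_cur = K;
      Sf_store.push_back(Sf_cur);
      Sp_store.push_back(Sp_cur);
      K_store.push_back(K_cur);
      kf = t;
    }
    m = mpred + K_cur * (Z.row(t - 1).t() - mpred.head(N));
    if (!m.is_finite())
      Rcpp::stop("non-finite filtered state at t = %d", (int) t);
    mf.row(t) = m.t();
  }

  // ---- backward pass ------------------------------------------------
  mat M = mf;                              // smoothed means, overwritten
  mat S_cur = (T <= kf) ? Sf_store[T] : Sf_cur;  // smoothed cov at t (= T)
  mat A00(PN, PN, fill::zeros);
  mat A10(N, PN, fill::zeros);
  mat A11(N, N, fill::zeros);
  mat C_next, J_next, J_ss;
  bool have_Jss = false, cov_frozen = false, cross_frozen = false;

  for (uword t = T; t >= 1; --t) {
    const mat& Sf_tm1 = (t - 1 <= kf) ? Sf_store[t - 1] : Sf_cur;
    const mat& Sp_t = (t <= kf) ? Sp_store[t - 1] : Sp_cur;
    const bool steady = (t - 1 >= kf);

    mat J;
    if (steady && have_Jss) {
      J = J_ss;
    } else {
      J = sympd_solve(Sp_t, comp_lmult(Atop, Sf_tm1), "smoother gain").t();
      if (steady) { J_ss = J; have_Jss = true; }
    }

    // cross-time covariance Sigma_{t,t-1}
    mat C_t;
    if (t == T) {
      mat ASf = comp_lmult(Atop, Sf_tm1);
      const mat& K_T = (T <= kf) ? K_store[T - 1] : K_cur;
      C_t = ASf - K_T * ASf.rows(0, N - 1);
    } else if (cross_frozen && steady) {
      C_t = C_next;
    } else {
      const mat& Sf_t = (t <= kf) ? Sf_store[t] : Sf_cur;
      mat ASt = comp_lmult(Atop, Sf_t);
      C_t = Sf_t * J.t() + J_next * (C_next - ASt) * J.t();
      if (freeze_tol > 0 && steady && t < T &&
          rel_diff(C_t, C_next) < freeze_tol)
        cross_frozen = true;
    }

    // smoothed mean and covariance at t-1
    vec mpred = comp_lmult_vec(Atop, mf.row(t - 1).t());
    M.row(t - 1) = (mf.row(t - 1).t() +
                    J * (M.row(t).t() - mpred)).t();
    mat S_tm1;
    if (cov_frozen && steady) {
      S_tm1 = S_cur;
    } else {
      S_tm1 = Sf_tm1 + J * (S_cur - Sp_t) * J.t();
      S_tm1 = 0.5 * (S_tm1 + S_tm1.t());
      if (freeze_tol > 0 && steady &&
          rel_diff(S_tm1, S_cur) < freeze_tol)
        cov_frozen = true;
    }
    if (!steady) { cov_frozen = false; cross_frozen = false; }

    A00 += S_tm1;
    A10 += C_t.rows(0, N - 1);
    A11 += S_cur.submat(0, 0, N - 1, N - 1);

    S_cur = S_tm1;
    C_next = C_t;
    J_next = J;
  }

  const mat M0 = M.rows(0, T - 1);
  const mat M1 = M.submat(1, 0, T, N - 1);
  mat S00 = A00 + M0.t() * M0;
  mat S10 = A10 + M1.t() * M0;
  mat S11 = A11 + M1.t() * M1;

  return Rcpp::List::create(
    Rcpp::Named("mean") = M,
    Rcpp::Named("S00") = S00,
    Rcpp::Named("S10") = S10,
    Rcpp::Named("S11") = S11,
    Rcpp::Named("n_stored") = (int) kf);
}
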