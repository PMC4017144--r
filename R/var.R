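#' Specify a vector autoregressive (VAR) model
#'
#' A VAR(P) process on N regions:
#' `s(t) = sum_p A^(p) s(t-p) + eta(t)`, `eta(t) ~ N(0, Lambda^-1)`,
#' where `A^(p)` is the N x N coefficient matrix at lag p and `Lambda` the
#' innovation precision. Entry `A^(p)[i, j]` carries the influence of region
#' j's past on region i (source in columns, target in rows).
#'
#' @param coeffs A single N x N matrix or a list of P such matrices (lag 1
#'   first); all entries must be finite.
#' @param lambda N x N symmetric positive-definite innovation precision;
#'   defaults to the identity.
#' @return Object of class `vbconn_var`: list with `coeffs` (list of P
#'   matrices), `lambda`, `N`, `P`.
#' @export
var_params <- function(coeffs, lambda = NULL) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  if (!is.list(coeffs) || length(coeffs) < 1L)
    stop("'coeffs' must be a matrix or a non-empty list of matrices")
  N <- nrow(coeffs[[1]])
  for (A in coeffs) {
    if (!is.matrix(A) || nrow(A) != N || ncol(A) != N)
      stop("all coefficient matrices must be square with matching size")
    if (any(!is.finite(A))) stop("coefficient matrices must be finite")
  }
  if (is.null(lambda)) lambda <- diag(N)
  if (!isTRUE(all.equal(lambda, t(lambda))))
    stop("'lambda' must be symmetric")
  ok <- tryCatch({ chol(lambda); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'lambda' must be positive definite")
  structure(list(coeffs = coeffs, lambda = lambda, N = N,
                 P = length(coeffs)),
            class = "vbconn_var")
}

# N x NP matrix [A^(1) ... A^(P)] from a coefficient list
.stack_coeffs <- function(coeffs) do.call(cbind, coeffs)

# split an N x NP stacked matrix back into a list of P matrices
.unstack_coeffs <- function(A_top, P) {
  N <- nrow(A_top)
  lapply(seq_len(P), function(p) A_top[, (p - 1) * N + seq_len(N), drop = FALSE])
}

#' First-order companion (embedding) form of a VAR(P) model
#'
#' Rewrites the order-P model as `x(t) = A_tilde x(t-1) + eta_tilde(t)` on
#' the stacked state `x(t) = [s(t); s(t-1); ...; s(t-P+1)]`. The top N rows
#' of `A_tilde` hold `[A^(1) ... A^(P)]`, the subdiagonal holds identity
#' blocks, and the innovation covariance `Q` is zero except for its top-left
#' N x N block, which equals `Lambda^-1`.
#'
#' @param params A `vbconn_var` model.
#' @return Object of class `vbconn_companion`: list with `A_tilde` (PN x PN),
#'   `Q` (PN x PN), `N`, `P`.
#' @export
build_companion <- function(params) {
  stopifnot(inherits(params, "vbconn_var"))
  N <- params$N; P <- params$P; PN <- P * N
  A_tilde <- matrix(0, PN, PN)
  A_tilde[seq_len(N), ] <- .stack_coeffs(params$coeffs)
  if (P > 1)
    A_tilde[cbind(N + seq_len((P - 1) * N), seq_len((P - 1) * N))] <- 1
  Q <- matrix(0, PN, PN)
  Q[seq_len(N), seq_len(N)] <- chol2inv(chol(params$lambda))
  structure(list(A_tilde = A_tilde, Q = Q, N = N, P = P),
            class = "vbconn_companion")
}

#' Spectral radius of a VAR model's companion matrix
#'
#' The largest eigenvalue modulus of the companion transition matrix; the
#' process is (covariance) stationary iff this is below 1.
#'
#' @param x A `vbconn_var` or `vbconn_companion` object.
#' @return Nonnegative scalar.
#' @export
spectral_radius <- function(x) {
  if (inherits(x, "vbconn_var")) x <- build_companion(x)
  stopifnot(inherits(x, "vbconn_companion"))
  max(Mod(eigen(x$A_tilde, only.values = TRUE)$values))
}

#' Simulate a VAR(P) process
#'
#' Generates `s(t) = sum_p A^(p) s(t-p) + eta(t)` with Gaussian innovations
#' `N(0, Lambda^-1)`, zero initial condition `s(t) = 0` for `t <= 0`, and a
#' discarded burn-in to remove the transient. Unstable models (spectral
#' radius >= 0.999, a guard against near-unit-root blowup in long
#' high-rate simulations) are refused unless `force = TRUE`. Uses the
#' session RNG.
#'
#' @param params A `vbconn_var` model.
#' @param n_time Number of retained time points T (>= 1).
#' @param burn_in Number of initial samples discarded (default 1000).
#' @param force Simulate even if the model is unstable (with a warning).
#' @param innovations Optional `(n_time + burn_in) x N` matrix of innovation
#'   draws to use instead of fresh Gaussian draws (for matched-stream
#'   comparisons); must already have covariance `Lambda^-1`.
#' @return A `n_time x N` matrix, rows are time points.
#' @export
simulate_var <- function(params, n_time, burn_in = 1000, force = FALSE,
                         innovations = NULL) {
  stopifnot(inherits(params, "vbconn_var"))
  if (n_time < 1) stop("'n_time' must be >= 1")
  sr <- spectral_radius(params)
  if (sr >= 0.999) {
    if (!force)
      stop(sprintf("model is unstable (spectral radius %.4f >= 0.999); %s",
                   sr, "use force = TRUE to simulate anyway"))
    warning(sprintf("simulating unstable model (spectral radius %.4f)", sr))
  }
  N <- params$N; P <- params$P
  n <- n_time + burn_in
  if (is.null(innovations)) {
    sigma <- chol2inv(chol(params$lambda))
    E <- matrix(stats::rnorm(n * N), n, N) %*% chol(sigma)
  } else {
    if (!is.matrix(innovations) || nrow(innovations) != n ||
        ncol(innovations) != N)
      stop("'innovations' must be a (n_time + burn_in) x N matrix")
    E <- innovations
  }
  A_top <- .stack_coeffs(params$coeffs)
  S <- matrix(0, n, N)
  xstack <- numeric(P * N)   # [s(t-1); ...; s(t-P)]
  for (t in seq_len(n)) {
    s_t <- drop(A_top %*% xstack) + E[t, ]
    S[t, ] <- s_t
    if (P > 1) xstack <- c(s_t, xstack[seq_len((P - 1) * N)])
    else xstack <- s_t
  }
  S[burn_in + seq_len(n_time), , drop = FALSE]
}

#' @export
print.vbconn_var <- function(x, ...) {
  cat(sprintf("VAR(%d) model on %d regions; spectral radius %.3f\n",
              x$P, x$N, spectral_radius(x)))
  invisible(x)
}
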