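# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths: dense joint-Gaussian conditioning
# for the smoother, explicit circulant/Kronecker assembly for the
# transform-domain and CG updates, and exhaustive pair counting for the AUC.

# full companion matrix from its top block
companion_full <- function(A_top) {
  N <- nrow(A_top); PN <- ncol(A_top)
  At <- matrix(0, PN, PN)
  At[seq_len(N), ] <- A_top
  if (PN > N) At[cbind(N + seq_len(PN - N), seq_len(PN - N))] <- 1
  At
}

# smoothed moments by conditioning the exact joint Gaussian of
# x(0..T), z(1..T) on z; x0 ~ N(0, I), innovations N(0, blkdiag(Q_top, 0)),
# observations z(t) = x(t)[1:N] + N(0, theta^-1 I)
dense_smoother_oracle <- function(A_top, Q_top, Z, theta) {
  N <- nrow(A_top); PN <- ncol(A_top); Tn <- nrow(Z)
  At <- companion_full(A_top)
  Q <- matrix(0, PN, PN); Q[1:N, 1:N] <- Q_top
  D <- (Tn + 1) * PN
  V <- matrix(0, D, D)
  blk <- function(t) (t * PN) + seq_len(PN)  # t = 0..Tn
  V[blk(0), blk(0)] <- diag(PN)
  for (t in seq_len(Tn)) {
    V[blk(t), blk(t)] <- At %*% V[blk(t - 1), blk(t - 1)] %*% t(At) + Q
    for (s in 0:(t - 1)) {
      V[blk(t), blk(s)] <- At %*% V[blk(t - 1), blk(s)]
      V[blk(s), blk(t)] <- t(V[blk(t), blk(s)])
    }
  }
  Bsel <- matrix(0, Tn * N, D)
  for (t in seq_len(Tn)) Bsel[(t - 1) * N + seq_len(N), blk(t)[1:N]] <- diag(N)
  Szz <- Bsel %*% V %*% t(Bsel) + diag(1 / theta, Tn * N)
  Sxz <- V %*% t(Bsel)
  K <- Sxz %*% solve(Szz)
  mu <- K %*% as.numeric(t(Z))
  Sig <- V - K %*% t(Sxz)
  list(mean = matrix(mu, ncol = PN, byrow = TRUE), cov = Sig, blk = blk)
}

# explicit circulant matrix whose first column is `col`
circulant <- function(col) {
  n <- length(col)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) ((i - j) %% n) + 1)
  matrix(col[idx], n, n)
}

# characteristic-polynomial coefficients by Faddeev-LeVerrier (for an
# eigenvalue oracle independent of eigen())
char_poly <- function(A) {
  n <- nrow(A)
  cf <- numeric(n + 1); cf[1] <- 1
  M <- diag(n)
  for (k in seq_len(n)) {
    M <- A %*% M
    cf[k + 1] <- -sum(diag(M)) / k
    M <- M + diag(cf[k + 1], n)
  }
  cf
}

# a stable random VAR for tests (redraws until the radius is comfortable)
stable_var <- function(N, P, sd = 0.25, max_radius = 0.9) {
  repeat {
    coeffs <- lapply(seq_len(P), function(p) matrix(rnorm(N * N, sd = sd), N, N))
    pars <- var_params(coeffs)
    if (spectral_radius(pars) < max_radius) return(pars)
  }
}

# an impulse ("identity") HRF kernel on a given grid
impulse_hrf <- function(dt, L = 5L) {
  structure(list(samples = c(1, rep(0, L - 1)), dt = dt, L = as.integer(L),
                 peak_time = 0, undershoot_time = NA_real_),
            class = "vbconn_hrf")
}
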