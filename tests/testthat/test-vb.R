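test_that("proxy update reaches its stated limits", {
  set.seed(61)
  y <- rnorm(40)
  x <- rnorm(40)
  imp <- impulse_hrf(1)
  # identity kernel, enormous noise precision: mean follows the data
  pr <- update_neuronal_proxy(y, imp, beta_mean = 1e12, theta = 1, x_mean = x)
  expect_equal(pr$mean, y, tolerance = 1e-8)
  # enormous proxy precision: mean follows the prior pull
  pr2 <- update_neuronal_proxy(y, canonical_hrf(1), beta_mean = 1,
                               theta = 1e12, x_mean = x)
  expect_equal(pr2$mean, x, tolerance = 1e-8)
})

test_that("transform-domain proxy equals the dense circulant solve", {
  set.seed(62)
  Tn <- 64
  k <- structure(list(samples = rnorm(8), dt = 1, L = 8L, peak_time = NA,
                      undershoot_time = NA), class = "vbconn_hrf")
  y <- rnorm(Tn); x <- rnorm(Tn)
  beta <- 2.3; theta <- 1.7
  pr <- update_neuronal_proxy(y, k, beta, theta, x)
  n <- pr$n_pad
  Hc <- circulant(c(k$samples, rep(0, n - 8)))
  M <- beta * crossprod(Hc) + theta * diag(n)
  zd <- solve(M, beta * crossprod(Hc, c(y, rep(0, n - Tn))) +
                 theta * c(x, rep(0, n - Tn)))
  expect_lt(max(abs(pr$mean - zd[1:Tn])) / max(abs(zd[1:Tn])), 1e-8)
  # stored first row matches the dense inverse's first row
  expect_equal(pr$cov_first_row, solve(M)[, 1], tolerance = 1e-8)
})

test_that("CG coefficient solve equals the dense posterior solve", {
  set.seed(63)
  N <- 3; P <- 2; PN <- N * P
  S00 <- crossprod(matrix(rnorm(PN * (PN + 4)), PN + 4, PN))
  S10 <- matrix(rnorm(N * PN), N, PN)
  lam <- crossprod(matrix(rnorm(N * N), N)) + diag(N)
  gam <- matrix(rexp(N * N) + 0.3, N, N)
  up <- update_var_coefficients(S00, S10, lam, gam, P, tol = 1e-12)
  # dense assembly: (S00 kron lam + Diag(I_P kron vec(gam))) a = vec(lam S10)
  Prec <- kronecker(S00, lam) + diag(rep(as.numeric(gam), P))
  a_dense <- solve(Prec, as.numeric(lam %*% S10))
  expect_lt(max(abs(as.numeric(up$mean) - a_dense)) / max(abs(a_dense)), 1e-6)
  # variance approximation is the reciprocal posterior-precision diagonal
  expect_equal(as.numeric(up$var), 1 / diag(Prec), tolerance = 1e-10)
})

test_that("scalar coefficient update matches the closed form", {
  S00 <- matrix(4.2); S10 <- matrix(1.1)
  lam <- matrix(0.8); gam <- matrix(2.5)
  up <- update_var_coefficients(S00, S10, lam, gam, P = 1, tol = 1e-12)
  expect_equal(drop(up$mean), 0.8 * 1.1 / (0.8 * 4.2 + 2.5), tolerance = 1e-10)
})

test_that("overwhelming ARD precision shrinks the coefficients to zero", {
  set.seed(64)
  S00 <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  S10 <- matrix(rnorm(18), 3, 6)
  up <- update_var_coefficients(S00, S10, diag(3),
                                matrix(1e12, 3, 3), P = 2)
  expect_lt(max(abs(up$mean)), 1e-9)
})

test_that("innovation-precision posterior has the stated parameters", {
  # nu = T + nu0
  w <- update_innovation_precision(diag(2), matrix(0, 2, 2), diag(2),
                                   matrix(0, 2, 2), n_time = 500, nu0 = 1)
  expect_identical(w$nu, 501)
  # zero expected residuals: W reduces to the prior scale
  w0 <- update_innovation_precision(matrix(0, 2, 2), matrix(0, 2, 2),
                                    matrix(0, 2, 2), matrix(0, 2, 2),
                                    n_time = 10, nu0 = 1, w0 = 1e-3)
  expect_equal(w0$W, diag(1e-3, 2), tolerance = 1e-12)
})

test_that("expected residual moments match brute-force summation", {
  set.seed(65)
  N <- 2; P <- 1; Tn <- 10
  A <- matrix(rnorm(4, sd = 0.4), 2, 2)
  M <- matrix(rnorm((Tn + 1) * N), Tn + 1, N)        # smoothed means t=0..T
  covs <- lapply(1:(Tn + 1), function(i) crossprod(matrix(rnorm(4), 2)))
  cross <- lapply(1:Tn, function(i) matrix(rnorm(4), 2, 2))
  # term-by-term evaluation of the residual moment sum
  P2_ref <- matrix(0, 2, 2)
  for (t in 1:Tn) {
    mu_t <- M[t + 1, ]; mu_tm1 <- M[t, ]
    P2_ref <- P2_ref +
      (mu_t - A %*% mu_tm1) %*% t(mu_t - A %*% mu_tm1) -
      cross[[t]] %*% t(A) - A %*% t(cross[[t]]) +
      covs[[t + 1]] + A %*% covs[[t]] %*% t(A)
  }
  # the update consumes the aggregated sufficient statistics
  S00 <- crossprod(M[1:Tn, , drop = FALSE]) + Reduce(`+`, covs[1:Tn])
  S10 <- crossprod(M[2:(Tn + 1), , drop = FALSE], M[1:Tn, , drop = FALSE]) +
    Reduce(`+`, cross)
  S11 <- crossprod(M[2:(Tn + 1), , drop = FALSE]) +
    Reduce(`+`, covs[2:(Tn + 1)])
  w <- update_innovation_precision(S00, S10, S11, A, n_time = Tn)
  expect_equal(w$P2, (P2_ref + t(P2_ref)) / 2, tolerance = 1e-10)
})

test_that("ARD update follows the stated shape and inverse scale", {
  # shape is P/2
  up <- update_ard(matrix(0.1, 2, 4), matrix(0.01, 2, 4), P = 2)
  expect_identical(up$shape, 1)
  # hand example: P = 2, means (0.3, 0.1), variances (0.01, 0.01)
  A <- matrix(0, 1, 2); A[1, 1] <- 0.3; A[1, 2] <- 0.1
  V <- matrix(0.01, 1, 2)
  up <- update_ard(A, V, P = 2)
  expect_equal(drop(up$rate), 0.06)
  expect_equal(drop(up$mean), 1 / 0.06)
  # a dead coefficient group hits the cap
  up0 <- update_ard(matrix(0, 1, 1), matrix(0, 1, 1), P = 1, cap = 1e12)
  expect_equal(drop(up0$mean), 1e12)
})

test_that("noise-precision posterior has the stated shape and limits", {
  set.seed(66)
  y <- rnorm(500)
  pr <- update_neuronal_proxy(y, canonical_hrf(1), 1, 1)
  up <- update_noise_precision(y, canonical_hrf(1), pr, a0 = 1e9, b0 = 1)
  expect_identical(up$shape, 250 + 1e9)

  # perfect reconstruction with zero posterior variance: rate reduces to b0
  imp <- impulse_hrf(1)
  n <- stats::nextn(500 + 5, 2)
  perfect <- list(mean = y, spectrum = rep(0, n), n_pad = n)
  up0 <- update_noise_precision(y, imp, perfect, a0 = 2, b0 = 3.5)
  expect_equal(up0$rate, 3.5, tolerance = 1e-8)
})

test_that("noise-precision rate matches a dense circulant evaluation", {
  set.seed(67)
  Tn <- 16
  k <- structure(list(samples = rnorm(5), dt = 1, L = 5L, peak_time = NA,
                      undershoot_time = NA), class = "vbconn_hrf")
  y <- rnorm(Tn)
  pr <- update_neuronal_proxy(y, k, beta_mean = 1.4, theta = 0.9,
                              x_mean = rnorm(Tn))
  up <- update_noise_precision(y, k, pr, a0 = 1, b0 = 0.2)
  n <- pr$n_pad
  Hc <- circulant(c(k$samples, rep(0, n - 5)))
  Sz <- circulant(pr$cov_first_row)
  zp <- c(pr$mean, rep(0, n - Tn))
  yp <- c(y, rep(0, n - Tn))
  ref <- 0.5 * (sum(y^2) - 2 * sum(yp * (Hc %*% zp)) +
                drop(t(zp) %*% crossprod(Hc) %*% zp) +
                sum(diag(crossprod(Hc) %*% Sz))) + 0.2
  expect_equal(up$rate, ref, tolerance = 1e-8)
})

test_that("shape parameters are exact for any problem size", {
  for (P in 1:4) expect_identical(update_ard(matrix(0.2, 2, 2 * P),
                                             matrix(0.1, 2, 2 * P), P)$shape,
                                  P / 2)
  for (Tn in c(16, 501)) {
    y <- rnorm(Tn)
    pr <- update_neuronal_proxy(y, impulse_hrf(1), 1, 1)
    expect_identical(update_noise_precision(y, impulse_hrf(1), pr,
                                            a0 = 7, b0 = 1)$shape, Tn / 2 + 7)
    expect_identical(update_innovation_precision(diag(2), matrix(0, 2, 2),
                                                 diag(2), matrix(0, 2, 2),
                                                 n_time = Tn, nu0 = 1)$nu,
                     Tn + 1)
  }
})

test_that("the fit is deterministic and invariant to per-region rescaling", {
  set.seed(68)
  ds <- generate_random_network(N = 3, P = 1, n_time = 150, snr_db = 10,
                                burn_in = 50)
  f1 <- vb_fit(ds$observed, ds$hrfs, P = 1, sigma2 = ds$sigma2)
  f2 <- vb_fit(ds$observed, ds$hrfs, P = 1, sigma2 = ds$sigma2)
  expect_identical(f1$connectivity, f2$connectivity)
  expect_identical(f1$iterations, f2$iterations)

  # joint rescaling of data and noise variance leaves the strengths unchanged
  sc <- c(5, 0.2, 11)
  f3 <- vb_fit(ds$observed %*% diag(sc), ds$hrfs, P = 1,
               sigma2 = ds$sigma2 * sc^2)
  expect_equal(f3$connectivity, f1$connectivity, tolerance = 1e-8)
})

test_that("null data drive all cross-connection strengths toward zero", {
  set.seed(69)
  Tn <- 300
  Y <- sapply(1:3, function(i)
    as.numeric(stats::filter(rnorm(Tn + 100), 0.6, "recursive"))[-(1:100)])
  h <- canonical_hrf(1)
  obs <- add_noise_snr(convolve_hrf(Y, h), 10)
  fit <- vb_fit(obs$series, h, P = 1, sigma2 = obs$sigma2)
  C <- fit$connectivity
  off <- C[row(C) != col(C)]
  # cross strengths collapse far below the self strengths
  expect_lt(max(off), 0.01)
  expect_lt(max(off) / min(diag(C)), 0.02)
})

test_that("ARD precisions of absent connections grow monotonically", {
  set.seed(70)
  n_runs <- 5
  frac_ok <- sapply(1:n_runs, function(r) {
    Tn <- 200
    Y <- sapply(1:2, function(i)
      as.numeric(stats::filter(rnorm(Tn + 50), 0.5, "recursive"))[-(1:50)])
    obs <- add_noise_snr(convolve_hrf(Y, canonical_hrf(1)), 10)
    sc <- sqrt(6 / colMeans(obs$series^2))
    ys <- obs$series %*% diag(sc)
    s2 <- obs$sigma2 * sc^2
    th <- 10 / mean(s2)
    beta <- rep(1 / mean(s2), 2); lam <- diag(2); gam <- matrix(1, 2, 2)
    A <- matrix(0, 2, 2); x_mean <- matrix(0, Tn, 2)
    g_trace <- matrix(NA, 30, 2)
    for (it in 1:30) {
      Z <- sapply(1:2, function(i)
        update_neuronal_proxy(ys[, i], canonical_hrf(1), beta[i], th,
                              x_mean[, i])$mean)
      sm <- kalman_smoother(A, chol2inv(chol(lam)), Z, th)
      x_mean <- sm$x_mean
      up <- update_var_coefficients(sm$S00, sm$S10, lam, gam, 1,
                                    warm_start = A)
      A <- up$mean
      lam <- update_innovation_precision(sm$S00, sm$S10, sm$S11, A,
                                         n_time = Tn)$mean
      gam <- update_ard(A, up$var, 1)$mean
      g_trace[it, ] <- c(gam[1, 2], gam[2, 1])
    }
    last10 <- g_trace[21:30, ]
    mean(apply(last10, 2, function(v) all(diff(v) >= 0)))
  })
  expect_gte(mean(frac_ok), 0.9)
})

test_that("fit input validation", {
  y <- matrix(rnorm(40), 20, 2)
  expect_error(vb_fit(y, canonical_hrf(1), P = 1, sigma2 = -1), "sigma2")
  expect_error(vb_fit(y, canonical_hrf(1), P = 0, sigma2 = 1), "P")
  expect_error(vb_fit(y, canonical_hrf(0.5), P = 1, sigma2 = 1, tr = 1),
               "TR grid")
  expect_error(vb_fit(y, list(canonical_hrf(1)), P = 1, sigma2 = 1),
               "one HRF")
})

test_that("connectivity matrix sums absolute coefficient means across lags", {
  A1 <- matrix(c(0, -0.4, 0, 0), 2, 2)       # a_21 = -0.4
  expect_equal(connectivity_matrix(list(A1))[2, 1], 0.4)
  expect_equal(connectivity_matrix(list(matrix(0, 2, 2))),
               matrix(0, 2, 2))
  A_1 <- matrix(0, 2, 2); A_1[1, 2] <- 0.2
  A_2 <- matrix(0, 2, 2); A_2[1, 2] <- -0.1
  expect_equal(connectivity_matrix(list(A_1, A_2))[1, 2], 0.3)
})
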