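test_that("random networks activate the stated number of unidirectional edges", {
  set.seed(31)
  ds <- generate_random_network(N = 5, P = 2, n_time = 50, burn_in = 10)
  expect_equal(nrow(ds$truth), 3)   # ceiling(5/2)
  # no pair is reciprocal
  keys <- paste(ds$truth[, 1], ds$truth[, 2])
  rev_keys <- paste(ds$truth[, 2], ds$truth[, 1])
  expect_false(any(rev_keys %in% keys))

  ds10 <- generate_random_network(N = 10, P = 2, n_time = 50, burn_in = 10)
  A1 <- ds10$params$coeffs[[1]]; A2 <- ds10$params$coeffs[[2]]
  on_edge <- matrix(FALSE, 10, 10)
  on_edge[cbind(ds10$truth[, 2], ds10$truth[, 1])] <- TRUE
  # every active pair has a coefficient at both lags; everything else is 0
  expect_true(all(A1[on_edge] != 0) && all(A2[on_edge] != 0))
  expect_true(all(A1[!on_edge] == 0) && all(A2[!on_edge] == 0))
  expect_true(all(diag(A1) == 0) && all(diag(A2) == 0))
})

test_that("active coefficients are drawn with the stated variance", {
  set.seed(32)
  draws <- unlist(lapply(1:25, function(i) {
    ds <- generate_random_network(N = 400, P = 2, n_time = 2, burn_in = 2)
    A <- do.call(cbind, ds$params$coeffs)
    A[A != 0]
  }))
  expect_gte(length(draws), 10000)
  expect_equal(var(draws), 0.05, tolerance = 0.05 * 0.05 / 0.05)  # within 5%
  expect_equal(mean(draws), 0, tolerance = 0.01)
})

test_that("mean-square rescaling matches hand evaluation and is idempotent", {
  y <- matrix(1, 10, 3)
  out <- rescale_rms(y, 6)
  expect_equal(out$series, matrix(sqrt(6), 10, 3))
  expect_equal(sum(out$series^2) / 30, 6)

  again <- rescale_rms(out$series, 6)
  expect_equal(again$scale, 1)
  expect_equal(again$series, out$series)

  expect_equal(formals(rescale_rms)$target, 6.0)
  expect_error(rescale_rms(matrix(0, 3, 3)), "zero")
})

test_that("SNR-controlled noise solves the printed relation exactly", {
  set.seed(33)
  y <- matrix(rnorm(400, mean = 5), 100, 4)
  ctr <- sweep(y, 2, colMeans(y))
  psig <- sum(ctr^2) / length(y)

  n0 <- add_noise_snr(y, 0)
  expect_equal(n0$sigma2, psig)
  n10 <- add_noise_snr(y, 10)
  expect_equal(n10$sigma2, psig / 10)

  # empirical SNR of the output tracks the request
  set.seed(34)
  snr_hat <- replicate(20, {
    nz <- add_noise_snr(y, 6)
    10 * log10(psig / mean((nz$series - y)^2))
  })
  expect_equal(mean(snr_hat), 6, tolerance = 0.1 / 6)

  expect_error(add_noise_snr(matrix(2, 5, 2), 0), "zero")
})

test_that("per-region noise puts every region at the stated SNR", {
  set.seed(35)
  y <- cbind(rnorm(4000, sd = 1), rnorm(4000, sd = 20))
  nz <- add_noise_snr(y, 3, per_region = TRUE)
  expect_length(nz$sigma2, 2)
  for (i in 1:2) {
    psig_i <- sum((y[, i] - mean(y[, i]))^2) / nrow(y)
    expect_equal(nz$sigma2[i], psig_i / 10^0.3)
  }
})

test_that("downsampling is pure decimation", {
  y <- matrix(0:9, 10, 1)
  expect_equal(downsample(y, 1), y)
  expect_equal(drop(downsample(y, 3)), c(0, 3, 6))
  expect_equal(nrow(downsample(matrix(0, 240000, 2), 50)), 4800)
  expect_error(downsample(y, 11), "exceeds")
})

test_that("two-node datasets honour the stated simulation settings", {
  set.seed(36)
  ds <- two_node_dataset(delay_ms = 10, tr_s = 0.5, snr_db = 0)
  expect_equal(nrow(ds$neuronal), 240000)         # 240 s at 1 kHz
  expect_equal(nrow(ds$observed), 240000 / 500)   # decimated to TR
  expect_equal(ds$delay_ms, 10L)
  expect_true(ds$strength >= 0.4 && ds$strength <= 0.9)
  expect_equal(ds$truth[1], ds$direction)
  expect_length(ds$sigma2, 2)

  # cross-coefficient magnitudes across many draws stay in [0.4, 0.9]
  set.seed(37)
  st <- replicate(1000, {
    d <- two_node_dataset(delay_ms = 10, tr_s = 0.5, snr_db = 0,
                          duration_s = 2, burn_in = 50)
    d$strength
  })
  expect_true(all(st >= 0.4 & st <= 0.9))
  # and span the interval rather than clustering
  expect_lt(min(st), 0.45)
  expect_gt(max(st), 0.85)
})

test_that("the cross influence sits at the requested lag of the 1 kHz model", {
  # with the self-coupling switched off the source is white and the
  # target's cross-correlation with it peaks exactly at the requested lag
  set.seed(38)
  d <- 25
  ds <- two_node_dataset(delay_ms = d, tr_s = 0.001, snr_db = 20,
                         duration_s = 60, self_coef = 0)
  src <- ds$neuronal[, ds$truth[1]]
  tgt <- ds$neuronal[, ds$truth[2]]
  cc <- stats::ccf(tgt, src, lag.max = 80, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], d)
})

test_that("generation is deterministic given the seed", {
  set.seed(39)
  a <- two_node_dataset(delay_ms = 40, tr_s = 0.25, snr_db = 5,
                        duration_s = 4, burn_in = 100)
  set.seed(39)
  b <- two_node_dataset(delay_ms = 40, tr_s = 0.25, snr_db = 5,
                        duration_s = 4, burn_in = 100)
  expect_identical(a$observed, b$observed)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sigma2, b$sigma2)

  set.seed(40)
  c1 <- generate_random_network(N = 4, P = 1, n_time = 60, snr_db = 0,
                                burn_in = 20)
  set.seed(40)
  c2 <- generate_random_network(N = 4, P = 1, n_time = 60, snr_db = 0,
                                burn_in = 20)
  expect_identical(c1$observed, c2$observed)
})

test_that("output noise variance decreases strictly with SNR", {
  set.seed(41)
  ds <- generate_random_network(N = 4, P = 2, n_time = 200, burn_in = 50)
  v <- sapply(c(-5, 0, 5, 10, 20), function(snr) {
    set.seed(42)
    add_noise_snr(ds$noiseless, snr)$sigma2
  })
  expect_true(all(diff(v) < 0))
})

test_that("two-node input validation", {
  expect_error(two_node_dataset(delay_ms = 0, tr_s = 0.5), "delay")
  expect_error(two_node_dataset(delay_ms = 10, tr_s = 0.0505), "multiple")
  expect_error(two_node_dataset(delay_ms = 5000, tr_s = 0.5, duration_s = 4),
               "duration")
})
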