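test_that("canonical kernel has the conventional peak and undershoot", {
  h1 <- canonical_hrf(dt = 1, duration = 30)
  expect_equal(h1$L, 30L)
  expect_length(h1$samples, 30)
  expect_true(all(is.finite(h1$samples)))
  expect_gt(max(h1$samples), 0)

  hf <- canonical_hrf(dt = 0.05)
  pt <- hrf_peak_times(hf)
  expect_equal(pt$peak, 5, tolerance = 0.05 / 5)
  expect_equal(pt$undershoot, 15.75, tolerance = 0.05 / 15.75)
  # the undershoot is a genuine negative lobe after the positive peak
  expect_lt(min(hf$samples[hf$samples < 0]), 0)
  expect_gt(which.min(hf$samples), which.max(hf$samples))
})

test_that("peak location is grid independent", {
  p1 <- hrf_peak_times(canonical_hrf(0.5))$peak
  p2 <- hrf_peak_times(canonical_hrf(0.25))$peak
  expect_lte(abs(p1 - p2), 0.5)
})

test_that("kernel constructor validates its arguments", {
  expect_error(canonical_hrf(dt = 0), "dt")
  expect_error(canonical_hrf(dt = -1), "dt")
  expect_error(canonical_hrf(dt = 1, duration = 0.5), "duration")
})

test_that("randomized kernels keep peaks and troughs in the stated ranges", {
  set.seed(11)
  dt <- 0.05
  pts <- replicate(1000, {
    k <- random_hrf(dt)
    unlist(hrf_peak_times(k))
  })
  expect_true(all(pts["peak", ] >= 2.5 - dt & pts["peak", ] <= 6.5 + dt))
  expect_true(all(pts["undershoot", ] >= 15 - dt &
                  pts["undershoot", ] <= 16.7 + dt))
})

test_that("randomized peak times are uniform on the stated interval", {
  set.seed(12)
  pk <- replicate(2000, hrf_peak_times(random_hrf(0.05))$peak)
  ks <- suppressWarnings(stats::ks.test(pk, "punif", 2.5, 6.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("a degenerate peak range reproduces the canonical kernel", {
  set.seed(13)
  k <- random_hrf(0.1, peak_range = c(5, 5))
  expect_identical(k$samples, canonical_hrf(0.1)$samples)
})

test_that("convolution is causal, exact against brute force, and linear", {
  # identity kernel passes the input through
  imp <- impulse_hrf(1)
  x <- rnorm(25)
  expect_equal(convolve_hrf(x, imp), x, tolerance = 1e-12)

  # an impulse input reads out the kernel
  h <- canonical_hrf(1)
  u <- numeric(50); u[8] <- 1
  y <- convolve_hrf(u, h)
  expect_equal(y[8:37], h$samples, tolerance = 1e-12)
  expect_equal(y[1:7], rep(0, 7), tolerance = 1e-12)

  # brute-force double-loop evaluation of the causal sum, T = 40, L = 7
  set.seed(14)
  hk <- structure(list(samples = rnorm(7), dt = 1, L = 7L, peak_time = NA,
                       undershoot_time = NA), class = "vbconn_hrf")
  x <- rnorm(40)
  ref <- sapply(seq_len(40), function(t) {
    s <- 0
    for (k in 1:7) if (t - k + 1 >= 1) s <- s + hk$samples[k] * x[t - k + 1]
    s
  })
  expect_equal(convolve_hrf(x, hk), ref, tolerance = 1e-10)

  # linearity
  u <- rnorm(40); v <- rnorm(40)
  expect_equal(convolve_hrf(2 * u - 3 * v, hk),
               2 * convolve_hrf(u, hk) - 3 * convolve_hrf(v, hk),
               tolerance = 1e-10)
})

test_that("convolution equals multiplication by the Toeplitz operator", {
  set.seed(15)
  h <- canonical_hrf(1)
  Tn <- 200
  H <- matrix(0, Tn, Tn)
  for (k in seq_len(h$L)) {
    i <- seq.int(k, Tn)
    H[cbind(i, i - k + 1)] <- h$samples[k]
  }
  x <- rnorm(Tn)
  expect_equal(convolve_hrf(x, h), drop(H %*% x), tolerance = 1e-10)
})

test_that("convolution rejects a sampling-interval mismatch", {
  expect_error(convolve_hrf(rnorm(10), canonical_hrf(1), dt = 2), "match")
})

test_that("kernels round-trip through delimited text", {
  k <- canonical_hrf(0.5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hrf(k, f)
  k2 <- read_hrf(f)
  expect_equal(k2$samples, k$samples)
  expect_equal(k2$dt, k$dt)
})
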