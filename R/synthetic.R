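#' Rescale a multivariate series to a target mean-square amplitude
#'
#' The scale statistic is `sum_t ||y(t)||^2 / (N T)`, i.e. the mean squared
#' amplitude over all samples; the series is multiplied by a single scalar so
#' this statistic equals `target`. The default target of 6.0 is the working
#' scale assumed by the estimator's deterministic hyperparameters; the value
#' itself is arbitrary as long as the hyperparameters match.
#'
#' @param y Numeric matrix, T x N (rows time), not all zero.
#' @param target Target mean-square amplitude (default 6.0).
#' @return List with `series` (rescaled matrix) and `scale` (the applied
#'   multiplicative factor).
#' @export
rescale_rms <- function(y, target = 6.0) {
  y <- as.matrix(y)
  ms <- sum(y^2) / length(y)
  if (ms == 0) stop("cannot rescale an all-zero series")
  sc <- sqrt(target / ms)
  list(series = y * sc, scale = sc)
}

#' Add i.i.d. Gaussian noise at a requested SNR
#'
#' The noise variance solves
#' `SNR_dB = 10 log10( sum_t ||y(t) - ybar||^2 / (N T sigma^2) )`
#' exactly, where `ybar` is the per-region temporal mean of the noiseless
#' series (centering removes the DC offset introduced by HRF convolution).
#' Zero-mean Gaussian noise of that variance is added to every sample. The
#' returned `sigma2` is the quantity handed to the estimator as the known
#' noise level. Uses the session RNG.
#'
#' @param y Noiseless T x N series.
#' @param snr_db Requested signal-to-noise ratio in dB.
#' @param per_region If `FALSE` (default) a single noise variance is set
#'   from the power pooled over regions; if `TRUE` each region receives
#'   noise at `snr_db` relative to its own centered power (appropriate when
#'   the generating process gives regions very different signal scales, as
#'   in the two-node delay study where the downstream region's BOLD
#'   variance exceeds the source's by up to two orders of magnitude).
#' @return List with `series` (noisy matrix) and `sigma2` (noise variance;
#'   length N if `per_region`).
#' @export
add_noise_snr <- function(y, snr_db, per_region = FALSE) {
  y <- as.matrix(y)
  if (any(!is.finite(y))) stop("'y' must be finite")
  ctr <- sweep(y, 2, colMeans(y))
  if (per_region) {
    psig <- colSums(ctr^2) / nrow(y)
    if (any(psig == 0)) stop("a region has zero centered power; SNR undefined")
  } else {
    psig <- sum(ctr^2) / length(y)
    if (psig == 0) stop("signal has zero centered power; SNR undefined")
  }
  sigma2 <- psig / 10^(snr_db / 10)
  noisy <- y + matrix(stats::rnorm(length(y)), nrow(y), ncol(y)) %*%
    diag(sqrt(sigma2), ncol(y))
  list(series = noisy, sigma2 = sigma2)
}

#' Decimate a series in time
#'
#' Pure decimation without anti-alias filtering (deliberately so: the
#' benchmark attributes downsampling effects to aliasing, so no low-pass
#' protection is applied): sample 1, then every k-th sample, truncated to
#' `floor(T / k)` output rows. `k = 1` is the identity.
#'
#' @param y T x N matrix.
#' @param k Positive integer decimation factor, at most T.
#' @return A `floor(T/k) x N` matrix.
#' @export
downsample <- function(y, k) {
  y <- as.matrix(y)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be a positive integer")
  if (k > nrow(y)) stop("decimation factor exceeds series length")
  idx <- seq.int(1L, by = k, length.out = nrow(y) %/% k)
  y[idx, , drop = FALSE]
}

#' Generate a random sparse-network fMRI benchmark dataset
#'
#' Draws a stable sparse VAR(P) network: `ceiling(N/2)` distinct unordered
#' region pairs are activated, each in a single randomly chosen direction
#' (so no pair is ever reciprocal), and for each active directed pair all P
#' lag coefficients are drawn zero-mean Gaussian with variance `coef_var`
#' (default 0.05). The innovation precision is the identity. Networks whose
#' companion spectral radius is not below 0.999 are rejected and redrawn.
#' The neuronal series is simulated, then each region is convolved with
#' `hrf` (canonical, 1 Hz grid, L = 30 by default). If `snr_db` is supplied
#' the noisy observation and its noise variance are filled in; otherwise the
#' dataset is returned pre-noise. Uses the session RNG.
#'
#' @param N Number of regions (>= 2).
#' @param P VAR order of the generating process.
#' @param n_time Number of time points T.
#' @param snr_db Optional SNR in dB for the additive observation noise.
#' @param coef_var Variance of active coefficients.
#' @param n_edges Number of activated directed connections
#'   (default `ceiling(N/2)`).
#' @param hrf `vbconn_hrf` kernel shared by all regions (default canonical
#'   at 1 Hz).
#' @param burn_in Simulation burn-in (see [simulate_var()]).
#' @param max_tries Maximum stability redraws before giving up.
#' @return Object of class `vbconn_dataset`: list with `neuronal` (T x N
#'   ground-truth series), `noiseless` (T x N convolved series), `observed`
#'   (noisy series or NULL), `tr` (sampling interval, s), `hrfs` (list of N
#'   kernels), `truth` (n_edges x 2 matrix, columns source/target),
#'   `params` (`vbconn_var` ground truth), `sigma2`, `snr_db`, `tries`.
#' @export
generate_random_network <- function(N, P = 2, n_time = 500, snr_db = NULL,
                                    coef_var = 0.05,
                                    n_edges = ceiling(N / 2),
                                    hrf = NULL, burn_in = 1000,
                                    max_tries = 1000) {
  if (N < 2) stop("'N' must be at least 2")
  if (P < 1) stop("'P' must be at least 1")
  if (is.null(hrf)) hrf <- canonical_hrf(dt = 1, duration = 30)
  stopifnot(inherits(hrf, "vbconn_hrf"))
  pairs <- t(utils::combn(N, 2))
  if (n_edges > nrow(pairs)) stop("more edges requested than distinct pairs")
  params <- NULL; truth <- NULL
  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("no stable network found in ", max_tries, " draws")
    sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
    flip <- stats::runif(n_edges) < 0.5
    src <- ifelse(flip, sel[, 2], sel[, 1])
    tgt <- ifelse(flip, sel[, 1], sel[, 2])
    coeffs <- lapply(seq_len(P), function(p) {
      A <- matrix(0, N, N)
      A[cbind(tgt, src)] <- stats::rnorm(n_edges, sd = sqrt(coef_var))
      A
    })
    params <- var_params(coeffs, diag(N))
    if (spectral_radius(params) < 0.999) {
      truth <- cbind(source = src, target = tgt)
      break
    }
  }
  neuronal <- simulate_var(params, n_time, burn_in = burn_in)
  noiseless <- convolve_hrf(neuronal, hrf)
  ds <- structure(
    list(neuronal = neuronal, noiseless = noiseless, observed = NULL,
         tr = hrf$dt, hrfs = rep(list(hrf), N), truth = truth,
         params = params, sigma2 = NULL, snr_db = NULL, tries = tries),
    class = "vbconn_dataset"
  )
  if (!is.null(snr_db)) {
    nz <- add_noise_snr(noiseless, snr_db)
    ds$observed <- nz$series
    ds$sigma2 <- nz$sigma2
    ds$snr_db <- snr_db
  }
  ds
}

#' Two-region delay/TR benchmark dataset
#'
#' Simulates the neuronal level at 1 kHz for `duration_s` seconds (240 s,
#' i.e. 240 000 samples, by default): both regions have a lag-1
#' self-coefficient of `self_coef` (0.95), and a single cross connection in
#' a randomly chosen direction sits at lag `d = round(delay_ms)` of the
#' 1 kHz model with magnitude drawn uniformly from `cross_range`
#' (0.4 to 0.9). Innovations are unit-variance i.i.d. Gaussian. Each region
#' is convolved with its HRF at 1 kHz (the same canonical kernel for
#' `hrf_mode = "fixed"`, independent randomized kernels for `"random"`),
#' decimated to the requested repetition time, and observation noise is
#' added at `snr_db`. The returned `hrfs` are the true per-region kernels
#' resampled on the output TR grid, ready to hand to the estimator. Uses
#' the session RNG.
#'
#' @param delay_ms Neuronal delay in milliseconds (>= 1, 1 ms grid).
#' @param tr_s Output sampling interval in seconds (a multiple of 1 ms).
#' @param hrf_mode `"fixed"` (canonical HRF for both regions) or `"random"`
#'   (independent randomized kernels, see [random_hrf()]).
#' @param snr_db SNR of the additive observation noise in dB.
#' @param duration_s Simulated duration in seconds at 1 kHz.
#' @param self_coef Lag-1 self-coefficient of both regions.
#' @param cross_range Uniform bounds for the cross-coefficient magnitude.
#' @param burn_in Discarded 1 kHz samples before the retained window.
#' @return A `vbconn_dataset` (see [generate_random_network()]); `neuronal`
#'   holds the full ground-truth series on the 1 kHz grid, `neuronal_tr`
#'   its decimation to the output grid (comparable to the fitted latent
#'   series), and extra fields `delay_ms`, `strength` and `direction`
#'   (source region index) record the generating connection. `truth` is a
#'   1 x 2 source/target matrix.
#' @export
two_node_dataset <- function(delay_ms, tr_s, hrf_mode = c("fixed", "random"),
                             snr_db = 0, duration_s = 240, self_coef = 0.95,
                             cross_range = c(0.4, 0.9), burn_in = 2000) {
  hrf_mode <- match.arg(hrf_mode)
  d <- as.integer(round(delay_ms))
  if (is.na(d) || d < 1L) stop("'delay_ms' must be >= 1")
  k <- round(tr_s * 1000)
  if (abs(tr_s * 1000 - k) > 1e-6 || k < 1)
    stop("'tr_s' must be a positive multiple of 1 ms")
  n_keep <- as.integer(round(duration_s * 1000))
  if (d >= n_keep) stop("delay exceeds the simulated duration")
  n <- n_keep + burn_in

  src <- sample.int(2L, 1L)
  tgt <- 3L - src
  strength <- stats::runif(1, cross_range[1], cross_range[2])
  E <- matrix(stats::rnorm(2 * n), n, 2)
  s_src <- as.numeric(stats::filter(E[, src], self_coef,
                                    method = "recursive"))
  drive <- E[, tgt]
  drive[(d + 1):n] <- drive[(d + 1):n] + strength * s_src[1:(n - d)]
  s_tgt <- as.numeric(stats::filter(drive, self_coef, method = "recursive"))
  S <- matrix(0, n, 2)
  S[, src] <- s_src
  S[, tgt] <- s_tgt
  S <- S[burn_in + seq_len(n_keep), , drop = FALSE]

  peaks <- if (hrf_mode == "fixed") c(5, 5) else stats::runif(2, 2.5, 6.5)
  hrf_1k <- lapply(peaks, function(pk) hrf_kernel(0.001, 30, peak_time = pk))
  bold <- vapply(1:2, function(i) .conv_causal(S[, i], hrf_1k[[i]]$samples),
                 numeric(n_keep))
  obs <- downsample(bold, k)
  # the coupling chain gives the downstream region a far larger BOLD
  # variance than the source; noise is therefore set per region so both
  # regions sit at the stated SNR
  nz <- add_noise_snr(obs, snr_db, per_region = TRUE)

  structure(
    list(neuronal = S, neuronal_tr = downsample(S, k), noiseless = obs,
         observed = nz$series, tr = tr_s,
         hrfs = lapply(peaks, function(pk)
           hrf_kernel(tr_s, 30, peak_time = pk)),
         truth = cbind(source = src, target = tgt),
         params = NULL, sigma2 = nz$sigma2, snr_db = snr_db,
         delay_ms = d, strength = strength, direction = src,
         hrf_mode = hrf_mode),
    class = "vbconn_dataset"
  )
}

#' @export
print.vbconn_dataset <- function(x, ...) {
  Tn <- nrow(if (!is.null(x$observed)) x$observed else x$noiseless)
  N <- ncol(x$noiseless)
  cat(sprintf("Synthetic fMRI dataset: %d regions x %d samples at TR = %g s\n",
              N, Tn, x$tr))
  cat(sprintf("  true connections: %d; noise: %s\n", nrow(x$truth),
              if (is.null(x$sigma2)) "none (pre-noise)"
              else sprintf("sigma^2 = %.4g (SNR %g dB)", x$sigma2, x$snr_db)))
  invisible(x)
}
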