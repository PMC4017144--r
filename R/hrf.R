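#' Construct a double-gamma hemodynamic response function kernel
#'
#' The BOLD impulse response is modelled as the difference of two gamma
#' density shapes (unit rate): a positive response lobe followed by a smaller
#' negative undershoot. The response-delay parameter is expressed directly as
#' the time of the positive peak: a gamma density with shape `peak_time + 1`
#' and rate 1 has its mode at `peak_time` seconds, and the undershoot lobe is
#' too small near the peak to shift it on any practical grid. The undershoot
#' lobe has shape `undershoot_time` (mode at `undershoot_time - 1` s) and is
#' scaled down by `undershoot_ratio` (6:1 by convention). The kernel is
#' normalized so its samples sum to one (unit DC gain, the convention of the
#' standard SPM generator). The normalization is irrelevant for simulation
#' (noise is SNR-relative), but it matters for estimation: unit DC gain puts
#' the deconvolved neuronal series on the same scale as the RMS-rescaled
#' observation, which is the scale the estimator's fixed prior
#' hyperparameters assume.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param duration Total kernel support in seconds; the kernel has
#'   `L = round(duration / dt)` samples at times `0, dt, ..., (L-1) dt`.
#' @param peak_time Time of the positive peak in seconds.
#' @param undershoot_time Undershoot delay parameter in seconds (gamma shape
#'   of the negative lobe); held at 16 for randomized kernels.
#' @param undershoot_ratio Peak-to-undershoot amplitude ratio.
#' @return An object of class `vbconn_hrf`: a list with elements `samples`
#'   (length `L`), `dt`, `L`, `peak_time`, `undershoot_time`.
#' @seealso [canonical_hrf()], [random_hrf()], [convolve_hrf()]
#' @export
hrf_kernel <- function(dt, duration = 30, peak_time = 5,
                       undershoot_time = 16, undershoot_ratio = 6) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive number")
  if (!is.numeric(duration) || length(duration) != 1L || duration < dt)
    stop("'duration' must be >= dt")
  if (peak_time <= 0 || undershoot_time <= 0)
    stop("peak and undershoot times must be positive")
  L <- as.integer(round(duration / dt))
  tt <- (seq_len(L) - 1) * dt
  h <- stats::dgamma(tt, shape = peak_time + 1, rate = 1) -
    stats::dgamma(tt, shape = undershoot_time, rate = 1) / undershoot_ratio
  h <- h / sum(h)
  structure(
    list(samples = h, dt = dt, L = L,
         peak_time = peak_time, undershoot_time = undershoot_time),
    class = "vbconn_hrf"
  )
}

#' Canonical hemodynamic response function
#'
#' Double-gamma kernel with the conventional canonical shape: positive peak
#' at 5 s, negative undershoot trough at 15.75 s, 30 s support.
#'
#' @inheritParams hrf_kernel
#' @return A `vbconn_hrf` kernel.
#' @examples
#' h <- canonical_hrf(dt = 1)
#' h$L                 # 30 samples at 1 Hz
#' hrf_peak_times(h)
#' @export
canonical_hrf <- function(dt, duration = 30) {
  hrf_kernel(dt = dt, duration = duration, peak_time = 5,
             undershoot_time = 16)
}

#' Randomized hemodynamic response function
#'
#' Draws the time-to-peak uniformly on `peak_range` (default 2.5 to 6.5 s,
#' the span of empirically reported peak positions across brain regions) and
#' holds the undershoot delay parameter at 16 s, so the resulting trough
#' falls between roughly 15 and 16.7 s depending on the drawn peak. Uses the
#' session RNG; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams hrf_kernel
#' @param peak_range Numeric length-2, bounds of the uniform time-to-peak
#'   draw in seconds. A degenerate range `c(5, 5)` reproduces the canonical
#'   kernel sample-for-sample.
#' @return A `vbconn_hrf` kernel whose `peak_time` records the drawn value.
#' @export
random_hrf <- function(dt, duration = 30, peak_range = c(2.5, 6.5)) {
  if (length(peak_range) != 2L || any(!is.finite(peak_range)) ||
      peak_range[1] > peak_range[2] || peak_range[1] <= 0)
    stop("'peak_range' must be positive and ordered")
  pk <- stats::runif(1, peak_range[1], peak_range[2])
  hrf_kernel(dt = dt, duration = duration, peak_time = pk,
             undershoot_time = 16)
}

#' Measure peak and trough times of a sampled kernel
#'
#' Locates the global maximum and the post-peak minimum on the sampling grid.
#'
#' @param kernel A `vbconn_hrf` kernel.
#' @return List with `peak` and `undershoot` times in seconds (grid-resolved).
#' @export
hrf_peak_times <- function(kernel) {
  stopifnot(inherits(kernel, "vbconn_hrf"))
  h <- kernel$samples
  ip <- which.max(h)
  if (ip >= length(h))
    return(list(peak = (ip - 1) * kernel$dt, undershoot = NA_real_))
  iu <- ip + which.min(h[(ip + 1):length(h)])
  list(peak = (ip - 1) * kernel$dt, undershoot = (iu - 1) * kernel$dt)
}

# causal linear convolution, zero-padded FFT; returns first length(x) samples
.conv_causal <- function(x, h) {
  Tn <- length(x)
  n <- stats::nextn(Tn + length(h) - 1L, 2)
  xf <- stats::fft(c(x, rep(0, n - Tn)))
  hf <- stats::fft(c(h, rep(0, n - length(h))))
  Re(stats::fft(xf * hf, inverse = TRUE))[seq_len(Tn)] / n
}

#' Convolve a time series with an HRF kernel
#'
#' Causal convolution `y(t) = sum_{k=1}^{L} h(k) x(t - k + 1)` with samples
#' outside the series treated as zero; `h(1)` multiplies the current sample.
#' Equivalent to multiplication by the T x T lower-triangular Toeplitz matrix
#' of the kernel. Computed by zero-padded FFT.
#'
#' @param x Numeric vector (length T) or matrix (T x N, one column per
#'   region); rows are time points.
#' @param kernel A `vbconn_hrf` kernel on the same sampling grid as `x`.
#' @param dt Optional sampling interval of `x`; if supplied it must match
#'   `kernel$dt`.
#' @return Object of the same shape as `x`.
#' @export
convolve_hrf <- function(x, kernel, dt = NULL) {
  stopifnot(inherits(kernel, "vbconn_hrf"))
  if (!is.null(dt) && !isTRUE(all.equal(dt, kernel$dt)))
    stop("kernel sampling interval (", kernel$dt,
         " s) does not match the series interval (", dt, " s)")
  if (is.matrix(x)) {
    out <- apply(x, 2, .conv_causal, h = kernel$samples)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  .conv_causal(as.numeric(x), kernel$samples)
}

#' Write an HRF kernel as two-column delimited text
#'
#' Columns are `time_s` and `amplitude`, tab-separated, full precision.
#'
#' @param kernel A `vbconn_hrf` kernel.
#' @param path Output file path.
#' @export
write_hrf <- function(kernel, path) {
  stopifnot(inherits(kernel, "vbconn_hrf"))
  tt <- (seq_len(kernel$L) - 1) * kernel$dt
  df <- data.frame(time_s = sprintf("%.17g", tt),
                   amplitude = sprintf("%.17g", kernel$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an HRF kernel from two-column delimited text
#'
#' Inverse of [write_hrf()]. `dt` is inferred from the time column; the
#' recorded peak/undershoot times are measured from the samples.
#'
#' @param path Input file path.
#' @return A `vbconn_hrf` kernel.
#' @export
read_hrf <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stop("expected columns 'time_s' and 'amplitude' in ", path)
  tt <- df$time_s
  if (length(tt) < 2) stop("kernel file must contain at least two samples")
  dt <- tt[2] - tt[1]
  k <- structure(
    list(samples = df$amplitude, dt = dt, L = length(tt),
         peak_time = NA_real_, undershoot_time = NA_real_),
    class = "vbconn_hrf"
  )
  pt <- hrf_peak_times(k)
  k$peak_time <- pt$peak
  k$undershoot_time <- pt$undershoot
  k
}

#' @export
print.vbconn_hrf <- function(x, ...) {
  pt <- hrf_peak_times(x)
  cat(sprintf(
    "HRF kernel: L = %d samples at dt = %g s (%.3g s support)\n",
    x$L, x$dt, x$L * x$dt))
  cat(sprintf("  peak at %.3g s, undershoot trough at %.3g s\n",
              pt$peak, pt$undershoot))
  invisible(x)
}
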