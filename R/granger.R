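# Conditional Wiener-Granger causality by multivariate least squares. The
# magnitude for j -> i is the log ratio of region i's residual variance when
# region j's past is excluded from the full VAR(P) over all regions, versus
# included. All reduced models reuse the full normal equations (submatrix
# solves), so the cost is one Gram matrix plus N Cholesky solves.

# lagged design matrix: rows t = P+1..T, column block p holds y(t-p, )
.lag_design <- function(y, P) {
  Tn <- nrow(y); N <- ncol(y)
  idx <- (P + 1):Tn
  X <- matrix(0, length(idx), N * P)
  for (p in seq_len(P))
    X[, (p - 1) * N + seq_len(N)] <- y[idx - p, , drop = FALSE]
  list(X = X, Y = y[idx, , drop = FALSE])
}

# residual sums of squares of each response column under the least-squares
# fit restricted to design columns `cols`
.rss_subset <- function(G, XtY, yy, cols) {
  ch <- tryCatch(chol(G[cols, cols, drop = FALSE]), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  B <- backsolve(ch, forwardsolve(t(ch), XtY[cols, , drop = FALSE]))
  yy - colSums(XtY[cols, , drop = FALSE] * B)
}

#' Conditional Granger causality magnitudes
#'
#' For each ordered pair (j -> i), the magnitude is
#' `ln( var(e_i | all regions except j) / var(e_i | all regions) )` where
#' the residual variances come from least-squares VAR(P) fits conditioned on
#' every other region; negative values (possible only through numerical
#' noise, since the models are nested) are floored at zero. Each region is
#' demeaned before fitting. Raw magnitudes are intended to be consumed
#' directly by ROC/direction metrics, without significance thresholding.
#'
#' @param y T x N series (rows time).
#' @param P VAR order of the fits.
#' @param floor_negative Floor negative log-ratios at 0 (default TRUE).
#' @return List of class `vbconn_granger` with `gc` (N x N matrix, rows
#'   target / columns source, zero diagonal) and `order`.
#' @export
conditional_granger <- function(y, P, floor_negative = TRUE) {
  y <- as.matrix(y)
  Tn <- nrow(y); N <- ncol(y)
  if (P < 1) stop("'P' must be >= 1")
  if (Tn - P <= N * P)
    stop("series too short for a VAR(", P, ") fit on ", N, " regions")
  y <- sweep(y, 2, colMeans(y))
  ld <- .lag_design(y, P)
  G <- crossprod(ld$X)
  XtY <- crossprod(ld$X, ld$Y)
  yy <- colSums(ld$Y^2)
  all_cols <- seq_len(N * P)
  rss_full <- .rss_subset(G, XtY, yy, all_cols)
  if (is.null(rss_full))
    stop("rank-deficient regressor matrix for the full model (all regions)")
  gc <- matrix(0, N, N)
  for (j in seq_len(N)) {
    keep <- setdiff(all_cols, j + N * (seq_len(P) - 1))
    rss_red <- .rss_subset(G, XtY, yy, keep)
    if (is.null(rss_red))
      stop("rank-deficient regressor matrix when excluding region ", j)
    val <- log(rss_red / rss_full)
    val[j] <- 0
    gc[, j] <- val
  }
  if (floor_negative) gc[gc < 0] <- 0
  structure(list(gc = gc, order = P), class = "vbconn_granger")
}

#' VAR order selection by BIC
#'
#' Fits the full multivariate VAR by least squares for each order in
#' `1..max_order` on the common sample (rows `max_order+1..T`, so all
#' candidate orders are scored on the same observations) and returns the
#' order minimizing `T_eff log det(Sigma_hat) + p N^2 log(T_eff)`, the
#' Gaussian BIC with the full innovation covariance determinant. Regions are
#' demeaned first.
#'
#' @param y T x N series.
#' @param max_order Largest candidate order (default 20).
#' @return The selected order (integer).
#' @export
select_order_bic <- function(y, max_order = 20) {
  y <- as.matrix(y)
  Tn <- nrow(y); N <- ncol(y)
  if (max_order < 1) stop("'max_order' must be >= 1")
  if (Tn - max_order <= N * max_order)
    stop("series too short to score order ", max_order)
  y <- sweep(y, 2, colMeans(y))
  ld <- .lag_design(y, max_order)
  Teff <- nrow(ld$X)
  G <- crossprod(ld$X)
  XtY <- crossprod(ld$X, ld$Y)
  bic <- numeric(max_order)
  for (p in seq_len(max_order)) {
    cols <- seq_len(N * p)
    ch <- chol(G[cols, cols, drop = FALSE])
    B <- backsolve(ch, forwardsolve(t(ch), XtY[cols, , drop = FALSE]))
    E <- ld$Y - ld$X[, cols, drop = FALSE] %*% B
    sig <- crossprod(E) / Teff
    bic[p] <- Teff * determinant(sig, logarithm = TRUE)$modulus +
      p * N^2 * log(Teff)
  }
  which.min(bic)
}

#' @export
print.vbconn_granger <- function(x, ...) {
  cat(sprintf("Conditional Granger causality, order %d, %d regions\n",
              x$order, nrow(x$gc)))
  off <- x$gc[row(x$gc) != col(x$gc)]
  cat(sprintf("  off-diagonal magnitudes: max %.4g, median %.4g\n",
              max(off), stats::median(off)))
  invisible(x)
}
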