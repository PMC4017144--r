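# Evaluation metrics for estimated connectivity against a known ground
# truth: undirected ROC/AUC over region pairs, direction accuracy
# (d-accuracy) over true connections, and energy-normalized MSE for latent
# signal recovery.

# undirected pair scores and labels from a score matrix and a directed or
# undirected truth edge set
.pair_scores <- function(C, truth) {
  N <- nrow(C)
  if (!is.matrix(C) || ncol(C) != N) stop("'C' must be a square matrix")
  truth <- as.matrix(truth)
  if (nrow(truth) > 0 &&
      (any(truth < 1) || any(truth > N) || any(truth[, 1] == truth[, 2])))
    stop("truth pairs must be distinct region indices within 1..N")
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  scores <- pmax(C[pairs], t(C)[pairs])  # con(i,j) = max(c_ij, c_ji)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  labels <- key(pairs[, 1], pairs[, 2]) %in% key(truth[, 1], truth[, 2])
  list(scores = scores, labels = labels)
}

#' Undirected ROC AUC of a connectivity matrix
#'
#' Each distinct region pair is scored by the larger of its two directed
#' strengths, `con(i,j) = max(c_ij, c_ji)`, the diagonal is excluded, and
#' the ROC curve is swept over all distinct score thresholds. The AUC is
#' computed by the rank (Mann-Whitney) formulation, which equals trapezoidal
#' integration of that curve with midrank tie handling; 1.0 is perfect
#' detection and 0.5 the level of a random detector.
#'
#' @param C N x N nonnegative score matrix (rows target, columns source).
#' @param truth Two-column matrix of true connections (source, target);
#'   interpreted undirected. There must be at least one true and one absent
#'   pair.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(C, truth) {
  ps <- .pair_scores(C, truth)
  n_pos <- sum(ps$labels)
  n_neg <- sum(!ps$labels)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: truth has no ", if (n_pos == 0) "positive"
         else "negative", " pairs")
  r <- rank(ps$scores)
  (sum(r[ps$labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points of a connectivity matrix
#'
#' True/false positive counts and rates for every threshold in the observed
#' undirected scores (plus sentinels), matching [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return `data.frame` with columns `threshold`, `tp`, `fp`, `tpr`, `fpr`,
#'   ordered from the strictest threshold (no detections) to the laxest.
#' @export
roc_curve <- function(C, truth) {
  ps <- .pair_scores(C, truth)
  n_pos <- sum(ps$labels)
  n_neg <- sum(!ps$labels)
  if (n_pos == 0 || n_neg == 0) stop("ROC undefined without both classes")
  th <- c(Inf, sort(unique(ps$scores), decreasing = TRUE), -Inf)
  tp <- vapply(th, function(s) sum(ps$scores >= s & ps$labels), numeric(1))
  fp <- vapply(th, function(s) sum(ps$scores >= s & !ps$labels), numeric(1))
  data.frame(threshold = th, tp = tp, fp = fp,
             tpr = tp / n_pos, fpr = fp / n_neg)
}

#' Direction accuracy (d-accuracy)
#'
#' For each true connection j -> i, the direction counts as correct when
#' `c_ij > c_ji` (the estimated strength is larger in the true direction);
#' exact ties earn half credit. The score is the fraction of true
#' connections directed correctly: 1.0 is perfect, 0.5 the level of a random
#' direction detector, and 0 a systematic inversion.
#'
#' @param C N x N score matrix (rows target, columns source).
#' @param truth Two-column matrix of true directed connections
#'   (source, target); each true connection must be strictly unidirectional.
#' @return d-accuracy in `[0, 1]`.
#' @export
d_accuracy <- function(C, truth) {
  truth <- as.matrix(truth)
  if (nrow(truth) == 0) stop("d-accuracy undefined for an empty truth set")
  N <- nrow(C)
  if (any(truth < 1) || any(truth > N) || any(truth[, 1] == truth[, 2]))
    stop("truth pairs must be distinct region indices within 1..N")
  key <- paste(truth[, 1], truth[, 2])
  if (any(paste(truth[, 2], truth[, 1]) %in% key))
    stop("truth contains a reciprocal connection; directions are ambiguous")
  fwd <- C[cbind(truth[, 2], truth[, 1])]   # c_ij, true direction j -> i
  rev <- C[cbind(truth[, 1], truth[, 2])]   # c_ji
  mean(ifelse(fwd > rev, 1, ifelse(fwd == rev, 0.5, 0)))
}

#' Energy-normalized mean squared error of a signal estimate
#'
#' `sum_t ||s(t) - s_est(t)||^2 / sum_t ||s(t)||^2`: 0 for a perfect
#' estimate, 1 for an all-zero estimate.
#'
#' @param s_true,s_est T x N matrices of matching shape; `s_true` must have
#'   nonzero energy.
#' @return Nonnegative scalar.
#' @export
nmse <- function(s_true, s_est) {
  s_true <- as.matrix(s_true); s_est <- as.matrix(s_est)
  if (!all(dim(s_true) == dim(s_est))) stop("shapes must match")
  energy <- sum(s_true^2)
  if (energy == 0) stop("true signal has zero energy")
  sum((s_true - s_est)^2) / energy
}

#' Evaluate a connectivity estimate against a directed ground truth
#'
#' Convenience wrapper returning the undirected AUC and the d-accuracy.
#'
#' @inheritParams d_accuracy
#' @return List with `auc` and `d_accuracy`.
#' @export
evaluate_connectivity <- function(C, truth) {
  list(auc = roc_auc(C, truth), d_accuracy = d_accuracy(C, truth))
}
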