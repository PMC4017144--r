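# Seeded benchmark sweeps over the synthetic generators: random sparse
# networks (network size x SNR x generating/fitted VAR order) and the
# two-node TR x delay grid under fixed or randomized HRFs. Every cell is
# replicated with seeds base_seed + replicate index, so results do not
# depend on execution order.

.mean_ci <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n == 0) return(c(mean = NA_real_, ci = NA_real_, n = 0))
  ci <- if (n > 1) 1.96 * stats::sd(v) / sqrt(n) else 0
  c(mean = mean(v), ci = ci, n = n)
}

# run one method on a completed dataset and score it against the truth
.score_method <- function(method, ds, P_fit, vb_ctrl, bic_max_order) {
  C <- if (method == "vb") {
    fit <- vb_fit(ds$observed, ds$hrfs, P = P_fit, sigma2 = ds$sigma2,
                  control = vb_ctrl)
    fit$connectivity
  } else if (method == "granger") {
    conditional_granger(ds$observed, P = P_fit)$gc
  } else if (grepl("^granger_[0-9]+$", method)) {
    conditional_granger(ds$observed,
                        P = as.integer(sub("granger_", "", method)))$gc
  } else if (method == "granger_bic") {
    ord <- select_order_bic(ds$observed, max_order = bic_max_order)
    conditional_granger(ds$observed, P = ord)$gc
  } else stop("unknown method: ", method)
  list(auc = tryCatch(roc_auc(C, ds$truth), error = function(e) NA_real_),
       d_accuracy = d_accuracy(C, ds$truth))
}

#' Random-network benchmark sweep
#'
#' For every combination of network size, SNR, generating order and fitted
#' order, draws `replications` independent random sparse networks (a fresh
#' network per replicate, seeded `base_seed + replicate`), runs each method,
#' and aggregates the undirected AUC and d-accuracy as the replicate mean
#' with a normal-approximation 95% confidence half-width.
#'
#' @param N Vector of network sizes.
#' @param snr_db Vector of SNRs in dB.
#' @param P_data Vector of generating VAR orders.
#' @param P_fit Vector of orders assumed by the methods (`NULL`: same as
#'   `P_data`).
#' @param n_time Time points per series.
#' @param replications Replicates per cell.
#' @param base_seed Seed offset; replicate r uses `base_seed + r`.
#' @param methods Character vector: `"vb"`, `"granger"`.
#' @param vb_control Settings for [vb_fit()].
#' @return `data.frame` with one row per cell x method: the factors plus
#'   `auc`, `auc_ci`, `d_accuracy`, `d_accuracy_ci`, `n_ok`.
#' @export
run_network_sweep <- function(N = c(5, 10, 25), snr_db = c(0, 5, 10),
                              P_data = 2, P_fit = NULL, n_time = 500,
                              replications = 10, base_seed = 1,
                              methods = c("vb", "granger"),
                              vb_control = vbconn::vb_control()) {
  grid <- expand.grid(N = N, snr_db = snr_db, P_data = P_data,
                      P_fit = if (is.null(P_fit)) NA else P_fit)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    pf <- if (is.na(grid$P_fit[g])) grid$P_data[g] else grid$P_fit[g]
    res <- array(NA_real_, c(replications, length(methods), 2))
    for (r in seq_len(replications)) {
      set.seed(base_seed + r)
      ds <- tryCatch(
        generate_random_network(N = grid$N[g], P = grid$P_data[g],
                                n_time = n_time, snr_db = grid$snr_db[g]),
        error = function(e) NULL)
      if (is.null(ds)) next
      for (m in seq_along(methods)) {
        sc <- tryCatch(
          .score_method(methods[m], ds, pf, vb_control, 20),
          error = function(e) NULL)
        if (!is.null(sc)) res[r, m, ] <- c(sc$auc, sc$d_accuracy)
      }
    }
    for (m in seq_along(methods)) {
      a <- .mean_ci(res[, m, 1]); d <- .mean_ci(res[, m, 2])
      out[[length(out) + 1]] <- data.frame(
        N = grid$N[g], snr_db = grid$snr_db[g], P_data = grid$P_data[g],
        P_fit = pf, method = methods[m],
        auc = a["mean"], auc_ci = a["ci"],
        d_accuracy = d["mean"], d_accuracy_ci = d["ci"],
        n_ok = as.integer(a["n"]), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Two-node TR/delay benchmark sweep
#'
#' For every (TR, delay) cell, draws `replications` two-node datasets
#' (seeded `base_seed + replicate`) and scores the direction accuracy of
#' each method. The full-scale grids are 40 linear TR steps on 0.05-2 s
#' by 40 linear delay steps on 5-300 ms with 50 replicates (see
#' [tr_delay_grid()]); the defaults here are desk-scale.
#'
#' @param tr_s Vector of repetition times in seconds.
#' @param delay_ms Vector of neuronal delays in milliseconds.
#' @param hrf_mode `"fixed"` or `"random"` (see [two_node_dataset()]).
#' @param snr_db SNR in dB.
#' @param replications Replicates per cell.
#' @param base_seed Seed offset; replicate r uses `base_seed + r`.
#' @param methods Character vector among `"vb"` (order `vb_order`, true
#'   HRFs supplied), `"granger_<k>"` (fixed order k), `"granger_bic"`
#'   (order selected on 1..`bic_max_order`).
#' @param vb_order VAR order assumed by the variational method.
#' @param bic_max_order Search bound for `"granger_bic"`.
#' @param vb_control Settings for [vb_fit()].
#' @return `data.frame` with one row per cell x method: `tr_s`, `delay_ms`,
#'   `method`, `d_accuracy`, `d_accuracy_ci`, `n_ok`.
#' @export
run_two_node_sweep <- function(tr_s = c(0.15, 0.5), delay_ms = c(50, 100),
                               hrf_mode = "fixed", snr_db = 0,
                               replications = 10, base_seed = 1,
                               methods = c("vb", "granger_1"),
                               vb_order = 1, bic_max_order = 20,
                               vb_control = vbconn::vb_control()) {
  grid <- expand.grid(tr_s = tr_s, delay_ms = delay_ms)
  out <- list()
  for (g in seq_len(nrow(grid))) {
    res <- matrix(NA_real_, replications, length(methods))
    for (r in seq_len(replications)) {
      set.seed(base_seed + r)
      ds <- tryCatch(
        two_node_dataset(delay_ms = grid$delay_ms[g], tr_s = grid$tr_s[g],
                         hrf_mode = hrf_mode, snr_db = snr_db),
        error = function(e) NULL)
      if (is.null(ds)) next
      for (m in seq_along(methods)) {
        sc <- tryCatch(
          .score_method(methods[m], ds, vb_order, vb_control,
                        bic_max_order),
          error = function(e) NULL)
        if (!is.null(sc)) res[r, m] <- sc$d_accuracy
      }
    }
    for (m in seq_along(methods)) {
      d <- .mean_ci(res[, m])
      out[[length(out) + 1]] <- data.frame(
        tr_s = grid$tr_s[g], delay_ms = grid$delay_ms[g],
        method = methods[m], d_accuracy = d["mean"],
        d_accuracy_ci = d["ci"], n_ok = as.integer(d["n"]),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Full-scale TR/delay grid of the two-node study
#'
#' 40 linear TR steps between 0.05 and 2 s crossed with 40 linear delay
#' steps between 5 and 300 ms: 1600 cells. Delays are rounded to the 1 ms
#' simulation grid by the generator.
#'
#' @return List with `tr_s` (length 40) and `delay_ms` (length 40).
#' @export
tr_delay_grid <- function() {
  list(tr_s = seq(0.05, 2, length.out = 40),
       delay_ms = seq(5, 300, length.out = 40))
}
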