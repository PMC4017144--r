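# vbconn — variational Bayes effective connectivity for fMRI

`vbconn` estimates directed (effective) connectivity between brain regions
from fMRI time series. The BOLD signal is an indirect, heavily low-passed
view of neuronal activity: each region's series is modelled as a causal
convolution of a latent neuronal signal with a hemodynamic response
function (HRF), plus Gaussian noise. Regressing observed series on each
other — as Wiener–Granger causality does — is confounded by that blur and
by the scanner's coarse sampling. `vbconn` instead infers connectivity at
the latent level.

## The model

Neuronal activity follows a latent VAR(P):

    s(t) = Σ_p A^(p) s(t−p) + η(t),        η(t) ~ N(0, Λ⁻¹)
    y_i(t) = Σ_k h_i(k) z_i(t−k+1) + ε_i(t)

where `z` is a precision-ϑ proxy of the stacked state (the trick that keeps
the state dimension at `PN` rather than `N·L` and lets the deconvolution
run per region in the Fourier domain), `h_i` is region *i*'s HRF, and each
connection's coefficients share one automatic-relevance-determination
precision across lags, so irrelevant connections are pruned as a group —
the Bayesian analogue of a group-lasso penalty. All factors (state sequence,
proxies, coefficients, innovation precision, ARD and noise precisions) are
updated by mean-field coordinate ascent: a variational Kalman smoother for
the state, FFT-based circulant updates for the deconvolution, and a
conjugate-gradient solve for the coefficient posterior. The reported
strength of the connection j → i is `c_ij = Σ_p |⟨a_ij^(p)⟩|` (rows index
the target region).

The package also ships the synthetic benchmark around the method: random
sparse-network generators, a two-node neuronal-delay/TR sweep with fixed or
randomized HRFs, a conditional Granger-causality baseline with fixed or
BIC-selected order, and ROC-AUC / direction-accuracy metrics. See the
methods vignette (`vignettes/connectivity-methods.Rmd`) for the full model,
parameter calibration, and benchmark design.

## Worked example

```r
library(vbconn)
set.seed(3)
ds <- generate_random_network(N = 5, P = 2, n_time = 500, snr_db = 10)
fit <- vb_fit(ds$observed, ds$hrfs, P = 2, sigma2 = ds$sigma2)
round(fit$connectivity, 3)
#>       [,1]  [,2]  [,3]  [,4]  [,5]
#> [1,] 2.431 0.000 0.000 0.001 0.000
#> [2,] 0.000 2.447 0.000 0.000 0.001
#> [3,] 0.000 0.007 2.392 0.000 0.000
#> [4,] 0.000 0.000 0.000 2.455 0.000
#> [5,] 0.000 0.000 0.000 0.000 2.451
ds$truth
#>      source target
#> [1,]      2      3
#> [2,]      5      2
#> [3,]      5      1
evaluate_connectivity(fit$connectivity, ds$truth)
#> $auc          0.905
#> $d_accuracy   1.000
```

The largest off-diagonal entries sit where the generator placed
connections: `c[3,2]` is the 2 → 3 edge and `c[2,5]` the 5 → 2 edge (rows
are targets, columns sources; the diagonal carries self-dynamics and is
excluded from evaluation). The undirected AUC over all 10 region pairs is
0.905 and every detected connection points in the true direction. The
Granger baseline on the same data:

```r
g <- conditional_granger(ds$observed, P = 2)
roc_auc(g$gc, ds$truth)
#> 0.952
```

At small network sizes the two approaches are comparable; the variational
method's advantage appears at large `N` (its group-sparse prior regularizes
where unpenalized least squares overfits) and at low SNR.

A thin command-line wrapper over these functions is installed at
`inst/cli/vbconn.R` with `simulate`, `fit`, `granger` and `evaluate`
subcommands.

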