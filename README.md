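# bndd: Bayesian Nonparametric Discontinuity Design

Quasi-experimental designs — regression discontinuity (RD), interrupted
time series (ITS), and geographic-boundary designs — draw causal
conclusions from a known assignment threshold instead of randomization.
Most implementations share two weaknesses: they *condition on the alleged
effect* (estimating the jump as if a discontinuity were certain, which
overstates both the effect and the confidence in it), and they rely on
simple parametric regressions that are easily misspecified.

`bndd` addresses both with Gaussian process (GP) regression and Bayesian
model comparison. It is aimed at applied statisticians and
epidemiologists analysing threshold-assigned interventions (policy
cutoffs, clinical thresholds, interruptions of a monitored time series,
spatial boundaries).

## The model

Observations are `y_i = f(x_i) + ε_i`, `ε_i ~ N(0, σ_n²)`, with a known
threshold `x0` splitting the data into a pre (control) and post
(treated) side (`x ≥ x0` is treated). Two models are compared:

- **M0 (continuous):** a single GP `f ~ GP(μ, k(x, x'; θ0))` over all
  data — the intervention did nothing.
- **M1 (discontinuous):** the latent processes on the two sides are
  independent: `k1(x, x'; θ1) = k(x, x'; θ1)` if `x, x'` are on the same
  side and `0` otherwise, so the Gram matrix is block-diagonal.

Hyperparameters are optimized by maximum marginal likelihood and the
model evidence is approximated by the BIC form
`log p(D | M) ≈ log p(y | x, θ̂, M) − (l/2) log n`, with `l` the number
of optimized hyperparameters. Evidence is compared through the log Bayes
factor `log BF10 = log p(D|M1) − log p(D|M0)`; positive values favour a
discontinuity, and — unlike a p-value — negative values are evidence
*for* continuity.

Conditional on M1, the RD effect is Gaussian, `d | D, M1 ~ N(m, s²)`,
with `m` the difference of the two one-sided posterior means at `x0` and
`s² = 2σ_n²` for stationary kernels. Averaging over the model posterior
gives the *spike-and-slab* distribution

```
p(d | D) = p(M0 | D) · δ(0) + p(M1 | D) · N(m, s²),
```

whose point summary `E[d | D] = p(M1 | D) · m` shrinks weak effects
toward zero. For ITS the effect is a curve
`m(x) = f_post(x) − f_pre(x)` on `x ≥ x0` (the pre fit extrapolated),
summarized by `max |m(x)|`; for a geographic boundary it is a curve
along the boundary polyline.

The covariance function is a design choice that selects the *kind* of
discontinuity being tested: `constant` (difference in means — a
quasi-experimental t-test), `linear` (mean and slope), `exp` (jumps in
the function only), `matern32` (jumps up to the first derivative),
`rbf` (any order), and `sm`, a spectral mixture kernel whose spectral
density is a Gaussian mixture — suited to quasi-periodic series and
extrapolation, and initialized from the Lomb–Scargle periodogram (valid
for unevenly sampled data). When several kernels are candidates, their
evidences are averaged (uniform prior) into a single decision metric
`log BF10_total`, and the effect distribution is marginalized over
kernels as well.

## Worked example

A regression discontinuity with a true jump of `d = 4` at `x0 = 0` under
noise σ = 1:

```r
library(bndd)
data <- generate_rd_dataset("linear", d = 4, sigma = 1, n = 100, seed = 42)
cfg <- analysis_config("rd", threshold = 0,
                       kernels = c("linear", "exp", "matern32", "rbf"),
                       n_restarts = 10, seed = 1)
res <- run_analysis(cfg, data)
print(res)
#> Discontinuity analysis (mode: rd )
#>      name log_ev_m0 log_ev_m1 log_bf10
#>    linear -182.5740 -151.7398 30.83417
#>       exp -161.7663 -149.4754 12.29091
#>  matern32 -162.0159 -149.8542 12.16163
#>       rbf -163.1178 -150.0387 13.07917
#> total log BF10: 12.44
#> model posterior: p(M0|D) = 3.97e-06 , p(M1|D) = 1
#> effect ( exp  kernel): summary = 4.375
#> BMA effect mean: 4.185 , spike mass: 0
```

Every kernel individually reports decisive evidence for a discontinuity
(`log BF10 ≫ 3`), the kernel-averaged total is 12.4 nats, the posterior
probability of the continuous model is negligible, and the
model-averaged effect estimate 4.19 is close to the true jump of 4 (the
spike mass — the fraction of model-averaged draws equal to exactly
zero — is 0 because M0 has essentially no posterior mass). With `d = 0`
data the same pipeline typically reports a *negative* total log Bayes
factor and a spike mass near 1.

`run_analysis` writes a JSON report (set `out =` in the config); the
same pipeline is scriptable via `inst/exec/bndd` (`bndd analyze`,
`bndd simulate`). Simulation benchmark runners for both designs are
exposed as `run_rd_benchmark()` (per-kernel and model-averaged effect
errors, Bayes factors, two-stage GP p-values) and `run_its_benchmark()`
(spectral-mixture extrapolation RMSE against a BIC-selected ARMA
baseline).

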