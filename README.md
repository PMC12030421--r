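# riceAssim

Bayesian recalibration of rice crop-management parameters — sowing date,
seeding rate and fertilizer nitrogen amount — by assimilating NDVI-derived
canopy observations into a crop growth model with a random-walk
Metropolis–Hastings (MCMC) sampler, then predicting yield with quantified
uncertainty.

**Who it is for.** Agronomists and crop-modelling researchers who have
per-stage canopy sensor readings (GreenSeeker-style NDVI, inverted to leaf
area index LAI and plant nitrogen accumulation PNA through exponential
regressions) and want to (a) recover the management inputs that best
explain them, (b) predict LAI/PNA/yield with credible uncertainty bands,
and (c) quantify how much the assimilation improves on direct spectral
inversion, which saturates over dense canopies (NDVI stops responding
beyond roughly LAI 6–7 and PNA 90 kg/ha).

## The method

With a uniform prior over box bounds on
θ = (sowing date, seeding rate, N amount), the likelihood at the observed
stages t = 1..T is

    log π_p(θ) = −(1/σ₁²) Σ_t (O₁(t) − S₁(t))² − (1/σ₂²) Σ_t (O₂(t) − S₂(t))²

where O₁/O₂ are NDVI-derived LAI/PNA, S₁/S₂ their simulated counterparts,
and σ₁/σ₂ scalar measurement SDs pooled from replicates.  Proposals step
each component by r·(max−min)/D with r ~ U[−1, 1] and D = 5, reflected at
the bounds (symmetric kernel, so the acceptance probability is
a_p = min{1, exp Δlog π_p}, accepting when a_p ≥ U).  Chains run N = 10000
iterations; 2000 are discarded as burn-in and the remaining 8000 give
posterior means, variances and credible intervals.  Posterior-predictive
ensembles (crop model re-run at every 20th retained sample) give per-stage
LAI/PNA and yield predictions with RMSD — the root-mean-square dispersion
of the ensemble — as the uncertainty measure.

Because the original crop simulator is an external executable, the package
ships a small deterministic surrogate rice model (GDD phenology, logistic
canopy growth with a nitrogen-saturating ceiling, pool-limited N uptake,
radiation-driven yield with an N plateau above ~210 kg/ha) behind a
pluggable likelihood interface, plus a seeded generator of complete
synthetic experiments (5 N rates × 3 replicates, saturating forward NDVI,
replicate noise).  See the methods vignette
(`vignettes/mcmc-crop-assimilation.Rmd`) for the model, its assumptions and
known limitations.

## Worked example

```r
library(riceAssim)

ex <- make_experiment(seed = 7)           # synthetic 5-rate N trial
ex$truth_treatment                        # true management parameters
#>   treatment n_rate sowing_doy seeding_rate
#> 1        N0      0      147.8        62.10
#> 2        N1     70      146.2        57.99
#> 3        N2    140      149.8        64.15
#> 4        N3    210      148.9        62.58
#> 5        N4    280      146.9        61.39

fit <- run_assimilation(ex$observations$N3, ex$weather, seed = 7)
fit
#> assimilation_fit
#>   chain: 10000 iterations, burn-in 2000, acceptance rate 0.11, seed 7
#>   recalibrated parameters (posterior means):
#>     sowing doy 147.49, seeding rate 66.29 kg/ha, N amount 156.9 kg/ha
#>   predicted yield 7311 kg/ha (RMSD 149, ensemble of 400)

fit$posterior
#> mh_posterior: 8000 retained samples (burn-in 2000), 95% credible intervals
#>      parameter   mean     var     sd  lower  upper
#> 1   sowing_doy 147.49   5.271  2.296 143.09 152.13
#> 2 seeding_rate  66.29 158.320 12.583  42.41  87.87
#> 3     n_amount 156.93 788.352 28.078 114.63 225.27
```

The recalibrated sowing date lands within 1.4 days of truth and the seeding
rate within 6%; the N amount is recovered to the right order but
underestimated (157 vs 210 kg/ha) because this plot's flowering
observations sit in the NDVI-saturated regime — exactly the bias the
comparison below measures.  Against the truth trajectory, the assimilated
estimates beat the direct spectral inversion on both state variables:

```r
truth <- extract_at_stages(ex$trajectories$N3)
compare_methods(truth,
                data.frame(lai = ex$observations$N3$o1, pna = ex$observations$N3$o2),
                data.frame(lai = fit$predictive$lai_mean, pna = fit$predictive$pna_mean))
#> method_comparison (reference vs spectral / assimilation):
#>  variable       method     r2   rmse
#>       lai     spectral 0.9872 0.4046
#>       lai assimilation 0.9961 0.3560
#>       pna     spectral 0.9973 5.3885
#>       pna assimilation 0.9990 5.1088
#>   lai: assimilation wins
#>   pna: assimilation wins
```

A command-line front end over the same pipeline (subcommands `synth`,
`calibrate`, `assimilate`, `evaluate`) is installed at
`system.file("cli", "riceassim.R", package = "riceAssim")`.

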