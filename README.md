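# ebprob

Logistic-regression surrogate models for the probability that a cardiac
myocyte fires an ectopic beat.

## Background

In ventricular myocytes, spontaneous calcium release from an overloaded
sarcoplasmic reticulum (SR) can depolarize the membrane after a beat — a
delayed afterdepolarization (DAD). When a DAD reaches the action-potential
threshold it triggers an ectopic beat (EB), a cellular-level arrhythmia
precursor. Whether a given realization of a stochastic myocyte model produces
an EB is a random event whose probability, P(EB), depends on a handful of
myocyte model inputs (MMIs): the initial cytosolic and SR calcium
concentrations and the scaling factors on the inward-rectifier potassium
conductance (G_K1) and the ryanodine-receptor opening rate (k_RyR).

Estimating P(EB) by brute force is expensive: each point in MMI space needs
many stochastic simulations. This package implements the surrogate-model
alternative: treat batches of simulations as binomial counts, fit a binomial
logistic regression on min-max-scaled MMIs with quadratic features, and use
the fitted closed form for prediction, sensitivity ranking, domain analysis,
and uncertainty propagation at negligible cost.

The surrogate is

    P(EB) = logistic(w0 + w · x),

where `x` holds the MMIs scaled to [0, 1] over a biophysically plausible
region of interest (ROI) plus selected squares and pairwise products, and
the weights are fitted by iteratively reweighted least squares on per-set
event counts (k events out of n realizations).

## What the package provides

- **Feature engine** — MMI spaces with ROI bounds, min-max scaling
  (extrapolating, never clipping), and quadratic feature expansion
  (`mmi_space()`, `scale_mmi()`, `feature_spec()`, `expand_features()`).
- **Model core** — binomial logistic fitting with convergence and
  complete-separation diagnostics, prediction, weight-based feature ranking,
  sub-models, and validation metrics (`fit_lrm()`, `predict_probability()`,
  `rank_features()`, `submodel()`, `validate_lrm()`).
- **Adaptive sampling pipeline** — the two-iteration design: uniform ROI
  sampling and a linear-only fit, then rejection sampling concentrated in the
  predicted transition domain, pooling, and exhaustive quadratic-feature
  selection by consistent AIC (`run_two_iteration_pipeline()`,
  `sample_transition()`, `select_feature_set()`).
- **Domain analysis** — transition/plateau classification and
  one-dimensional model characteristic curves (`classify_domain()`,
  `mc_curve()`).
- **Uncertainty propagation** — Monte Carlo propagation of normal input
  uncertainty to a P(EB) distribution with entropy and modality summaries,
  and the analytic logit-normal distribution when a single uncertain MMI
  enters only linearly (`propagate_mc()`, `analytic_distribution()`,
  `mean_p_vs_sigma()`).
- **Toy myocyte simulator** — a seedable stochastic event generator with a
  known probability surface and DAD/EB-like voltage traces, used as ground
  truth for end-to-end pipeline validation (`toy_model_config()`,
  `simulate_batches()`).
- **Replication and I/O** — reconstruction of a published 10-feature
  ectopic-beat model from its printed weights, re-evaluation of the published
  scenario probabilities, and CSV/JSON persistence plus a command-line tool
  (`table1_model()`, `replicate_scenarios()`, `write_lrm()`,
  `inst/scripts/ebprob`).

## Worked example

Reconstruct the published model and evaluate it:

```r
library(ebprob)

m <- table1_model()
m
#> Logistic surrogate model (reconstructed), 10 features over 4 MMIs
#>   intercept: -44.0101
#>             feature weight   se
#>           ca_sr_ini  71.27 3.81
#>            k_ryr_sf  44.37 2.56
#>         ca_sr_ini^2 -24.41 2.13
#>  ca_sr_ini*k_ryr_sf -15.36 2.76
#>          k_ryr_sf^2 -13.45 1.14
#>            ca_i_ini  12.77 0.53
#>             g_k1_sf  -7.98 0.62
#>           g_k1_sf^2  -3.62 0.49
#>          ca_i_ini^2  -2.68 0.46
#>    g_k1_sf*k_ryr_sf  -2.48 0.54

# P(EB) at a published MMI set (printed value: 0.02)
predict_probability(m, c(ca_i_ini = 150, ca_sr_ini = 500,
                         g_k1_sf = 0.638, k_ryr_sf = 1))
#> [1] 0.02133301
```

Propagate heart-failure G_K1 uncertainty (printed moments: 0.8788 ± 0.1183):

```r
us <- uncertainty_spec(
  c(ca_i_ini = 150, ca_sr_ini = 550, g_k1_sf = 0.51, k_ryr_sf = 1),
  c(g_k1_sf = 0.0852))
propagate_mc(m, us, n_samples = 1e6, seed = 42)
#> P(event) distribution (1000000 MC samples), 100 bins
#>   mean 0.8769, sd 0.1194, entropy 3.465 nats, unimodal
```

Run the full two-iteration pipeline against the toy simulator, whose true
probability surface is the reconstructed model, and validate on fresh sets:

```r
sim <- toy_model_config()
run <- run_two_iteration_pipeline(pipeline_config(seed = 7), sim)
test_pts <- sample_roi(run$config$space, 50, seed = 8)
validate_lrm(run$model, simulate_batches(sim, test_pts, n = 100, seed = 9))
#> Surrogate validation on 50 MMI sets ( 14 in transition domain)
#>   mean |error|: 0.003632 +/- 0.008158
#>   R^2 (all): 0.9997  R^2 (transition): 0.9992
```

## Command-line tool

`inst/scripts/ebprob` wraps the main workflows:

```sh
Rscript inst/scripts/ebprob simulate --sets 100 --n 100 --seed 1 --out obs.csv
Rscript inst/scripts/ebprob fit --obs obs.csv --select --out model.json
Rscript inst/scripts/ebprob pipeline --seed 1 --out-dir run/
Rscript inst/scripts/ebprob predict --point ca_i_ini=150,ca_sr_ini=500,g_k1_sf=0.638,k_ryr_sf=1
Rscript inst/scripts/ebprob mc-curve --axis ca_sr_ini --point ca_i_ini=150,g_k1_sf=0.338,k_ryr_sf=1 --out curve.csv
Rscript inst/scripts/ebprob uncertainty --point ca_i_ini=150,ca_sr_ini=550,g_k1_sf=0.51,k_ryr_sf=1 --sigma g_k1_sf=0.0852 --seed 1 --out dist.csv
Rscript inst/scripts/ebprob replicate-paper --seed 1
```

Every randomized command takes `--seed` and logs an auto-generated seed when
none is given.

## Documentation

Methods, modeling assumptions, numerical choices, and known limitations are
described in the vignette source at `vignettes/surrogate-methods.Rmd` and in
the roxygen comments above each exported function in `R/`.

## License

MIT (see `LICENSE`).
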