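# helisteps

Single-molecule stepping analysis for hairpin-unwinding helicases.

## The problem

In a constant-force optical-tweezers hairpin assay, a helicase (the model
system here is a monomeric SF1 helicase such as UvrD) unwinds a DNA hairpin
stem; every base pair unwound releases two nucleotides of ssDNA, which
increases the tether extension. Recorded at 100–267 Hz, the position signal
(in bp unwound) is a noisy staircase: dwells separated by discrete steps.
The scientific questions are (i) how large the steps are and whether the
step size is a fundamental constant or a variable quantity, (ii) how many
catalytic (ATP-binding) events occur per step, and (iii) whether the
observed statistics are consistent with a *delayed strand release*
mechanism, in which the motor unwinds 1 bp per ATP but sequesters the two
nascent strands as loops and releases them only every few cycles, in bursts
of 1–4 nt per strand.

`helisteps` implements that entire analysis chain as reusable, tested R
functions, together with a kinetic Monte-Carlo generator that embodies the
delayed-release looping mechanism, so every stage can be validated against
ground truth without instrument data.

## What is in the box

| Stage | Functions |
|---|---|
| Synthetic traces (kinetic MC, ground-truth event logs) | `generator_config()`, `simulate_trace()`, `make_fixture_set()`, `check_conservation()`, `merge_unresolved_events()` |
| DNA mechanics & hairpin thermodynamics | `polymer_params()`, `xwlc_extension()`, `delta_x_to_bp()`, `ss_stretch_free_energy()`, `hairpin_model()`, `p_open()`, `fec_predict()` |
| Step detection (iterative chi-square with counter-fit) | `detect_steps()`, `dwell_position()`, `dwell_uncertainty()`, `extract_steps()` |
| Step-size statistics | `step_size_kde()`, `bootstrap_kde()`, `kde_periodicity()`, `fit_double_gaussian()`, `pairwise_distance_distribution()`, `covariate_independence()` |
| Dwell-time kinetics | `classify_and_filter_dwells()`, `dwell_vs_step()`, `fit_trendline()`, `n_min()`, `nmin_outlier_scan()`, `speeds()`, `fit_michaelis_menten()` |
| Loop-release model | `release_distribution()`, `step_pmf_from_release()`, `sample_theoretical_steps()`, `release_dist_from_counts()` |
| I/O and orchestration | `read_trace()`/`write_trace()`, `read_steps()`/`write_steps()`, `read_config()`, `run_pipeline()` |

The key statistics, in the field's standard notation:

- Per-dwell position `x*_i` is the mode of a Gaussian KDE (sigma = 0.1 bp)
  of the dwell samples; its standard error is
  `sigma_i = sqrt(<(x - x*_i)^2> / N_i)` with `N_i` the number of
  uncorrelated samples. Steps are `s = x*_{i+1} - x*_i` with
  `sigma_s = sqrt(sigma_i^2 + sigma_{i+1}^2)`; steps under 0.5 bp are
  excluded and their dwells merged.
- The step-size distribution is an error-weighted KDE (one Gaussian kernel
  per step, width `sigma_s`, 0.01-bp grid) with a 10,000-iteration
  bootstrap standard-error band.
- Dwell classes +/+, -/-, +/-, -/+ come from the flanking step signs;
  `n_min = (<t^2>/<t>^2 - 1)^-1` bounds the number of rate-limiting events
  per dwell; speed-vs-ATP curves are fit to
  `v = Vmax [ATP] / (KM + [ATP])`.
- The theoretical step distribution is the convolution of the independent
  3' and 5' release-size pmfs, mapped to bp by halving the released
  nucleotide count — which is why half-integer steps and a 0.5-bp
  periodicity appear whenever an odd total is released.

## Worked example

```r
library(helisteps)

cfg <- generator_config()          # defaults at the measured study conditions
cfg
#> Delayed-release stepping generator
#>   k_cat = 220 /s, k_on = 5.64103 /uM/s  (Vmax = 220 bp/s, KM = 39 uM)
#>   cycles/release pmf on 1..4: 0.05 0.20 0.45 0.30 (mean 3.00)
#>   noise 0.3 bp rms @ 100 Hz, backstep prob 0.08, loop cap 8 nt

sim <- simulate_trace(cfg, atp = 0.5, duration = 25, seed = 42, id = "demo")
sim$events
#> Event log (unwinding): 20 events, 61 catalytic cycles
#>    backstep: 2, release: 18

fit <- detect_steps(sim$trace)
summary(fit)
#> Step fit of 'demo': 22 dwells, 21 raw steps
#>   raw step sizes: mean 2.37 bp (sd 2.12), 19 up / 2 down
#>   dwell durations: median 0.93 s

steps <- extract_steps(fit)        # < 0.5 bp exclusion + dwell merging
mean(steps$s[steps$s > 0])
#> [1] 3.14
```

The trace had 61 catalytic cycles but only 20 observable events — the
hallmark of delayed release — and the detected unwinding steps average
~3 bp even though the motor advances 1 bp per cycle. Pooling many traces
(see `run_pipeline()`) sharpens the estimate toward 3.0 bp and resolves the
0.5-bp periodicity of the step-size KDE.

## Vignette

`vignettes/stepping-analysis.Rmd` documents the generative model and its
assumptions, every tunable parameter with units and defaults, the numerical
choices in the estimators, and what passing the synthetic-data checks does
and does not establish about instrument data.
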