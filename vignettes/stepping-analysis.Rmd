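---
title: "Stepping analysis of hairpin-unwinding helicases: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepping analysis of hairpin-unwinding helicases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helisteps)
```

This vignette is the package's account of the science it implements: the
generative model behind the synthetic traces, the estimators in the
analysis chain, the numerical choices that had to be made where more than
one defensible option existed, and the limits of what the synthetic checks
demonstrate.

## 1. The delayed-release looping model

A non-hexameric helicase held on a DNA hairpin under constant force
unwinds the duplex one base pair per catalytic cycle. In the
delayed-release (strand-sequestration) picture, the two nucleotides of
ssDNA created by each unwinding cycle are not handed to the tether
immediately: they accumulate as loops held by non-canonical protein–DNA
contacts near the motor core, one loop per strand. Only every few cycles
do the contacts rearrange and release a burst of 1–4 nt from each loop.
Because the tether extension reflects *released* ssDNA, the observed
position advances in discrete jumps of $(r_3 + r_5)/2$ base pairs, where
$r_3$ and $r_5$ are the per-strand release sizes. An odd total gives a
half-integer jump — the signature periodicity of 0.5 bp in the step-size
distribution — and the variable number of cycles between releases gives a
broad, roughly 3-bp-mean step-size distribution even though the chemical
step is 1 bp/ATP.

Re-zipping (the motor translocating on the opposing strand while the
duplex reanneals behind it) is modeled as the mirror process: every cycle
re-anneals 1 bp and transfers 1 nt *out of* each loop into the duplex, and
every few cycles the contacts break and several nucleotides of taut ssDNA
are *incorporated* into longer loops, shortening the tether in a discrete
jump.

### The kinetic Monte-Carlo generator

`simulate_trace()` implements this mechanism with the following state per
strand: loop content $L$ (nt), hairpin position $h$ (bp), and the tally of
released nucleotides. Each catalytic cycle draws a waiting time
$\mathrm{Exp}(k_{on}[\mathrm{ATP}]) + \mathrm{Exp}(k_{cat})$ — ATP binding
followed by catalysis — so the mean speed is exactly Michaelis–Menten with
$V_{max} = k_{cat}\cdot 1\,\mathrm{bp}$ and $K_M = k_{cat}/k_{on}$. After
$N_c$ cycles, drawn from the `cycles_per_release` pmf, a release event
draws $r_3, r_5$ independently from the per-strand release distributions.

Defaults, and where they come from:

| Parameter | Default | Rationale |
|---|---|---|
| `k_cat` | 220 /s | measured unwinding $V_{max}$ (re-zipping: 210 /s) |
| `k_on` | 220/39 /µM/s | measured $K_M$ = 39 µM (re-zipping: 35 µM) |
| `cycles_per_release` | (0.05, 0.20, 0.45, 0.30) on 1–4 | mean exactly 3, mode 3 — calibrated to the MD result that ~3-nt releases dominate, with support 1–4 nt |
| `release_3p`, `release_5p` | (0.05, 0.20, 0.45, 0.30) on 1–4 nt | same MD summary, per strand; exact published bar heights were not digitized |
| `loop_cap` | 8 nt/strand | bounds the carry-over random walk (no bound is reported experimentally) |
| `noise_sd` | 0.3 bp rms @ 100 Hz | chosen so that at 0.5 µM ATP ~80% or more of detected steps have $\sigma_s < 0.25$ bp, the reported precision regime |
| `backstep_prob` | 0.08 | backsteps are reported as <10% of steps |
| `burst_mean_bp` | 20 bp | reported burst length at 10 µM ATP |
| `sample_rate` | 100 Hz (267 Hz for 10 µM) | instrument acquisition rates |

Three design points deserve explanation, because the mechanism's verbal
description underdetermines them:

**Truncation and carry-over.** A release draw larger than the current loop
is truncated to the loop content, and the remainder carries over — this is
what decouples $r_3 + r_5$ from $2 N_c$ and produces half-integer steps.
Truncation alone biases releases small, so loops would drift upward
without bound. Instead of emitting a separate "forced release" event when
a loop exceeds the cap (which would break the renewal identity below), the
*scheduled* release is enlarged: $r = \min(L, \max(\mathrm{draw},
L - \mathrm{cap}))$. Every event therefore follows exactly its drawn cycle
count, and the renewal-reward identity — mean observed step (bp) equals
the mean of `cycles_per_release` — holds exactly in steady state (the test
suite verifies it to better than 2% at $10^4$ events). Re-zipping is
mirrored: the incorporation draw is enlarged when the loop would underflow
before the next event and truncated at the cap.

**Backsteps.** Backsteps are implemented as sign-flipped excursions
*outside* the loop bookkeeping: a jump of $-(r_3+r_5)/2$ (during
unwinding) with loops, hairpin position, and the released-nt tally
untouched. Routing them through the loops instead (re-sequestration that
must later be re-released) would inflate the mean of processive steps by
~8% through conservation; treating them as spontaneous events distinct
from processive activity matches how they are interpreted experimentally
and keeps the conservation invariant
$\mathrm{released} = 2\Delta h - (L_3 + L_5)$ exact at every logged event.

**Initial loops.** Unwinding traces start with empty loops — physically,
nothing has been unwound yet — so the first events are slightly
truncation-biased; this transient is part of the mechanism. Re-zipping
traces start with loops at the stationary post-event level (6 nt/strand,
measured from a long simulation), since a re-zipping burst follows prior
unwinding with loaded loops; starting lower would bias short-trace
incorporation sizes upward through the underflow guard.

The generator emulates piecewise-constant latent motion with i.i.d.
Gaussian measurement noise on a uniform grid. It does **not** emulate bead
and trap Brownian dynamics, force-feedback response, correlated (1/f)
instrument noise, drift, hairpin-sequence-dependent unwinding rates, or
dimer-specific kinetics. Consequences for interpretation are in Section 6.

## 2. Step detection

`detect_steps()` is an iterative chi-square step fitter. Starting from one
dwell, it repeatedly inserts the step location that maximally reduces the
residual sum of squares (best split over all current dwells, cached per
segment). The number of steps is chosen by a counter-fit quality ratio:
for each step count $j$, a counter fit segments the trace *only* at the
best split location within each fitted dwell — mid-plateau if the fit is
right — and $S(j) = \chi^2_{counter}/\chi^2_{fit}$ peaks near the true
step count. The accepted count is the smallest $j$ within 1% of the peak
quality (the plateau rule avoids spurious extra steps), and the whole fit
is rejected (zero steps) unless the peak quality reaches the
`sensitivity` threshold.

The threshold default (5) was calibrated on synthetic fixtures: across 100
pure-noise traces (0.3 bp rms) the maximum quality ratio stayed below 1.9,
while staircases with 2–4 bp steps and 30–70-sample dwells scored above
12, so the default separates the two regimes with a wide margin; the test
suite enforces ≤5% false-positive traces and ≥95% transition recovery
within ±2 samples. Dwells shorter than `min_dwell` (3 samples) are never
created, which sets the detector's dead time — at 267 Hz this is 11 ms,
close to the 15 ms short-dwell limit used in the double-step analysis.

Per-dwell quantities follow the standard prescription: the dwell position
$x^*$ is the mode of a Gaussian KDE with 0.1-bp kernels evaluated on a
0.01-bp grid spanning the dwell's range; the uncertainty is
$\sigma_i = \sqrt{\langle (x - x^*)^2\rangle / N_i}$ with the effective
uncorrelated count $N_i = \max(1, n/(1 + 2\tau))$ estimated from the
integrated autocorrelation time $\tau$ of the dwell residuals (initial
positive sequence estimator; for AR(1) noise this reproduces the
closed-form $n(1-\phi)/(1+\phi)$).

`extract_steps()` applies the 0.5-bp exclusion: the smallest sub-threshold
step is removed, its flanking dwells merged (position and uncertainty
recomputed from the pooled samples; durations summed, conserving total
time), and the scan repeats until stable, so the rule is idempotent.
Whether sub-threshold dwells should be merged or dropped is not settled by
the method's verbal description; merging was chosen because it conserves
both displacement and time.

## 3. Step-size statistics

The step-size KDE sums one Gaussian kernel per step, centered at $s$ with
width $\sigma_s$, on a 0.01-bp grid from 0 to $\max(s + 3\sigma)$
(unwinding) or $\min(s-3\sigma)$ to 0 (re-zipping), normalized to unit
integral. The bootstrap band resamples steps with replacement (default
10,000 iterations, implemented as one matrix product over multinomial
weight vectors, so the full band costs seconds) and reports the pointwise
standard deviation.

**Peak significance and periodicity.** The significance of peaks is
operationalized as: a local maximum counts if it exceeds twice the
bootstrap SE *and* rises by at least twice the SE above its deeper
flanking trough (a prominence requirement — a bump must be
distinguishable from the curve around it, not merely from zero). Maxima
closer together than one median kernel width are collapsed to the highest,
since structure finer than a kernel cannot be resolved. The periodicity is
the median spacing of the surviving peaks. On low-noise synthetic data
with mixed odd/even releases this yields 0.5 bp; with even-only totals it
yields 1.0 bp.

**Double-Gaussian fits.** `fit_double_gaussian()` is a deterministic EM,
initialized at the sample mean and twice the mean (the double-step reading
of the second component), components reported in ascending magnitude. Two
robustness choices: (i) a BIC guard compares the converged two-component
fit against a single Gaussian and reports a flagged single-Gaussian
fallback when the split is spurious — a two-component ML fit of a pure
Gaussian otherwise splits it into two overlapping halves; (ii) for the
merged-event analysis at 10 µM ATP the variances are pooled
(`equal_var = TRUE`), because with a few-percent double-step component the
heteroscedastic fit spreads its second component over the heavy lattice
tail of the singles rather than the 6-bp peak. The pooled-variance EM is
cross-checked against an independent mixture implementation in the test
suite.

**Pairwise distances.** The signed pairwise-distance histogram uses a
0.25-bp bin — deliberately coarser than the 0.5-bp lattice, since this
estimator targets the multi-bp stepping period, not the sub-bp structure —
lightly smoothed before peak-finding; the periodicity is the median peak
spacing, reported per sign.

**Covariate checks.** Independence of step size from force, stem position,
and ATP uses Pearson correlation of $|s|$ with a permutation p-value
(10,000 shuffles) rather than a parametric test, since nothing guarantees
normality of step sizes.

## 4. Dwell-time kinetics

Dwells are classified by flanking step signs; the dead-time exclusion is
20 ms at ≤5 µM ATP and 7 ms at ≥10 µM (the fast-acquisition condition).
Dwell-vs-step-size curves use a sliding boxcar of 35 points — the midpoint
of the conventional 25–45 range, exposed as a parameter — with standard
errors $\mathrm{sd}/\sqrt{w}$. Trendlines are fit in the
$\kappa(d + d_0)$ parameterization by weighted least squares (linear in
$\kappa$ and $\kappa d_0$; $d_0$'s SE by the delta method); a flat curve
is flagged degenerate with $d_0$ undefined rather than reported.

$n_{min} = (\langle t^2\rangle/\langle t\rangle^2 - 1)^{-1}$ is scale
invariant and equals $k$ for Erlang-$k$ dwells; with heterogeneous rates
it falls below the event count, which is the basis for inferring that only
one or two of the several ATP bindings before a large step are
rate-limiting. Its standard error uses the delta method on
$(\langle t\rangle, \langle t^2\rangle)$ including their sample
covariance, since no closed form is conventionally agreed.

The bootstrap outlier scan exploits the fact that a single very long dwell
inflates the variance much faster than the squared mean: the bootstrap
$n_{min}$ distribution becomes bimodal, with the low mode collecting
resamples rich in the outlier. Operational thresholds (the method's verbal
description gives none): bimodality is declared when a two-component
mixture of the bootstrap values has minor weight ≥ 0.1 and mode separation
≥ 4 pooled SDs; a dwell is flagged when its occurrence count among
low-mode resamples exceeds its expectation by ≥ 3 binomial SDs. On clean
Erlang samples the scan removes nothing; a dwell at 20 times the mean is
flagged reliably.

Speeds at step-resolvable ATP (≤10 µM) divide the mean step magnitude by
the mean same-direction dwell time, ignoring the rare backstep classes;
at saturating ATP they come from straight-line fits of uninterrupted runs,
either user-specified intervals or maximal monotone runs (≥0.5 s) of the
boxcar-smoothed trace. Michaelis–Menten fits use Levenberg–Marquardt
nonlinear least squares weighted by $1/\mathrm{se}^2$ when speed SEs are
available (the weighting convention is not otherwise fixed); a flat
speed-vs-ATP curve returns the plateau with $K_M \approx 0$ flagged as
saturation-degenerate.

## 5. DNA mechanics and hairpin thermodynamics

Force-to-extension uses the extensible worm-like chain in the high-force
(Odijk) interpolation $x(F) = h\,(1 - \tfrac12\sqrt{kT/FP} + F/S)$ with
$P_{ds} = 53$ nm, $P_{ss} = 1$ nm, $h_{ds} = 0.34$ nm/bp,
$h_{ss} = 0.59$ nm/nt, $S_{ds} = 1100$ pN, $S_{ss} = 1000$ pN, at 22 °C
($kT$ computed from the temperature, 4.075 pN·nm). This closed form is the
standard companion to that parameter set. Below ~1 pN the interpolation
turns negative and is clamped to zero; the stretching free energy
$\int_0^F x_{ss}\,dF'$ integrates the clamped form (closed-form
antiderivative; only the clamping threshold is found numerically), so it
is non-negative and increasing. Unwinding distance conversion divides the
extension change by twice the ssDNA extension at the measured force
(2 nt released per bp unwound).

Hairpin base-pairing energies use the unified nearest-neighbor
$\Delta H/\Delta S$ set (packaged as a TSV) with the logarithmic
monovalent-salt entropy correction $0.368\,\ln[\mathrm{Na}^+]$ cal/mol/K
per stack, evaluated at 55 mM and 295.15 K. Each stack is assigned to its
fork-proximal base pair; the final stem position carries the duplex
initiation term; the tetraloop is a fixed cap excluded from opening sums.
The thermal opening probability downstream of stem position $n$ at force
$F$ is

$$P_{open}(n, F) = \frac{\sum_{m\ge 1} e^{-\Delta G(m)}}{\sum_{m\ge 0}
e^{-\Delta G(m)}},\qquad \Delta G(m) = \sum_{j=n}^{n+m-1}
\Delta G_{bp}(j) - 2m\,\Delta G_{stretch}(F),$$

summed over the full remaining stem (opening past the tetraloop, i.e.
complete unfolding, is excluded; the stem end is absorbing), evaluated in
log-sum-exp form. Positions are 1-based from the fork; "downstream" means
larger $n$. The packaged fixtures use synthetic ~50% G-C stems (the
experimental stem sequences live in supplementary material not reproduced
here); a uniform-G-C variant mirrors the published sequence-dependence
control.

## 6. What the synthetic checks do and do not show

The test suite and the acceptance script demonstrate that, on data
generated by the delayed-release mechanism at the study conditions
(25 traces at 0.5 µM ATP and 100 Hz with 0.3 bp rms noise; nine ATP
concentrations from 0.5 to 1000 µM; 267 Hz at 10 µM), the analysis chain
recovers the generative parameters: ~3.0 bp mean steps of either sign, the
kinetic constants to a few percent, the 0.5-bp KDE periodicity, and a
~6-bp second mixture component once events inside the 15-ms dead time are
merged. Problem sizes were chosen so the whole suite runs in a couple of
minutes on one CPU: 400–1200 detected steps per headline estimate, $10^4$
samples for the moment-based oracles, $10^5$ draws for the convolution
check, 2000–10,000 bootstrap iterations.

Passing these checks shows the estimators are correct and calibrated *for
this generative model*. It does not establish that instrument data satisfy
the model: real traces carry correlated noise, drift, force-feedback
artifacts, sequence-dependent kinetics, and heterogeneity between
molecules, none of which are emulated. The pipeline ingests real traces
through the same TSV interface (`read_trace()`), but detection
sensitivity and the dead-time cutoffs should be re-examined against the
instrument's noise spectrum before quantitative use. Step detection at
10 µM ATP (dwells of ~18 samples at 267 Hz) is at the edge of
resolvability and over-splits; the double-step analysis therefore operates
on event logs with an explicit dead-time merge rather than on detector
output.

## 7. Known limitations

- The generator's loop-release schedule (`cycles_per_release`) and the
  per-strand release pmfs are calibrated summaries, not fits to published
  figure panels; analyses that depend on fine details of the release-size
  distribution should supply their own pmfs via
  `release_dist_from_counts()`.
- Re-zipping loop dynamics are the mirrored assumption the mechanism's
  description labels speculative; strand-switch kinetics beyond the ~20-bp
  mean burst length are not quantified, so `alternating` mode is
  qualitative.
- `p_open()` assigns stacking energies per base pair at single-bp
  granularity, which is an approximation at the two stem ends.
- The chi-square detector assumes piecewise-constant signal with white
  noise; correlated noise inflates the false-positive rate unless the
  sensitivity is raised.
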