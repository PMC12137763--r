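---
title: "Methods: organ-specific T2* mapping, centiles and robustness checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-specific T2* mapping, centiles and robustness checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalT2star)
```

## The problem

T2\* relaxometry of the placenta and fetal brain is an indirect, in-vivo
probe of tissue oxygenation: deoxyhemoglobin shortens the effective
transverse relaxation time, and mean organ T2\* falls steadily over normal
gestation. A whole-uterus multi-echo gradient-echo acquisition samples the
decay curve at a handful of echo times in under a minute, after which the
quantitative work is (i) fitting a decay model per voxel, (ii) averaging
T2\* over an organ mask with some guard against partial-volume
contamination, and (iii) situating the organ mean on gestational-age
normative curves so that a single exam can be read as low, normal or high.
This package implements that quantification chain, the agreement metrics
used to validate such pipelines (repeat consistency, Bland-Altman limits of
agreement, Dice overlap), and a synthetic uterine phantom that exercises
every stage with known ground truth.

## Signal model and solvers

Each voxel is modelled as a single compartment,

$$S(TE) = S_0 \, e^{-TE/T_2^*},$$

with two free parameters: the extrapolated signal at zero echo time $S_0$
and the effective relaxation time $T_2^*$ (ms). Two least-squares solvers
are provided:

* **Log-linear** (`method = "loglinear"`): ordinary least squares of
  $\ln S$ on $TE$, so $T_2^* = -1/\text{slope}$ and
  $S_0 = e^{\text{intercept}}$. Closed-form, fast, and exact on noiseless
  data, but it minimizes the residual in the log domain, which re-weights
  errors at low signal.
* **Bounded NLLS** (`method = "nlls"`, the default): projected
  Levenberg-Marquardt on the untransformed residual
  $\sum_e (S_e - S_0 e^{-TE_e/T_2^*})^2$, initialized from the log-linear
  solution (fallback: $T_2^*$ = median TE, $S_0$ = first usable echo).
  This is the faithful reading of "least squares fitting to a
  monoexponential decay"; the log-linear route is retained because it is
  the standard fast approximation and a useful cross-check — on noiseless
  voxels the two agree to solver tolerance, and the test suite asserts
  that the NLLS residual never exceeds the log-linear one.

Both solvers are vectorized across voxels; a default 64×64×48 volume fits
in a few seconds on one core, comfortably inside the real-time budget such
pipelines aim for (wall-clock is logged, never asserted).

Numerical choices worth knowing about:

* **Bounds and validity.** $T_2^*$ is constrained to `t2_bounds`
  (default 1–2000 ms, chosen to exceed the organ thresholds and the long
  fluid T2\* they guard against). A voxel whose solution sits at a bound,
  a non-decaying voxel (log-linear slope ≥ 0), a non-converged voxel, or
  one with fewer than `min_valid_echoes` usable samples is flagged invalid
  and carries NaN in the assembled map. Degenerate slope-zero voxels are
  invalidated rather than saturated at the upper bound, so they cannot
  silently inflate organ means.
* **Convergence.** NLLS stops at a relative parameter change below 1e-8 or
  200 iterations; per-voxel damping is adapted multiplicatively and steps
  are accepted only when the objective does not increase.
* **Weighting.** Both solvers are unweighted; no echo weighting scheme is
  assumed.
* **Noise floor.** Magnitude MRI noise is Rician, which biases low-SNR
  samples upward and can inflate T2\* late in the decay. The default fit
  deliberately ignores this (matching common practice for this
  acquisition regime, where the protocol keeps SNR high); an opt-in
  correction $S' = \sqrt{\max(S^2 - 2\sigma_n^2,\,0)}$ with user-supplied
  $\sigma_n$ is available via `fit_options(rician_correction = TRUE)`.

## Organ quantification

`summarize_organ()` averages T2\* over a mask after discarding (a) invalid
fits and (b) voxels above an organ-specific upper threshold — 500 ms for
the placenta, 900 ms for the fetal brain — which suppresses partial-volume
contamination from amniotic fluid and other fluid-dominated voxels whose
T2\* is far longer than parenchyma. The comparison is inclusive
(`t2star <= threshold` is kept), and voxels above threshold are excluded
rather than clipped, since clipping would bias the mean toward the
threshold. Organ volume is pure mask geometry (voxel count × voxel
volume, 3.125 × 3.125 × 3 mm³ = 29.296875 mm³ by default) and is
unaffected by any filtering; the voxel accounting
(`used + over_threshold + invalid = mask`) is reported in full.

## Normative curves and classification

From a control table of (GA, organ, measure, value) records,
`build_normative_models()` fits, per organ and measure:

* a mean trend by OLS — quadratic in GA for fetal-brain mean T2\*, linear
  for placental mean T2\* and both volumes;
* 5th and 95th centile curves by quantile regression (pinball loss,
  Barrodale-Roberts simplex via the *quantreg* package), sharing the trend's
  polynomial degree. The degree-sharing is an assumption: the centile
  model form is genuinely open here, and matching the trend keeps the
  curves parsimonious and mirrors how such growth-chart centiles are
  usually drawn.

`classify()` evaluates the centiles at the exam's GA and assigns
low/normal/high with inclusive boundaries (a value exactly on a centile
is normal — a documented tie rule, not a claim about prevalence). GA
outside the training range is flagged `extrapolated` but still
classified; refusing would be safer statistically but useless clinically,
so the flag preserves honesty without blocking use. No non-crossing
constraint is imposed during fitting; crossing of the 5th above the 95th
centile inside the GA range is detected on a 101-point grid and raises a
warning. With only two centiles, variations that stay inside the band are
invisible — finer centile grids are an obvious extension and are out of
scope here.

## Agreement metrics

`bland_altman()` reports the mean difference and ±1.96 SD limits of
agreement of paired series, oriented first-minus-second with the
orientation recorded in labels; the SD uses the n−1 denominator (the
convention is documented because reported mean differences alone do not
pin it down). `dice()` is $2|A\cap B|/(|A|+|B|)$ with the degenerate
both-empty case defined as 1.0. `repeat_consistency()` mirrors how
repeat-acquisition stability is reported for this kind of pipeline: all
pairwise mean-T2\* differences for k repeats, the per-repeat centile band,
and a stability flag that is true iff all repeats share one band.

## The synthetic phantom: what it does and does not emulate

`phantom_spec()`/`generate_phantom()` build a whole-uterus stand-in: an
ellipsoidal fetal brain and an oblate-ellipsoid placenta in a low-signal,
short-T2\* background, with the acquisition constants of a low-field
multi-echo EPI protocol (TE = 57/152/248/344 ms, 3.125 × 3.125 × 3 mm³
voxels). The default grid is 64×64×48 — a down-sampled whole-uterus FOV
that keeps the full pipeline fast while leaving ~10⁴ organ voxels for
statistics.

Defaults were fixed once, before any result was inspected at scale, as
plausible low-field values:

* GA trends (weeks $g$): placental T2\* $= 375 - 4.5g$ ms; brain T2\*
  $= 600 - 2g - 0.15g^2$ ms (both decreasing over gestation, well below
  their 500/900 ms thresholds at term); brain volume $= 12000(g-15)$ mm³;
  placental volume $= 15000g - 100000$ mm³. Default exam GA is 37 weeks,
  typical of late-gestation screening.
* Cohort scatter: 30 ms (placenta) and 20 ms (brain) around the T2\*
  trends, 60 000 / 15 000 mm³ around the volumes — the placenta gets the
  larger relative scatter, as placental measurements at late gestation
  are the more variable ones. The synthetic control cohort defaults to 88
  cases over GA 20–40 weeks.
* Noise is additive Gaussian by default so that solver accuracy can be
  tested free of magnitude bias; a Rician mode exists to exercise the
  noise-floor correction. `snr_sigma(spec, 20)` returns the σ giving
  first-echo SNR 20 in the weaker organ.
* The contraction confound multiplies placental T2\* by $1-f$ over either
  the whole parenchyma (`region = "full"`, default, $f = 0.4$ — the
  organ-level depression of a strong contractile state, sized so the
  organ mean lands clearly below the 5th centile) or one half of the
  placenta (`region = "half"`, for localized contractile activity). The
  motion confound rigidly shifts the brain on selected echoes, corrupting
  the decay sampled at the nominal location.
* `generate_repeat_series()` derives per-repeat seeds deterministically
  from the base seed, so repeats share geometry and truth and differ only
  in noise and stated perturbations.

What the phantom does **not** emulate: real fetal anatomy, EPI
distortion, B0 inhomogeneity, coil sensitivity, partial-volume mixtures
at organ boundaries, or maternal tissue heterogeneity. Consequently,
passing phantom tests demonstrates the correctness of the numerical
chain — fitting, filtering, centile logic, agreement metrics — not
segmentation performance or clinical accuracy on real data. The phantom
segmenter (`segment_phantom()`) is deliberately trivial (geometry plus an
intensity gate on the second echo, the echo used for segmentation input);
real masks come from external tools through `load_external_mask()`, and
any trained network remains a pluggable interface, not a component.

## Problem sizes used in tests

The suite runs the full default grid (64×64×48, both solvers) for the
round-trip and SNR-20 recovery checks, 10⁴ simulated voxels for noise
monotonicity, n = 2000 cohorts for quantile coverage (the 5%-coverage
check uses a 99% binomial interval), 100-instance oracle comparisons for
the metrics, and a 48×48×36 grid for the three-repeat robustness
scenarios. Smaller 32×32×24 and 24×24×18 grids are used where only
mechanism, not statistics, is under test.

## Known limitations

* The monoexponential model is the standard single-compartment reading;
  multi-compartment or stretched-exponential decays are out of scope.
* Quantile curves may cross outside well-sampled GA ranges; the package
  warns rather than constrains.
* The Rician correction needs a user-supplied noise estimate; no
  background-based σ estimation is provided.
* Masks must share the acquisition grid; there is no resampling.
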