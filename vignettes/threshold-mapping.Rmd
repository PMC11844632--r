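---
title: "Gaussian-process threshold mapping: model, sampling and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-process threshold mapping: model, sampling and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threshmap)
```

## The estimation problem

A retinal implant stimulates the retina through a rectangular grid of
electrodes (the default geometry is the 6 × 10, 60-electrode Argus II
array). Each electrode has a perceptual threshold: the smallest current
amplitude, in μA, at which the user reliably reports a percept. Thresholds
are measured psychophysically on a discrete amplitude ladder — here 60
log-spaced values from 40 to 677 μA — and the 677 μA device safety limit
censors any electrode whose true threshold lies above it: such electrodes
are recorded *at* the maximum and flagged.

Measuring every electrode is expensive, but thresholds are spatially
correlated: neighboring electrodes share tissue coupling, current spread
and local retinal condition. threshmap therefore treats the threshold map
as a realization of a spatial random field, measures a subset of
electrodes, and interpolates the rest by Gaussian process regression,
with the posterior standard deviation as a per-electrode confidence
measure.

## Model and transform

The GP is fit on transformed targets: log10 of the threshold, then
standardized to zero mean and unit variance over the training electrodes
(population standard deviation; a zero-spread training set clamps the scale
to 1 and records a flag instead of failing). Two reasons for this choice,
which is a `use_log` flag rather than hard-wired:

- thresholds span orders of magnitude within one array, and relative
  (percent) error is the quantity of interest, so errors should be
  homoscedastic on a log scale;
- the hyperparameter box constraints are only meaningful on a unit-scale
  target: the signal variance σ² is bounded in (0.1, 10), and a raw-μA
  target with variance ~10⁴ would pin every fit to the boundary.

The predictive mean is inverted exactly back to μA (the inverse transform
is monotone, so the reported `mean_uA` is the posterior median on the μA
scale); the reported standard deviation stays in transformed space, which
is the scale on which it is comparable across electrodes and the scale the
adaptive strategy ranks by.

Three stationary kernels over inter-electrode distance `d` (in pitch units;
default pitch 1, so the length-scale bounds read as 1–50 electrode
spacings) are provided: RBF for smooth fields, Matérn ν = 3/2 for fields
with sharper transitions, and a hybrid
σ² [α·RBF(d; ℓ₁)/σ² + (1 − α)·Matérn(d; ℓ₂)/σ²]. The hybrid factors a
single signal variance out of both components, so its free parameters stay
interpretable: one overall scale, two length scales and a mixing weight.
The mixing weight α is treated as a free parameter in [0, 1] and optimized
jointly with the length scales — fixing it would require knowledge of the
smooth/rough mix that the model is supposed to discover.

The observation-noise term σₙ² δᵢⱼ enters the training covariance diagonal.
Its bounds (10⁻⁵, 1) keep it strictly positive, which the Cholesky
factorization needs; a 10⁻¹⁰ diagonal jitter is added as well. The
predictive variance reported by `predict()` is the new-measurement
variance k(0) + σₙ² − k*ᵀ(K + σₙ²I)⁻¹k*, i.e. the noise term is treated as
part of the kernel: far from all training data the standard deviation
reverts to √(σ² + σₙ²), and at a training electrode it falls to about the
noise floor.

### Hyperparameter optimization

The log marginal likelihood is maximized with L-BFGS-B over log-transformed
positive parameters (α on its natural scale) inside the bounded box, with
10 restarts by default: the first from the spec's initial values
(σ² = 1, ℓ = 3, σₙ² = 0.1, α = 0.5), the rest drawn log-uniformly within
the bounds from a seeded generator, so fits are exactly reproducible. A
restart that ends worse than its starting point is replaced by the starting
point, so the achieved LML never falls below the initial one. Censored
electrodes are excluded from training by default: their recorded 677 μA is
only a lower bound, and training on it would bias the field downward near
the censored site. (`include_censored = TRUE` exists for sensitivity
analysis; a censored-likelihood/Tobit GP is out of scope.) A single-electrode
training set is allowed but warned about — the posterior then reverts to
the prior away from that electrode.

## Sampling strategies

- **uniform**: n draws without replacement from the active set. The
  unbiased baseline; clusters spatially at small n.
- **spatial**: Poisson-disk sampling adapted to the discrete grid. The
  initial radius is r₀ = √(WH/n) (grid extent W × H, so the disks roughly
  tile the array), candidates are proposed in the annulus [r, 2r] around a
  random frontier electrode and accepted if at least r from every selected
  electrode; a frontier electrode retires after 30 failed proposals. The
  literature version simply terminates when no candidate remains, but the
  benchmark needs exactly n electrodes, so the radius shrinks by 0.8 and
  sampling resumes; the final radius is recorded in the plan and the
  spacing guarantee is stated against it.
- **adaptive**: an initial uniform subset (default n_init = 5) is measured,
  a GP is fit, and the unmeasured active electrode with the largest
  posterior standard deviation is acquired next, one electrode per
  iteration, refitting hyperparameters each time by default
  (`refit = FALSE` freezes them, which is much cheaper and changes the
  acquisition only through the hyperparameters). Ties break toward the
  lowest electrode id so plans are deterministic.

All three are deterministic functions of their seed. Benchmark cells derive
their seeds by hashing the base seed with the cell coordinates (map label,
strategy, n, iteration), and the *same* plan seed is shared across kernel
families, so kernel contrasts are paired on identical training sets for the
geometry-driven strategies (the adaptive plan is model-dependent and is
rebuilt per family from the same seed). Strategy contrasts pair on
(map, n, iteration) with independent strategy-specific plans.

## Evaluation

`evaluate_once()` fits on the plan and scores MAPE — (1/N) Σ|yᵢ − ŷᵢ|/yᵢ ×
100, in linear μA — on the held-out set: active, non-censored, unsampled
electrodes. Censored electrodes are not scored, because comparing a
prediction of the (unknown, supra-maximum) true threshold against the
recorded ceiling value would penalize correct behavior. A cell with no
evaluable held-out electrode produces a flagged invalid record rather than
disappearing.

Condition contrasts use the Wilcoxon signed-rank test on paired MAPE
records, two-sided, at the conventional 0.05 level with no multiplicity
correction. Zero differences are dropped (the classic convention). Because
paired MAPE values can tie in absolute value, the exact null distribution
is computed by a tie-aware convolution over signed average ranks for up to
25 non-zero pairs — `stats::wilcox.test` declines to be exact under ties —
and a normal approximation with continuity and tie corrections is used
beyond that. Fewer than one non-zero pair yields an explicit
"test undefined" result.

## The synthetic generator

Real threshold maps combine a smooth global trend with sharp local
discontinuities, plus censoring and broken electrodes. The generator
emulates exactly that, in log10 space: a constant baseline (default
log10 150 μA, mid-ladder) plus a draw from a zero-mean Gaussian field with
squared-exponential covariance (length scale 3 pitch units, sd 0.25
log10-units), plus optional rectangular patch offsets (the sharp
discontinuities), plus independent per-electrode measurement noise
(sd 0.02 log10-units, ≈ 4.7% relative — on the order of a good adaptive
psychophysical estimate, and the irreducible error floor of the benchmark).
Values are converted to μA, snapped to the nearest ladder value in log
space, clamped to [40, 677], censored at 677, and electrodes drop out as
inactive with probability 0.05.

The latent field is deliberately squared-exponential — maximally smooth —
while the presets with patches add the non-smoothness that favors a Matérn
kernel. This lets the benchmark reproduce the qualitative kernel ranking
without building the conclusion into the generator's covariance itself.

Presets: `smooth` (no patches), `patchy` (two 2 × 3 patches at ±0.5
log10-units, i.e. ≈ 3× threshold steps), `censored-heavy` (baseline
log10 500 μA, so a large fraction censors).

What the generator does *not* emulate: trial-by-trial psychophysics (noise
is Gaussian in log amplitude, not derived from a yes/no staircase),
impedance or eccentricity covariates, threshold drift within a session, and
whatever spatial statistics real users' maps have beyond "smooth trend plus
patches". Passing the packaged benchmark therefore demonstrates that the
estimator, sampling and scoring machinery are correct and that the method
works on fields with the assumed structure — not that the same error levels
will be achieved on clinical data.

## Problem sizes and numerical choices

The packaged benchmark runs 10 smooth-preset maps × 10 iterations × {20,
50} sampled electrodes with the Matérn kernel and spatial sampling — 200
fits of at most 50 training points, a few minutes on one CPU — and the test
suite uses smaller sweeps of the same machinery. Key numeric details in one
place: Cholesky with 10⁻¹⁰ jitter everywhere; posterior variance clamped at
zero (tolerance 10⁻¹⁰, with a warning beyond it); population (not sample)
sd in the standardizer; acquisition ties to the lowest id; PDS distance
comparisons with a 10⁻⁹ slack so exact grid distances are not rejected by
round-off; all seeds are 31-bit hashes so they remain valid R integers.

## Known limitations

Censoring is handled by exclusion, not by a censored likelihood; the
kernels are isotropic with a single length scale per component; no
covariates beyond 2-D grid position; the Wilcoxon exact path is O(n·Σr) in
time and is capped at 25 pairs; and the generator's parameters are
plausibility choices for a realistic test bed, not estimates fitted to any
participant's data.
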