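---
title: "Trial-resolved power-envelope networks: model, estimators and design choices"
author: "oscnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-resolved power-envelope networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

During an auditory perceptual decision, large-scale networks of coupled
neural oscillations reorganize from trial to trial. This package implements
a trial-by-trial analysis that asks whether the *topology* of those
networks — how segregated or integrated the coupling pattern of band-limited
power envelopes is on a given trial — predicts how fast the decision on that
trial is made. Because real source-projected MEG recordings are rarely
shareable, the package pairs the analysis chain with a generative
synthetic-data layer, so that every estimator can be validated by parameter
recovery against a known ground truth.

The analysis chain is:

1. **Stimuli and design** (`textureSpec()`, `makeTexture()`,
   `makeDesign()`): acoustic textures of 72 frequency-modulated sweeps
   (100 ms each, slopes ±3.3 octaves/s) in a 400-ms sound; spectral centers
   at ±2, 1, 0.5, 0.25 semitones around 707.1 Hz and sweep-slope coherence
   at 25/50/75/100%. Blocks of 128 trials contain each
   direction × coherence × spectral-center cell exactly twice, and the
   pitch/direction tasks alternate across blocks.
2. **Behavior** (`movingAccuracy()`, `decisionSpeed()`, `rankZ()`):
   trial series of moving-average accuracy (rectangular window, 4 trials)
   and decision speed (reciprocal response time); no-response trials are
   masked.
3. **Spectral analysis** (`buildGrid()`, `waveletTransform()`): Morlet
   wavelets (6 cycles) at 12 frequencies — 1, 2, 4 Hz plus
   2^(3…5 in steps of 0.25) Hz — evaluated at 41 time points from −0.5 to
   +1.5 s in 0.05-s steps. Epochs are mirror-extended for the sub-8-Hz
   wavelets, whose support exceeds the epoch.
4. **Connectivity** (`orthogonalize()`, `envelopeConnectivity()`):
   per-trial all-to-all Pearson correlations between log power envelopes,
   after pairwise orthogonalization
   `|Im(y · conj(x) / |x|)|²`, which removes the instantaneous shared
   component that field spread induces between nearby sources. Both
   directions are averaged and the matrix symmetrized.
5. **Graphs** (`thresholdDensity()`, `networkMetrics()`): each trial's
   correlation matrix is thresholded by the rank of absolute correlation to
   a fixed 10% edge density (5% as a robustness setting) and binarized.
   Whole-brain diagnostics: mean functional connectivity of retained edges,
   global efficiency, mean local efficiency, Louvain modularity Q. Nodal
   diagnostics: strength, local efficiency, within-module z-score, nodal
   efficiency, participation coefficient.
6. **Inference** (`subjectGlm()`, `circularNull()`, `fcrCorrect()`):
   a two-level GLM. Per subject, the rank-transformed and z-scored
   behavioral series is regressed on a rank-z network metric plus the
   rank-z acoustic covariates (spectral center, coherence). Group mean
   weights per frequency are tested against a null of 350 circular shifts
   of the behavioral series (shift k applied to every subject alike), with
   two-sided 2.5/97.5 percentile bounds, and corrected across frequencies
   by the false coverage-statement rate: after selecting frequencies whose
   95% null interval excludes the observation, intervals are rebuilt at
   level 1 − Fs·q/Ft and only still-excluded frequencies survive.

## The generative model

`simulateEpochs()` draws, per trial, source signals

> x_i(t) = exp(a_i(t)) · cos(2π f_c t + φ_i) + background_i(t)

where the log amplitude envelopes a_i(t) are correlated Gaussian processes
(target matrix C_t), the carrier phases φ_i are independent and uniform,
and the background is 1/f (pink) noise scaled to a fixed
oscillation-to-background variance ratio. A per-trial latent
w_t ~ U(0, 1) interpolates C_t between a **segregated** endpoint (4 equal
modules, within-module correlation 0.7, between 0.05) and an **integrated**
endpoint (uniform correlation 0.15). `simulateBehavior()` couples decision
speed to the z-scored latent: speed = 1.8 + 0.3·z(w) + N(0, 0.5), floored
at 0.05 s⁻¹, with response time 1/speed, Bernoulli(0.70) correctness and
1% no-response trials.

### Parameter choices that matter

- **Carrier frequency** 20 Hz: mid-beta, between the 19.03 and 22.63 Hz
  grid bins, so recovery must appear at those bins and nowhere at 1–4 Hz.
- **Log-envelope bandwidth** (`envelopeCutoff`, default 2 Hz): the
  envelope process must fluctuate *within* the 2-s analysis window for a
  within-trial correlation over 41 samples to carry information; a process
  band-limited to 0.3 Hz has fewer than two effective samples per window
  and makes every per-trial estimate pure noise. Slow across-trial network
  drift is instead modeled by the latent w_t itself. The cutoff sits
  inside the ±3.2 Hz passband of the 6-cycle wavelet at 20 Hz, so envelope
  dynamics survive the spectral estimator.
- **Log-envelope SD** 0.75: band-limited power then fluctuates by roughly
  a factor of e^±1.5, typical of cortical band power.
- **SNR** 3 (oscillation vs. total 1/f background variance): a favourable
  but plausible source-level ratio; the in-band ratio after wavelet
  filtering is what matters for the estimator.
- **Endpoint contrast** (0.7/0.05 modular vs. 0.15 uniform): chosen during
  design so that the four whole-brain metrics respond to w_t with the
  expected signs (mean FC, local efficiency, modularity up; global
  efficiency down) at correlations of roughly 0.3–0.6 with the latent —
  strong enough for recovery at desk scale, far from saturation.
- **Behavioral coupling** slope 0.3 with noise SD 0.5 gives a
  latent-to-speed correlation of 0.3/√(0.09+0.25) ≈ 0.51.

## What the synthetic data do and do not emulate

The simulator produces source-space signals directly: no forward model, no
beamforming, no sensor noise, no artifacts. Field spread is available only
as an instantaneous linear mixing toggle (`mixing`), which exists to test
that orthogonalization suppresses leakage-induced coupling; it is not a
physical leakage model. Accuracy is not linked to the network state by
default (the planted effect is on speed), response-time distributions are
Gaussian-in-speed rather than shifted-lognormal, and all sources share one
carrier frequency. Passing recovery tests therefore demonstrates that the
estimators and inference machinery are correct and calibrated — not that
real MEG data will show these effects.

## Numerical choices

- Wavelets are unit-energy; coefficients are synthesized in the frequency
  domain using only the bins where the wavelet's Gaussian spectrum exceeds
  1e-9 of its peak, which is exact to ~1e-13 relative against a full
  inverse FFT.
- Log power is floored at 1e-30 of the trial's maximum power before the
  logarithm; pairs with constant envelopes get correlation 0 with a
  warning.
- Density thresholding breaks ties deterministically by upper-triangle
  index order; the edge count is exactly floor(density · N(N−1)/2).
- Shortest paths use BFS via boolean matrix powers; disconnected pairs
  contribute 0 to efficiencies (1/∞); nodes of degree < 2 have local
  efficiency 0. Mean nodal efficiency equals global efficiency to machine
  precision because both are derived from one distance matrix.
- Louvain community detection (igraph) runs 10 restarts under a fixed seed
  and keeps the best-Q partition; within-module z-scores use the
  population SD and map zero-SD modules to z = 0.
- Rank-z uses average ranks for ties and the population (1/n) denominator;
  since ranks are rotation-invariant, all circular shifts of a subject
  reduce to one matrix product with a precomputed pseudo-inverse row.
- Circular shifts use the common offsets 1…n_shifts for every subject
  (independent random offsets are available); subjects with unequal valid
  trial counts are handled per subject, with n_shifts capped at the
  smallest count.

## Design decisions where the design was open

- **Moving-average alignment**: centered, with a shrinking window at the
  series edges (trailing alignment available). Length is preserved.
- **Coherent sweep count**: round(coherence × n_sweeps).
- **Sweep start frequencies**: uniform in log frequency over ±1.5 octaves
  around the spectral center (configurable); onsets uniform over
  [0, duration − sweep duration].
- **Incoherent slopes**: ±3.3 octaves/s with random sign per sweep.
- **Audio rendering**: exponential frequency glides with 5-ms
  raised-cosine ramps, peak-normalized; a 16-bit PCM WAV writer is
  included for listening checks.
- **Orthogonalization direction**: both directions computed and averaged
  before symmetrization.
- **Baseline correction**: per trial (trial-averaged optional), over
  −0.5–0 s.
- **Analysis window presets**: main (−0.5…1.5 s), prestimulus
  (−0.85…0 s), poststimulus (0…1 s) and response window (1…1.5 s) reuse
  the same stats layer.

## Problem sizes used by the test suite

The package's own validation runs at desk scale, chosen so the full suite
completes on a single CPU: the default pipeline configuration is 12
subjects × 200 trials × 64 sources × 12 frequencies, while the recovery
study in the test suite uses 20 independent runs of 6 subjects × 96 trials
× 32 sources at the five diagnostic frequencies (1, 2, 4, 19.03,
22.63 Hz) with 90 circular shifts, and the type-I calibration uses 500
repetitions of 12 subjects × 200 trials × 12 surrogate regressors with 100
shifts. Statistical power at these sizes is ample (the planted group-level
effect is ~5 null standard errors), so shrinking the study does not soften
the checks.

## Known limitations

- The per-trial correlation over 41 points is a high-variance estimator by
  construction; per-trial network metrics inherit that variance, and only
  the trial-resolved *regression* aggregates it away.
- At 10% density a 32–64 node graph holds 49–201 edges; topology metrics
  at this scale are meaningful but noisier than on the ~1800-node grids
  used with real recordings.
- Louvain Q values depend on the optimizer; the package asserts Q of the
  returned partition exactly, and optimality only where exhaustive search
  is feasible (n ≤ 8).
- The two-level GLM treats subjects as exchangeable (mean of standardized
  weights); no parametric mixed-effects machinery is provided.
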