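# oscnet

Trial-resolved analysis of large-scale power-envelope networks of neural
oscillations, and their relation to perceptual decision behavior — with a
fully synthetic ground-truth layer so that every stage is testable without
recordings.

## What it does

For auditory decision experiments with "cloud of sweeps" texture stimuli,
the package links the **topology of frequency-specific brain networks** to
**trial-by-trial decision speed**:

1. per-trial Morlet wavelet coefficients (6 cycles) on a 1–32 Hz grid,
   41 time points (−0.5 … 1.5 s, 0.05 s steps);
2. per-trial all-to-all power-envelope correlations with pairwise
   orthogonalization, `env(y|x) = |Im(y · conj(x)/|x|)|²`, which removes
   zero-lag leakage before the Pearson correlation of log envelopes;
3. binary undirected graphs at a fixed 10% edge density (ranked by
   absolute correlation), with whole-brain diagnostics — mean functional
   connectivity, global efficiency, mean local efficiency, Louvain
   modularity Q — and nodal diagnostics (strength, local efficiency,
   within-module z-score, nodal efficiency, participation);
4. a two-level rank-based GLM: per subject, rank-z decision speed is
   regressed on a rank-z network metric controlling for stimulus spectral
   center and coherence; group mean weights per frequency are tested
   against a circular-shift permutation null (percentile 2.5/97.5,
   two-sided) and corrected across frequencies by the false
   coverage-statement rate, rebuilding intervals at level `1 − Fs·q/Ft`.

The synthetic layer generates the stimuli and balanced designs (72-sweep
400-ms textures, 128-trial blocks with alternating pitch/direction tasks),
source-space oscillatory epochs whose log-envelope correlation matrix
interpolates per trial between a modular and an integrated network state,
and behavior whose decision speed follows that latent state.

## Worked example

```r
library(oscnet)

## stimulus arithmetic: the eight spectral centers around 707.1 Hz
round(spectralCenters(707.1))
#> [1] 630 667 687 697 717 728 749 794

## a balanced session: 6 blocks x 128 trials, tasks alternating
d <- makeDesign(6, seed = 1)
table(d$task)
#> direction     pitch
#>       384       384

## end-to-end synthetic run (desk scale, ~40 s):
cfg <- runConfig(seed = 42, nSubjects = 6, nTrials = 96, nSources = 32,
                 freqs = c(1, 2, 4, 2^4.25, 2^4.5), nShifts = 90)
run <- runPipeline(cfg)
reportResults(run)
```

The report prints one row per metric and frequency. With the default
planted coupling (a 20-Hz carrier whose network state drives decision
speed), the run above yields, e.g. for mean functional connectivity,
`beta = 0.255` at 19.03 Hz and `beta = 0.264` at 22.63 Hz — both marked
`**` (outside the FCR-corrected null bounds of roughly ±0.09) — while the
1–4 Hz mean-FC rows stay inside their null intervals (betas 0.061,
−0.002 and 0.027). Local efficiency and modularity show the same positive effect at
the carrier bins and global efficiency the mirrored negative one
(`beta = −0.249` at 19.03 Hz): segregated network states speed decisions
up, integrated states slow them down, exactly as planted.

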