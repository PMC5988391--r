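Package: oscnet
Title: Trial-Resolved Power-Envelope Networks of Neural Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking large-scale networks of coupled neural
    oscillations to trial-by-trial perceptual decision behavior. Implements
    frequency-modulated acoustic texture stimuli and balanced trial designs,
    a source-space oscillation simulator with planted power-envelope coupling
    networks, Morlet wavelet time-frequency analysis, pairwise-orthogonalized
    power-envelope correlations, density-thresholded binary brain graphs with
    whole-brain and nodal graph diagnostics, and a two-level rank-based
    general linear model with a circular-shift permutation null and false
    coverage-statement rate (FCR) correction. A synthetic-data layer makes
    every analysis stage verifiable by parameter recovery without any
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'stimgen.R'
    'synthmeg.R'
    'behavior.R'
    'spectral.R'
    'connectivity.R'
    'netmetrics.R'
    'stats.R'
    'pipeline.R'
    'io.R'
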