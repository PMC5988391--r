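## S4 classes for the texture-stimulus / oscillation-network pipeline.
## Heavy numeric payloads are plain arrays inside the objects; accessors
## rather than direct slot access are the supported interface.

#' TextureSpec: parametric description of a cloud-of-sweeps stimulus
#'
#' An acoustic texture is a brief sound made of many overlapping
#' frequency-modulated sine sweeps. Its *spectral center* places the texture
#' in log-frequency relative to a mean center frequency; its *coherence* is
#' the fraction of sweeps sharing one signed frequency slope.
#'
#' @slot duration Texture duration in seconds (default 0.4).
#' @slot nSweeps Number of sweeps (default 72).
#' @slot sweepDuration Duration of each sweep in seconds (default 0.1).
#' @slot meanCenterFreq Mean center frequency in Hz (default 707.1).
#' @slot semitoneDeviation Deviation of this texture's spectral center from
#'   the mean center frequency, in semitones (e.g. one of +/-2, 1, 0.5, 0.25).
#' @slot coherence Fraction of sweeps sharing the coherent slope, in (0, 1].
#' @slot coherentDirection `"up"` or `"down"`.
#' @slot slopeMagnitude Absolute frequency slope in octaves/second
#'   (default 3.3).
#' @slot freqSpanOctaves Total log-frequency span (octaves) over which sweep
#'   start frequencies are drawn, centered on the spectral center
#'   (default 3, i.e. +/- 1.5 octaves).
#' @seealso [textureSpec()], [makeTexture()]
#' @export
setClass("TextureSpec",
  representation(
    duration = "numeric", nSweeps = "integer", sweepDuration = "numeric",
    meanCenterFreq = "numeric", semitoneDeviation = "numeric",
    coherence = "numeric", coherentDirection = "character",
    slopeMagnitude = "numeric", freqSpanOctaves = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (object@sweepDuration <= 0 || object@sweepDuration > object@duration)
      msg <- c(msg, "sweepDuration must lie in (0, duration]")
    if (object@nSweeps < 1L) msg <- c(msg, "nSweeps must be >= 1")
    if (object@meanCenterFreq <= 0) msg <- c(msg, "meanCenterFreq must be positive")
    if (object@coherence <= 0 || object@coherence > 1)
      msg <- c(msg, "coherence must lie in (0, 1]")
    if (!object@coherentDirection %in% c("up", "down"))
      msg <- c(msg, "coherentDirection must be 'up' or 'down'")
    if (object@slopeMagnitude <= 0) msg <- c(msg, "slopeMagnitude must be positive")
    if (object@freqSpanOctaves < 0) msg <- c(msg, "freqSpanOctaves must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' TextureStimulus: one realized acoustic texture
#'
#' @slot spec The [TextureSpec-class] the stimulus was drawn from.
#' @slot sweeps A `data.frame` with one row per sweep and columns `onset`
#'   (s), `start_freq` (Hz), `slope` (octaves/s) and `is_coherent` (logical).
#' @seealso [makeTexture()], [synthesizeAudio()]
#' @export
setClass("TextureStimulus",
  representation(spec = "TextureSpec", sweeps = "data.frame"),
  validity = function(object) {
    sw <- object@sweeps; sp <- object@spec
    msg <- character()
    need <- c("onset", "start_freq", "slope", "is_coherent")
    if (!all(need %in% names(sw)))
      return(paste("sweeps must have columns", paste(need, collapse = ", ")))
    if (nrow(sw) != sp@nSweeps) msg <- c(msg, "number of sweeps != nSweeps")
    if (any(sw$onset < 0 | sw$onset > sp@duration - sp@sweepDuration + 1e-12))
      msg <- c(msg, "onsets must lie in [0, duration - sweepDuration]")
    if (sum(sw$is_coherent) != round(sp@coherence * sp@nSweeps))
      msg <- c(msg, "coherent sweep count != round(coherence * nSweeps)")
    if (length(unique(sw$slope[sw$is_coherent])) > 1L)
      msg <- c(msg, "coherent sweeps must share one signed slope")
    if (length(msg)) msg else TRUE
  })

#' CouplingModel: ground-truth generative model for source-space epochs
#'
#' Describes band-limited oscillatory sources whose log power envelopes carry
#' a planted correlation structure, riding on a 1/f background. When
#' `envelopeCorrAlt` is non-empty the per-trial target correlation matrix is
#' a convex mixture `w * envelopeCorr + (1 - w) * envelopeCorrAlt` with a
#' latent mixing weight `w` drawn per trial; `w` is recorded as the planted
#' per-trial network statistic.
#'
#' @slot nSources Number of sources (>= 4).
#' @slot carrierFreq Carrier frequency of the oscillation in Hz (default 20).
#' @slot envelopeCorr Target source-by-source correlation matrix of log
#'   envelopes (symmetric, unit diagonal, positive semi-definite).
#' @slot envelopeCorrAlt Optional second endpoint matrix for the per-trial
#'   mixture (empty matrix when unused).
#' @slot envelopeCutoff Low-pass cutoff of the log-envelope process in Hz
#'   (default 2): log envelopes fluctuate below this rate, within the
#'   analysis window.
#' @slot logEnvSd Standard deviation of the log amplitude envelope
#'   (default 0.75).
#' @slot behaviorSlope Effect of the (z-scored) planted network statistic on
#'   decision speed, in speed units per SD (default 0.3).
#' @slot behaviorNoiseSd SD of trial-level Gaussian noise on decision speed
#'   (default 0.5).
#' @slot snr Ratio of oscillation variance to 1/f background variance
#'   (default 3).
#' @slot mixing Instantaneous linear source-mixing coefficient in [0, 1)
#'   emulating field spread / leakage (default 0 = no mixing); used only for
#'   orthogonalization testing.
#' @seealso [couplingModel()], [simulateEpochs()], [simulateBehavior()]
#' @export
setClass("CouplingModel",
  representation(
    nSources = "integer", carrierFreq = "numeric",
    envelopeCorr = "matrix", envelopeCorrAlt = "matrix",
    envelopeCutoff = "numeric", logEnvSd = "numeric",
    behaviorSlope = "numeric", behaviorNoiseSd = "numeric",
    snr = "numeric", mixing = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- object@nSources
    if (n < 4L) msg <- c(msg, "nSources must be >= 4")
    C <- object@envelopeCorr
    if (!all(dim(C) == c(n, n))) msg <- c(msg, "envelopeCorr must be nSources x nSources")
    else {
      if (max(abs(C - t(C))) > 1e-8) msg <- c(msg, "envelopeCorr must be symmetric")
      if (max(abs(diag(C) - 1)) > 1e-8) msg <- c(msg, "envelopeCorr must have unit diagonal")
    }
    if (length(object@envelopeCorrAlt) && !all(dim(object@envelopeCorrAlt) == c(n, n)))
      msg <- c(msg, "envelopeCorrAlt must be empty or nSources x nSources")
    if (object@carrierFreq <= 0) msg <- c(msg, "carrierFreq must be positive")
    if (object@snr < 0) msg <- c(msg, "snr must be >= 0")
    if (object@mixing < 0 || object@mixing >= 1) msg <- c(msg, "mixing must lie in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' EpochSet: per-trial source-space signal tensor
#'
#' @slot signals Numeric array `trials x sources x samples`.
#' @slot sampleRate Sampling rate in Hz (default 500).
#' @slot window Epoch window in seconds relative to stimulus onset
#'   (default `c(-1, 2)`).
#' @slot trialData `data.frame` with one row per trial (task, acoustic
#'   features, and for simulated data the planted statistic column
#'   `planted_stat`).
#' @seealso [simulateEpochs()], [waveletTransform()]
#' @export
setClass("EpochSet",
  representation(signals = "array", sampleRate = "numeric",
                 window = "numeric", trialData = "data.frame"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@signals)
    if (length(d) != 3L) return("signals must be a trials x sources x samples array")
    nsamp <- round(diff(object@window) * object@sampleRate)
    if (d[3] != nsamp)
      msg <- c(msg, sprintf("samples (%d) != window span * sampleRate (%d)", d[3], nsamp))
    if (!all(is.finite(object@signals))) msg <- c(msg, "signals contain non-finite values")
    if (nrow(object@trialData) != d[1])
      msg <- c(msg, "trialData rows != number of trials")
    if (length(msg)) msg else TRUE
  })

#' FrequencyGrid: wavelet analysis grid
#'
#' @slot freqs Center frequencies in Hz, ascending.
#' @slot cycles Number of wavelet cycles (default 6).
#' @slot bandwidthOct Nominal spectral bandwidth in octaves, recorded as
#'   metadata (default 0.5).
#' @seealso [buildGrid()], [waveletTransform()]
#' @export
setClass("FrequencyGrid",
  representation(freqs = "numeric", cycles = "numeric", bandwidthOct = "numeric"),
  validity = function(object) {
    if (is.unsorted(object@freqs, strictly = TRUE)) return("freqs must be strictly ascending")
    if (any(object@freqs <= 0)) return("freqs must be positive")
    if (object@cycles <= 0) return("cycles must be positive")
    TRUE
  })

#' TFRSet: complex spectrotemporal coefficients
#'
#' @slot coeffs Complex array `trials x sources x freqs x times`.
#' @slot times Analysis time points in seconds relative to stimulus onset.
#' @slot freqs Center frequencies in Hz.
#' @slot sampleRate Sampling rate of the underlying epochs in Hz.
#' @slot baselineWindow Two-element numeric, the baseline window in seconds
#'   (default `c(-0.5, 0)`).
#' @seealso [waveletTransform()], [logPowerBaseline()], [envelopeConnectivity()]
#' @export
setClass("TFRSet",
  representation(coeffs = "array", times = "numeric", freqs = "numeric",
                 sampleRate = "numeric", baselineWindow = "numeric"),
  validity = function(object) {
    d <- dim(object@coeffs)
    if (length(d) != 4L) return("coeffs must be trials x sources x freqs x times")
    if (d[3] != length(object@freqs)) return("freq dimension mismatch")
    if (d[4] != length(object@times)) return("time dimension mismatch")
    if (!all(is.finite(Mod(object@coeffs)))) return("coeffs contain non-finite values")
    TRUE
  })

#' ConnectivityStack: per-trial envelope-correlation matrices at one frequency
#'
#' @slot corr Numeric array `trials x N x N`; each slice is a symmetric
#'   correlation matrix with `NA` diagonal.
#' @slot frequency Carrier frequency in Hz.
#' @slot nTimepoints Number of analysis time points each correlation was
#'   estimated over (41 on the default grid).
#' @seealso [envelopeConnectivity()], [networkMetrics()]
#' @export
setClass("ConnectivityStack",
  representation(corr = "array", frequency = "numeric", nTimepoints = "integer"),
  validity = function(object) {
    d <- dim(object@corr)
    if (length(d) != 3L || d[2] != d[3]) return("corr must be trials x N x N")
    off <- object@corr[!is.na(object@corr)]
    if (length(off) && (min(off) < -1 - 1e-8 || max(off) > 1 + 1e-8))
      return("correlations must lie in [-1, 1]")
    TRUE
  })

#' BinaryGraph: fixed-density binary undirected graph
#'
#' @slot adjacency Binary symmetric matrix with zero diagonal.
#' @slot density Requested edge density (fraction of possible edges).
#' @slot retainedWeights Correlation values of the retained edges
#'   (upper-triangle order).
#' @seealso [thresholdDensity()], [globalEfficiency()], [louvainModularity()]
#' @export
setClass("BinaryGraph",
  representation(adjacency = "matrix", density = "numeric",
                 retainedWeights = "numeric"),
  validity = function(object) {
    A <- object@adjacency
    if (nrow(A) != ncol(A)) return("adjacency must be square")
    if (any(A != t(A))) return("adjacency must be symmetric")
    if (any(diag(A) != 0)) return("diagonal must be zero")
    if (!all(A %in% c(0, 1))) return("adjacency must be binary")
    if (sum(A) / 2 != length(object@retainedWeights))
      return("edge count != number of retained weights")
    TRUE
  })

#' NetworkSeries: per-trial graph diagnostics at one frequency
#'
#' @slot trialMetrics `data.frame` with one row per trial and columns
#'   `mean_fc`, `global_efficiency`, `mean_local_efficiency`, `modularity_q`.
#' @slot nodal Named list of `trials x N` matrices: `strength`,
#'   `local_efficiency`, `within_module_z`, `nodal_efficiency`,
#'   `participation` (empty list when nodal metrics were not requested).
#' @slot frequency Frequency in Hz.
#' @slot density Graph density used for thresholding.
#' @seealso [networkMetrics()], [subjectGlm()]
#' @export
setClass("NetworkSeries",
  representation(trialMetrics = "data.frame", nodal = "list",
                 frequency = "numeric", density = "numeric"),
  validity = function(object) {
    need <- c("mean_fc", "global_efficiency", "mean_local_efficiency", "modularity_q")
    if (!all(need %in% names(object@trialMetrics)))
      return(paste("trialMetrics must have columns", paste(need, collapse = ", ")))
    eff <- c(object@trialMetrics$global_efficiency,
             object@trialMetrics$mean_local_efficiency)
    if (any(eff < -1e-12 | eff > 1 + 1e-12)) return("efficiencies must lie in [0, 1]")
    q <- object@trialMetrics$modularity_q
    if (any(q < -0.5 - 1e-12 | q > 1 + 1e-12)) return("modularity Q must lie in [-0.5, 1]")
    TRUE
  })

#' GlmResult: two-level neurobehavioral GLM with a circular-shift null
#'
#' @slot table `data.frame` with one row per frequency: `frequency`,
#'   `beta` (group mean standardized weight), `lo`/`hi` (uncorrected null
#'   percentile bounds), `significant`, `lo_fcr`/`hi_fcr` (FCR-adjusted
#'   bounds, `NA` when nothing was selected), `significant_fcr`.
#' @slot subjectBetas Matrix `subjects x freqs` of per-subject weights.
#' @slot null Array `shifts x freqs` of group-mean null weights.
#' @slot subjectNull Array `shifts x subjects x freqs` of per-subject null
#'   weights (kept for task contrasts).
#' @slot regressor Name of the regressor of interest.
#' @slot alpha Two-sided significance level (default 0.05).
#' @slot fcrLevel Adjusted confidence level `1 - Fs * q / Ft` (NA when no
#'   frequency was selected in the first pass).
#' @seealso [runPipeline()], [fcrCorrect()], [taskContrast()]
#' @export
setClass("GlmResult",
  representation(table = "data.frame", subjectBetas = "matrix", null = "matrix",
                 subjectNull = "array", regressor = "character",
                 alpha = "numeric", fcrLevel = "numeric"),
  validity = function(object) {
    if (nrow(object@table) != ncol(object@null)) return("table rows != null columns")
    if (any(object@table$lo > object@table$hi, na.rm = TRUE))
      return("ci lower must be <= upper")
    TRUE
  })

## ---- accessors ----

#' @describeIn EpochSet-class Number of trials.
#' @param x Object.
#' @export
setMethod("nTrials", "EpochSet", function(x) dim(x@signals)[1])
#' @describeIn EpochSet-class Number of sources.
#' @export
setMethod("nSources", "EpochSet", function(x) dim(x@signals)[2])
#' @describeIn EpochSet-class Sampling rate in Hz.
#' @export
setMethod("sampleRate", "EpochSet", function(x) x@sampleRate)
#' @describeIn EpochSet-class Trial metadata.
#' @export
setMethod("trialData", "EpochSet", function(x) x@trialData)

#' @describeIn TFRSet-class Number of trials.
#' @param x Object.
#' @export
setMethod("nTrials", "TFRSet", function(x) dim(x@coeffs)[1])
#' @describeIn TFRSet-class Number of sources.
#' @export
setMethod("nSources", "TFRSet", function(x) dim(x@coeffs)[2])
#' @describeIn TFRSet-class Wavelet center frequencies.
#' @export
setMethod("frequencies", "TFRSet", function(x) x@freqs)
#' @describeIn TFRSet-class Sampling rate in Hz.
#' @export
setMethod("sampleRate", "TFRSet", function(x) x@sampleRate)

#' @describeIn FrequencyGrid-class Center frequencies.
#' @param x Object.
#' @export
setMethod("frequencies", "FrequencyGrid", function(x) x@freqs)

#' @describeIn ConnectivityStack-class Number of trials.
#' @param x Object.
#' @export
setMethod("nTrials", "ConnectivityStack", function(x) dim(x@corr)[1])
#' @describeIn ConnectivityStack-class Number of sources.
#' @export
setMethod("nSources", "ConnectivityStack", function(x) dim(x@corr)[2])

#' @describeIn NetworkSeries-class Number of trials.
#' @param x Object.
#' @export
setMethod("nTrials", "NetworkSeries", function(x) nrow(x@trialMetrics))

#' Per-trial graph metrics table
#'
#' @param x A [NetworkSeries-class].
#' @return `data.frame` of whole-brain metrics, one row per trial.
#' @export
trialMetrics <- function(x) {
  stopifnot(is(x, "NetworkSeries"))
  x@trialMetrics
}

#' Nodal graph metrics
#'
#' @param x A [NetworkSeries-class].
#' @param which Metric name (`"strength"`, `"local_efficiency"`,
#'   `"within_module_z"`, `"nodal_efficiency"`, `"participation"`), or `NULL`
#'   for the whole list.
#' @return A `trials x N` matrix, or a named list of them.
#' @export
nodalMetrics <- function(x, which = NULL) {
  stopifnot(is(x, "NetworkSeries"))
  if (is.null(which)) x@nodal else x@nodal[[which]]
}

#' Result table of a two-level GLM
#'
#' @param x A [GlmResult-class].
#' @return `data.frame` with one row per frequency.
#' @export
resultTable <- function(x) {
  stopifnot(is(x, "GlmResult"))
  x@table
}

## ---- show methods ----

#' Compact one-line displays for oscnet objects
#'
#' @param object Object to display.
#' @return `invisible(NULL)`.
#' @keywords internal
#' @export
setMethod("show", "TextureSpec", function(object) {
  cat(sprintf(
    "TextureSpec: %d sweeps / %.0f ms, center %.1f Hz %+.2f st, coherence %.2f (%s), slope %.1f oct/s\n",
    object@nSweeps, object@duration * 1000, object@meanCenterFreq,
    object@semitoneDeviation, object@coherence, object@coherentDirection,
    object@slopeMagnitude))
})

setMethod("show", "TextureStimulus", function(object) {
  show(object@spec)
  cat(sprintf("  %d sweeps realized (%d coherent)\n",
              nrow(object@sweeps), sum(object@sweeps$is_coherent)))
})

setMethod("show", "CouplingModel", function(object) {
  cat(sprintf(
    "CouplingModel: %d sources, carrier %.2f Hz, snr %.2f, mixing %.2f\n",
    object@nSources, object@carrierFreq, object@snr, object@mixing))
  cat(sprintf("  behavior slope %.2f (noise sd %.2f); trial-varying network: %s\n",
              object@behaviorSlope, object@behaviorNoiseSd,
              if (length(object@envelopeCorrAlt)) "yes" else "no"))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@signals)
  cat(sprintf("EpochSet: %d trials x %d sources x %d samples @ %g Hz, window [%g, %g] s\n",
              d[1], d[2], d[3], object@sampleRate, object@window[1], object@window[2]))
})

setMethod("show", "FrequencyGrid", function(object) {
  cat(sprintf("FrequencyGrid: %d frequencies %.4g-%.4g Hz, %g cycles\n",
              length(object@freqs), min(object@freqs), max(object@freqs),
              object@cycles))
})

setMethod("show", "TFRSet", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("TFRSet: %d trials x %d sources x %d freqs x %d times (%g to %g s)\n",
              d[1], d[2], d[3], d[4], min(object@times), max(object@times)))
})

setMethod("show", "ConnectivityStack", function(object) {
  d <- dim(object@corr)
  cat(sprintf("ConnectivityStack @ %.4g Hz: %d trials x %d x %d (from %d time points)\n",
              object@frequency, d[1], d[2], d[3], object@nTimepoints))
})

setMethod("show", "BinaryGraph", function(object) {
  n <- nrow(object@adjacency)
  cat(sprintf("BinaryGraph: %d nodes, %d edges (density %.3g)\n",
              n, sum(object@adjacency) / 2, object@density))
})

setMethod("show", "NetworkSeries", function(object) {
  cat(sprintf("NetworkSeries @ %.4g Hz (density %.2g): %d trials, nodal metrics: %s\n",
              object@frequency, object@density, nrow(object@trialMetrics),
              if (length(object@nodal)) paste(names(object@nodal), collapse = ", ")
              else "none"))
})

setMethod("show", "GlmResult", function(object) {
  cat(sprintf("GlmResult for '%s': %d frequencies, %d subjects, %d shifts\n",
              object@regressor, nrow(object@table), nrow(object@subjectBetas),
              nrow(object@null)))
  sig <- object@table$frequency[object@table$significant_fcr]
  cat(if (length(sig)) sprintf("  FCR-significant at: %s Hz\n",
                               paste(signif(sig, 4), collapse = ", "))
      else "  no FCR-significant frequencies\n")
})
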