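#' @import methods
NULL

#' Number of trials in an object
#'
#' @param x An object holding per-trial data (e.g. [EpochSet-class],
#'   [TFRSet-class], [ConnectivityStack-class], [NetworkSeries-class]).
#' @return Integer scalar.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' Number of sources (network nodes) in an object
#'
#' @param x An object holding source-resolved data.
#' @return Integer scalar.
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' Sampling rate accessor
#'
#' @param x An object carrying a sampling rate.
#' @return Sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Frequency accessor
#'
#' @param x An object carrying wavelet center frequencies.
#' @return Numeric vector of frequencies in Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Per-trial metadata accessor
#'
#' @param x An object carrying a trial table.
#' @return A `data.frame` with one row per trial.
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))
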