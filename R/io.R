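## Artifact serialization: CSV for tabular objects, RDS containers for the
## heavy tensors.

#' Write a trial design or behavior table to CSV
#'
#' @param x `data.frame` (e.g. from [makeDesign()] or [simulateBehavior()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrialTable <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a trial design or behavior table from CSV
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
readTrialTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the sweep table of a texture stimulus to CSV
#'
#' @param stim A [TextureStimulus-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSweepTable <- function(stim, path) {
  stopifnot(is(stim, "TextureStimulus"))
  utils::write.csv(stim@sweeps, path, row.names = FALSE)
  invisible(path)
}

#' Save / load pipeline tensors
#'
#' [EpochSet-class], [TFRSet-class], [ConnectivityStack-class] and
#' [NetworkSeries-class] objects are stored as single-object RDS
#' containers; the class is validated on load.
#'
#' @param x Object to save.
#' @param path File path.
#' @return `saveContainer` returns `path` invisibly; `readContainer`
#'   returns the validated object.
#' @export
saveContainer <- function(x, path) {
  stopifnot(is(x, "EpochSet") || is(x, "TFRSet") ||
              is(x, "ConnectivityStack") || is(x, "NetworkSeries"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname saveContainer
#' @export
readContainer <- function(path) {
  x <- readRDS(path)
  if (!(is(x, "EpochSet") || is(x, "TFRSet") ||
        is(x, "ConnectivityStack") || is(x, "NetworkSeries")))
    stop("not a pipeline container: ", path)
  validObject(x)
  x
}

#' Write a GLM result table to CSV
#'
#' @param x A [GlmResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(x, path) {
  stopifnot(is(x, "GlmResult"))
  utils::write.csv(resultTable(x), path, row.names = FALSE)
  invisible(path)
}
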