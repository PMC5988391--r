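## Acoustic texture stimuli ("cloud of sweeps") and the balanced trial design.

#' Construct a texture specification
#'
#' @param duration Texture duration in seconds.
#' @param nSweeps Number of frequency-modulated sweeps.
#' @param sweepDuration Duration of each sweep in seconds.
#' @param meanCenterFreq Mean center frequency in Hz.
#' @param semitoneDeviation Spectral-center deviation in semitones.
#' @param coherence Fraction of sweeps sharing the coherent slope, in (0, 1].
#' @param coherentDirection `"up"` or `"down"`.
#' @param slopeMagnitude Absolute sweep slope in octaves/second.
#' @param freqSpanOctaves Total log-frequency span of sweep start
#'   frequencies in octaves (start frequencies are drawn uniformly over
#'   +/- `freqSpanOctaves / 2` around the spectral center).
#' @return A [TextureSpec-class].
#' @examples
#' textureSpec(coherence = 0.5, semitoneDeviation = -1)
#' @export
textureSpec <- function(duration = 0.4, nSweeps = 72L, sweepDuration = 0.1,
                        meanCenterFreq = 707.1, semitoneDeviation = 0,
                        coherence = 1, coherentDirection = c("up", "down"),
                        slopeMagnitude = 3.3, freqSpanOctaves = 3) {
  new("TextureSpec", duration = duration, nSweeps = as.integer(nSweeps),
      sweepDuration = sweepDuration, meanCenterFreq = meanCenterFreq,
      semitoneDeviation = semitoneDeviation, coherence = coherence,
      coherentDirection = match.arg(coherentDirection),
      slopeMagnitude = slopeMagnitude, freqSpanOctaves = freqSpanOctaves)
}

#' Spectral centers from semitone deviations
#'
#' Each deviation of `d` semitones places a spectral center at
#' `meanFreq * 2^(d/12)`.
#'
#' @param meanFreq Mean center frequency in Hz (positive).
#' @param deviations Numeric vector of deviations in semitones.
#' @return Spectral centers in Hz, ascending.
#' @examples
#' round(spectralCenters(707.1, c(-2, -1, -0.5, -0.25, 0.25, 0.5, 1, 2)))
#' @export
spectralCenters <- function(meanFreq,
                            deviations = c(-2, -1, -0.5, -0.25,
                                           0.25, 0.5, 1, 2)) {
  if (!is.numeric(meanFreq) || length(meanFreq) != 1L || meanFreq <= 0)
    stop("meanFreq must be a single positive number")
  sort(meanFreq * 2^(deviations / 12))
}

#' Realize one acoustic texture
#'
#' Draws sweep onsets uniformly over `[0, duration - sweepDuration]` and
#' start frequencies uniformly in log frequency around the spectral center.
#' `round(coherence * nSweeps)` sweeps get the shared signed slope; the
#' remaining sweeps get `slopeMagnitude` with an independent random sign.
#'
#' @param spec A [TextureSpec-class].
#' @param seed Integer seed; identical `(spec, seed)` give identical stimuli.
#' @return A [TextureStimulus-class].
#' @examples
#' stim <- makeTexture(textureSpec(coherence = 0.25), seed = 1)
#' sum(stim@sweeps$is_coherent)  # 18 of 72
#' @export
makeTexture <- function(spec, seed = NULL) {
  stopifnot(is(spec, "TextureSpec"))
  validObject(spec)
  localSeed(seed, {
    n <- spec@nSweeps
    nCoh <- as.integer(round(spec@coherence * n))
    center <- spec@meanCenterFreq * 2^(spec@semitoneDeviation / 12)
    onset <- stats::runif(n, 0, spec@duration - spec@sweepDuration)
    startFreq <- center * 2^stats::runif(n, -spec@freqSpanOctaves / 2,
                                         spec@freqSpanOctaves / 2)
    cohSlope <- spec@slopeMagnitude *
      if (spec@coherentDirection == "up") 1 else -1
    isCoh <- rep(FALSE, n)
    isCoh[sample.int(n, nCoh)] <- TRUE
    slope <- ifelse(isCoh, cohSlope,
                    spec@slopeMagnitude * sample(c(-1, 1), n, replace = TRUE))
    sw <- data.frame(onset = onset, start_freq = startFreq, slope = slope,
                     is_coherent = isCoh)
    new("TextureStimulus", spec = spec, sweeps = sw)
  })
}

#' Render a texture stimulus to an audio waveform
#'
#' Each sweep contributes a sine with exponentially gliding frequency
#' `f(t) = f0 * 2^(slope * t)` and 5-ms raised-cosine on/off ramps; the sum
#' is peak-normalized to `|x| <= 1`.
#'
#' @param stim A [TextureStimulus-class].
#' @param sampleRate Audio sampling rate in Hz (>= 8000).
#' @param rampDuration On/off ramp duration per sweep in seconds.
#' @return Numeric waveform of length `round(duration * sampleRate)`.
#' @export
synthesizeAudio <- function(stim, sampleRate = 44100, rampDuration = 0.005) {
  stopifnot(is(stim, "TextureStimulus"))
  if (sampleRate < 8000) stop("sampleRate must be >= 8000 Hz")
  sp <- stim@spec
  nSamp <- round(sp@duration * sampleRate)
  x <- numeric(nSamp)
  sw <- stim@sweeps
  if (nrow(sw)) {
    fMax <- max(sw$start_freq * 2^(pmax(sw$slope, 0) * sp@sweepDuration))
    if (fMax > sampleRate / 2)
      warning(sprintf(
        "highest instantaneous frequency (%.0f Hz) exceeds Nyquist (%.0f Hz)",
        fMax, sampleRate / 2))
  }
  nSweepSamp <- round(sp@sweepDuration * sampleRate)
  t <- seq_len(nSweepSamp) / sampleRate
  nRamp <- max(1L, round(rampDuration * sampleRate))
  win <- rep(1, nSweepSamp)
  ramp <- 0.5 * (1 - cos(pi * seq_len(nRamp) / nRamp))
  win[seq_len(nRamp)] <- ramp
  win[nSweepSamp + 1 - seq_len(nRamp)] <- ramp
  for (k in seq_len(nrow(sw))) {
    f0 <- sw$start_freq[k]; m <- sw$slope[k]
    ## phase of an exponential glide: 2*pi * f0 * (2^(m t) - 1) / (m ln 2)
    phase <- if (abs(m) > 1e-12) {
      2 * pi * f0 * (2^(m * t) - 1) / (m * log(2))
    } else 2 * pi * f0 * t
    i0 <- round(sw$onset[k] * sampleRate)
    idx <- i0 + seq_len(nSweepSamp)
    keep <- idx <= nSamp
    x[idx[keep]] <- x[idx[keep]] + (sin(phase) * win)[keep]
  }
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk
  x
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' @param x Numeric waveform in `[-1, 1]` (clipped otherwise).
#' @param path Output file path.
#' @param sampleRate Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
writeWav <- function(x, path, sampleRate = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Generate the balanced trial design
#'
#' Each block holds 128 trials: every combination of sweep direction (2),
#' coherence (4 levels) and spectral center (8 levels) exactly twice, in
#' randomized order. The two tasks (judge the overall pitch vs. the overall
#' sweep direction) alternate from block to block; the response-button label
#' mapping is randomized per trial.
#'
#' @param nBlocks Number of blocks (>= 1).
#' @param seed Integer seed.
#' @param firstTask Task of the first block; by default drawn at random.
#' @return `data.frame` with columns `trial`, `block`, `trial_in_block`,
#'   `task`, `direction`, `coherence`, `spectral_center` (semitones),
#'   `spectral_center_hz`, `rep`, `button_map`.
#' @examples
#' d <- makeDesign(6, seed = 1)
#' table(d$task)  # 384 trials per task
#' @export
makeDesign <- function(nBlocks, seed = NULL,
                       firstTask = c("random", "pitch", "direction")) {
  if (nBlocks < 1) stop("nBlocks must be >= 1")
  firstTask <- match.arg(firstTask)
  localSeed(seed, {
    dirs <- c("up", "down")
    cohs <- c(0.25, 0.5, 0.75, 1)
    devs <- c(-2, -1, -0.5, -0.25, 0.25, 0.5, 1, 2)
    cells <- expand.grid(direction = dirs, coherence = cohs,
                         spectral_center = devs, rep = 1:2,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    t0 <- if (firstTask == "random") sample(c("pitch", "direction"), 1)
          else firstTask
    tasks <- rep(c(t0, setdiff(c("pitch", "direction"), t0)),
                 length.out = nBlocks)
    blocks <- lapply(seq_len(nBlocks), function(b) {
      blk <- cells[sample.int(nrow(cells)), , drop = FALSE]
      blk$block <- b
      blk$task <- tasks[b]
      blk$trial_in_block <- seq_len(nrow(blk))
      blk$button_map <- sample(1:2, nrow(blk), replace = TRUE)
      blk
    })
    d <- do.call(rbind, blocks)
    d$trial <- seq_len(nrow(d))
    d$spectral_center_hz <- 707.1 * 2^(d$spectral_center / 12)
    rownames(d) <- NULL
    d[, c("trial", "block", "trial_in_block", "task", "direction",
          "coherence", "spectral_center", "spectral_center_hz", "rep",
          "button_map")]
  })
}
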