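## Morlet wavelet time-frequency decomposition on the analysis grid, log
## power and baseline correction.

#' Build the wavelet frequency grid
#'
#' Center frequencies are spaced logarithmically in base 2 with exponents
#' from 3 to 5 in steps of 0.25 (8 to 32 Hz), preceded by three lower
#' frequencies at 1, 2 and 4 Hz: 12 frequencies in total. Wavelets use 6
#' cycles; the nominal 0.5-octave bandwidth is kept as metadata.
#'
#' @param lowFreqs Extra low frequencies prepended to the log-spaced part.
#' @param exponents Base-2 exponents of the log-spaced part.
#' @param cycles Number of wavelet cycles.
#' @return A [FrequencyGrid-class].
#' @examples
#' frequencies(buildGrid())
#' @export
buildGrid <- function(lowFreqs = c(1, 2, 4),
                      exponents = seq(3, 5, by = 0.25), cycles = 6) {
  new("FrequencyGrid", freqs = c(lowFreqs, 2^exponents), cycles = cycles,
      bandwidthOct = 0.5)
}

## Frequency response of a unit-energy analytic Morlet wavelet sampled on
## the DFT grid of a length-L signal at rate fs. With sigma_t = cycles /
## (2 pi f0), the continuous transform of pi^(-1/4) sigma_t^(-1/2)
## exp(-t^2/(2 sigma_t^2)) exp(i 2 pi f0 t) is
## pi^(-1/4) sqrt(2 pi sigma_t) exp(-2 pi^2 sigma_t^2 (f - f0)^2).
morletSpectrum <- function(f0, L, fs, cycles) {
  sigmaT <- cycles / (2 * pi * f0)
  f <- c(seq(0, floor(L / 2)), seq(-ceiling(L / 2) + 1, -1)) * (fs / L)
  pi^(-1 / 4) * sqrt(2 * pi * sigmaT) * exp(-2 * pi^2 * sigmaT^2 * (f - f0)^2)
}

#' Morlet wavelet transform of source-space epochs
#'
#' Complex spectrotemporal coefficients are computed by multiplication in
#' the frequency domain with unit-energy analytic Morlet wavelets and
#' evaluated at the analysis time points (default -0.5 to +1.5 s in steps of
#' 0.05 s: 41 points). For frequencies below `mirrorBelow` the epoch is
#' mirror-extended symmetrically on both sides before convolution, so that
#' the long wavelets at 1-4 Hz are supported over the whole analysis window;
#' coefficients at higher frequencies are unaffected by the extension.
#'
#' @param epochs An [EpochSet-class].
#' @param grid A [FrequencyGrid-class] (default [buildGrid()]).
#' @param times Analysis time points in seconds (default
#'   `seq(-0.5, 1.5, 0.05)`).
#' @param mirror Apply mirror extension for low frequencies (default TRUE).
#' @param mirrorBelow Frequencies below this value (Hz) use the extension.
#' @param baselineWindow Baseline window stored for [logPowerBaseline()].
#' @return A [TFRSet-class].
#' @export
waveletTransform <- function(epochs, grid = buildGrid(),
                             times = seq(-0.5, 1.5, by = 0.05),
                             mirror = TRUE, mirrorBelow = 8,
                             baselineWindow = c(-0.5, 0)) {
  stopifnot(is(epochs, "EpochSet"), is(grid, "FrequencyGrid"))
  fs <- epochs@sampleRate
  d <- dim(epochs@signals)
  nT <- d[1]; nS <- d[2]; L <- d[3]
  freqs <- grid@freqs
  ## sample index of each analysis time point (signal sample k covers time
  ## window[1] + (k-1)/fs at its left edge; times must land on samples)
  idx <- round((times - epochs@window[1]) * fs) + 1L
  if (any(idx < 1L | idx > L))
    stop("analysis time points fall outside the epoch")
  useMirror <- mirror & freqs < mirrorBelow
  Lm <- 3L * L
  ## check wavelet support at the lowest frequency
  sigmaT <- grid@cycles / (2 * pi * min(freqs))
  span <- if (any(useMirror)) Lm / fs else L / fs
  if (6 * sigmaT > span)
    stop("epoch too short for the lowest frequency, even after extension")
  dt <- 1 / fs
  ## Per frequency, precompute the significant spectral bins of the wavelet
  ## and the inverse-DFT synthesis matrix restricted to the analysis time
  ## points (the wavelet spectrum is a narrow Gaussian, so almost all bins
  ## are numerically zero and the coefficients can be synthesized directly
  ## at the 41 output samples instead of by a full inverse FFT).
  synth <- lapply(seq_along(freqs), function(k) {
    Lk <- if (useMirror[k]) Lm else L
    off <- if (useMirror[k]) L else 0L
    psi <- morletSpectrum(freqs[k], Lk, fs, grid@cycles)
    sel <- which(psi > max(psi) * 1e-9)
    E <- exp(2i * pi * outer(off + idx - 1, sel - 1) / Lk)
    list(sel = sel, W = E * rep(psi[sel] * dt / Lk, each = length(idx)))
  })
  coeffs <- array(complex(real = 0), dim = c(nT, nS, length(freqs),
                                             length(times)))
  for (tr in seq_len(nT)) {
    x <- matrix(aperm(epochs@signals[tr, , , drop = FALSE],
                      c(3, 2, 1)), L, nS)                  # L x nS
    Fx <- stats::mvfft(x)
    Fm <- if (any(useMirror))
      stats::mvfft(rbind(x[L:1, , drop = FALSE], x, x[L:1, , drop = FALSE]))
    else NULL
    for (k in seq_along(freqs)) {
      Fk <- if (useMirror[k]) Fm else Fx
      coeffs[tr, , k, ] <-
        t(synth[[k]]$W %*% Fk[synth[[k]]$sel, , drop = FALSE])
    }
  }
  new("TFRSet", coeffs = coeffs, times = times, freqs = freqs,
      sampleRate = fs, baselineWindow = baselineWindow)
}

#' Baseline-corrected log power
#'
#' Log power is `log(|coefficient|^2)`, floored at a small fraction of the
#' maximum power; the mean log power over the baseline window is subtracted
#' per trial, source and frequency (trial-averaged baseline available as an
#' option).
#'
#' @param tfr A [TFRSet-class].
#' @param baselineWindow Baseline window in seconds (default from `tfr`).
#' @param perTrial Subtract a per-trial baseline (default TRUE); otherwise
#'   the baseline is averaged over trials first.
#' @param epsilonFraction Power floor as a fraction of the maximum power.
#' @return Numeric array `trials x sources x freqs x times` of
#'   baseline-corrected log power.
#' @export
logPowerBaseline <- function(tfr, baselineWindow = NULL, perTrial = TRUE,
                             epsilonFraction = 1e-30) {
  stopifnot(is(tfr, "TFRSet"))
  if (is.null(baselineWindow)) baselineWindow <- tfr@baselineWindow
  inBase <- tfr@times >= baselineWindow[1] & tfr@times <= baselineWindow[2]
  if (!any(inBase)) stop("baseline window contains no analysis time points")
  pow <- Mod(tfr@coeffs)^2
  eps <- epsilonFraction * max(pow)
  if (eps == 0) eps <- .Machine$double.xmin
  if (any(pow < eps)) warning("zero power floored at epsilon before log")
  lp <- log(pmax(pow, eps))
  base <- apply(lp[, , , inBase, drop = FALSE], 1:3, mean)
  if (!perTrial) base <- array(rep(colMeans(base), each = dim(lp)[1]),
                               dim = dim(base))
  sweep(lp, 1:3, base, `-`)
}
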