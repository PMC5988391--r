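## Source-space oscillation simulator with a planted envelope-coupling
## network, and a behavioral observer whose decision speed tracks a chosen
## per-trial network statistic. Ground truth for parameter recovery.

#' Construct a coupling model
#'
#' @param nSources Number of sources (>= 4).
#' @param carrierFreq Oscillation carrier frequency in Hz.
#' @param envelopeCorr Target log-envelope correlation matrix (symmetric,
#'   unit diagonal, positive semi-definite). Projected to the nearest PSD
#'   matrix with a warning if needed.
#' @param envelopeCorrAlt Optional second endpoint: when given, the per-trial
#'   target correlation is `w * envelopeCorr + (1 - w) * envelopeCorrAlt`
#'   with a latent `w ~ U(0, 1)` per trial, recorded as the planted
#'   per-trial statistic.
#' @param envelopeCutoff Low-pass cutoff of the log-envelope process in Hz
#'   (default 2, within the wavelet passband at a 20 Hz carrier, so that
#'   envelopes fluctuate within the per-trial analysis window; slow
#'   across-trial network drift is carried by the latent mixing weight).
#' @param logEnvSd SD of the log amplitude envelope.
#' @param behaviorSlope Planted effect of the z-scored statistic on decision
#'   speed (speed units per SD).
#' @param behaviorNoiseSd SD of trial-level speed noise.
#' @param snr Oscillation-to-background variance ratio.
#' @param mixing Instantaneous linear leakage coefficient in [0, 1).
#' @return A [CouplingModel-class].
#' @export
couplingModel <- function(nSources = 64L, carrierFreq = 20,
                          envelopeCorr = diag(nSources),
                          envelopeCorrAlt = matrix(numeric(0), 0, 0),
                          envelopeCutoff = 2, logEnvSd = 0.75,
                          behaviorSlope = 0.3, behaviorNoiseSd = 0.5,
                          snr = 3, mixing = 0) {
  fix <- function(C, what) {
    if (!length(C)) return(C)
    ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      warning(what, " is not positive semi-definite; projecting to nearest PSD")
      C <- nearestPSD(C)
    }
    C
  }
  new("CouplingModel", nSources = as.integer(nSources),
      carrierFreq = carrierFreq,
      envelopeCorr = fix(envelopeCorr, "envelopeCorr"),
      envelopeCorrAlt = fix(envelopeCorrAlt, "envelopeCorrAlt"),
      envelopeCutoff = envelopeCutoff, logEnvSd = logEnvSd,
      behaviorSlope = behaviorSlope, behaviorNoiseSd = behaviorNoiseSd,
      snr = snr, mixing = mixing)
}

#' Block-modular correlation matrix
#'
#' A correlation matrix with `nModules` equal blocks: `within` correlation
#' inside each block and `between` across blocks. Used as the segregated
#' endpoint of the per-trial network manipulation.
#'
#' @param nSources Number of sources (multiple of `nModules` preferred).
#' @param nModules Number of modules.
#' @param within Within-module correlation.
#' @param between Between-module correlation.
#' @return An `nSources x nSources` correlation matrix.
#' @export
modularCorrelation <- function(nSources, nModules = 4, within = 0.6,
                               between = 0.05) {
  mod <- sort(rep(seq_len(nModules), length.out = nSources))
  C <- matrix(between, nSources, nSources)
  for (m in seq_len(nModules)) {
    idx <- which(mod == m)
    C[idx, idx] <- within
  }
  diag(C) <- 1
  C
}

#' Uniform (integrated) correlation matrix
#'
#' All off-diagonal correlations equal; the integrated endpoint of the
#' per-trial network manipulation.
#'
#' @param nSources Number of sources.
#' @param rho Common off-diagonal correlation.
#' @return An `nSources x nSources` correlation matrix.
#' @export
uniformCorrelation <- function(nSources, rho = 0.25) {
  C <- matrix(rho, nSources, nSources)
  diag(C) <- 1
  C
}

## Smooth low-pass Gaussian process, generated at a coarse envelope rate and
## linearly interpolated up to the signal rate. Columns are correlated via
## the Cholesky factor of the target matrix, then identically filtered, so
## cross-source correlations are preserved.
slowLogEnvelopes <- function(cholC, nSamples, sampleRate, cutoff, sdLog) {
  n <- ncol(cholC)
  envRate <- max(8 * cutoff, 4)           # coarse rate, Hz
  pad <- 3                                # generate 3x length, keep center
  nEnv <- ceiling(nSamples / sampleRate * envRate)
  nGen <- pad * nEnv
  Z <- matrix(stats::rnorm(nGen * n), nGen, n) %*% cholC
  ## Gaussian low-pass in the frequency domain (SD = cutoff)
  f <- c(seq(0, floor(nGen / 2)), seq(-ceiling(nGen / 2) + 1, -1)) *
    (envRate / nGen)
  H <- exp(-0.5 * (f / cutoff)^2)
  Zf <- stats::mvfft(Z) * H
  Zs <- Re(stats::mvfft(Zf, inverse = TRUE)) / nGen
  keep <- floor((pad - 1) / 2 * nEnv) + seq_len(nEnv)
  Zs <- Zs[keep, , drop = FALSE]
  ## restore unit variance per column, then scale to sdLog
  sds <- colSdsFast(Zs)
  sds[sds == 0] <- 1
  Zs <- Zs * rep(sdLog / sds, each = nEnv)
  ## linear interpolation up to the signal rate (uniform coarse grid)
  tEnv <- (seq_len(nEnv) - 0.5) / envRate
  tSig <- (seq_len(nSamples) - 0.5) / sampleRate
  pos <- (tSig - tEnv[1]) * envRate + 1
  lo <- pmin(pmax(floor(pos), 1L), nEnv - 1L)
  frac <- pmin(pmax(pos - lo, 0), 1)
  Zs[lo, , drop = FALSE] * (1 - frac) + Zs[lo + 1L, , drop = FALSE] * frac
}

colSdsFast <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X * X) / n - mu * mu, 0) * n / (n - 1))
}

## 1/f (pink) background noise, unit variance per column, synthesized
## directly in the frequency domain.
pinkNoise <- function(nSamples, n) {
  f <- c(seq(0, floor(nSamples / 2)), seq(-ceiling(nSamples / 2) + 1, -1))
  g <- 1 / sqrt(pmax(abs(f), 1))
  Zf <- matrix(complex(real = stats::rnorm(nSamples * n),
                       imaginary = stats::rnorm(nSamples * n)),
               nSamples, n) * g
  X <- Re(stats::mvfft(Zf, inverse = TRUE)) / nSamples
  sds <- colSdsFast(X)
  sds[sds == 0] <- 1
  X * rep(1 / sds, each = nSamples)
}

#' Simulate source-space oscillatory epochs
#'
#' Per trial, each source signal is a carrier-frequency oscillation whose
#' instantaneous amplitude is a slowly varying log-normal envelope
#' (correlated across sources per the model's target matrix, with
#' independent carrier phases across sources) plus pink background noise at
#' the stated SNR. When the model defines two endpoint matrices, a latent
#' mixing weight `w ~ U(0, 1)` per trial interpolates between them and is
#' stored in `trialData$planted_stat`.
#'
#' @param model A [CouplingModel-class].
#' @param design A trial `data.frame` from [makeDesign()] (or any data frame
#'   with one row per trial), or a plain trial count.
#' @param seed Integer seed.
#' @param window Epoch window in seconds (default `c(-1, 2)`).
#' @param sampleRate Sampling rate in Hz (default 500).
#' @return An [EpochSet-class].
#' @export
simulateEpochs <- function(model, design, seed = NULL, window = c(-1, 2),
                           sampleRate = 500) {
  stopifnot(is(model, "CouplingModel"))
  validObject(model)
  if (is.numeric(design) && length(design) == 1L)
    design <- data.frame(trial = seq_len(design))
  nT <- nrow(design)
  nS <- model@nSources
  nSamp <- round(diff(window) * sampleRate)
  tSec <- window[1] + (seq_len(nSamp) - 0.5) / sampleRate
  varyNet <- length(model@envelopeCorrAlt) > 0
  localSeed(seed, {
    w <- if (varyNet) stats::runif(nT) else rep(NA_real_, nT)
    sig <- array(0, dim = c(nT, nS, nSamp))
    chConst <- if (!varyNet) safeChol(model@envelopeCorr) else NULL
    M <- NULL
    if (model@mixing > 0) {
      a <- model@mixing
      M <- matrix(a / (nS - 1), nS, nS)
      diag(M) <- 1 - a
    }
    for (tr in seq_len(nT)) {
      ch <- if (varyNet) {
        C <- w[tr] * model@envelopeCorr + (1 - w[tr]) * model@envelopeCorrAlt
        diag(C) <- 1
        safeChol(C)
      } else chConst
      logA <- slowLogEnvelopes(ch, nSamp, sampleRate, model@envelopeCutoff,
                               model@logEnvSd)
      A <- exp(logA)
      phi <- stats::runif(nS, 0, 2 * pi)
      osc <- A * cos(outer(2 * pi * model@carrierFreq * tSec, phi, `+`))
      x <- if (model@snr > 0) {
        bg <- pinkNoise(nSamp, nS)
        oscSd <- colSdsFast(osc)
        osc + bg * rep(oscSd / sqrt(model@snr), each = nSamp)
      } else pinkNoise(nSamp, nS)
      if (!is.null(M)) x <- x %*% M
      sig[tr, , ] <- t(x)
    }
    td <- as.data.frame(design)
    td$planted_stat <- w
    new("EpochSet", signals = sig, sampleRate = sampleRate, window = window,
        trialData = td)
  })
}

#' Simulate trial-by-trial behavior coupled to a network statistic
#'
#' Decision speed per trial is an affine function of the z-scored planted
#' statistic, `speed = baseSpeed + behaviorSlope * z + noise`, floored at
#' a small positive value; response time is `1/speed`. Correctness is
#' Bernoulli with probability `targetAccuracy`; a configurable fraction of
#' trials gets no response (`NA` response time).
#'
#' @param model A [CouplingModel-class] (supplies slope and noise SD).
#' @param perTrialStat Numeric vector, the planted statistic per trial.
#' @param targetAccuracy Mean accuracy to calibrate to, in (0.5, 1).
#' @param seed Integer seed.
#' @param baseSpeed Mean decision speed in 1/s (default 1.8).
#' @param noResponseRate Fraction of no-response trials (default 0.01).
#' @return `data.frame` with columns `correct` (0/1), `response_time`
#'   (s, `NA` on no-response trials) and `planted_stat`.
#' @export
simulateBehavior <- function(model, perTrialStat, targetAccuracy = 0.70,
                             seed = NULL, baseSpeed = 1.8,
                             noResponseRate = 0.01) {
  stopifnot(is(model, "CouplingModel"))
  if (!all(is.finite(perTrialStat))) stop("perTrialStat must be finite")
  if (targetAccuracy <= 0.5 || targetAccuracy >= 1)
    stop("targetAccuracy must lie in (0.5, 1)")
  n <- length(perTrialStat)
  z <- if (stats::sd(perTrialStat) > 0)
    (perTrialStat - mean(perTrialStat)) / stats::sd(perTrialStat)
  else rep(0, n)
  localSeed(seed, {
    speed <- baseSpeed + model@behaviorSlope * z +
      stats::rnorm(n, 0, model@behaviorNoiseSd)
    speed <- pmax(speed, 0.05)
    rt <- 1 / speed
    rt[stats::runif(n) < noResponseRate] <- NA_real_
    correct <- stats::rbinom(n, 1, targetAccuracy)
    data.frame(correct = correct, response_time = rt,
               planted_stat = perTrialStat)
  })
}
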