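## Two-level neurobehavioral GLM, circular-shift permutation null,
## FCR-corrected inference, task contrasts and trial-lag cross-correlation.

#' Single-subject rank-based GLM weight
#'
#' All variables are rank-transformed and z-scored, then the behavioral
#' series is regressed by OLS on the regressor of interest plus covariates
#' and an intercept. With a single predictor and no covariates the returned
#' weight equals Spearman's rho.
#'
#' @param y Behavioral series (decision speed or moving-average accuracy).
#' @param x Regressor of interest (oscillatory power or a network metric).
#' @param covariates Optional `data.frame` of acoustic covariates
#'   (spectral center, coherence).
#' @param valid Optional logical mask of usable trials (>= 10 needed).
#' @return Standardized weight of `x` (numeric scalar).
#' @export
subjectGlm <- function(y, x, covariates = NULL, valid = NULL) {
  X <- data.frame(x = x)
  if (!is.null(covariates)) X <- cbind(X, as.data.frame(covariates))
  if (is.null(valid)) valid <- rep(TRUE, length(y))
  if (sum(valid & is.finite(y)) < 10) stop("need at least 10 valid trials")
  fitRankGlm(y, X, valid)$weights[["x"]]
}

## Pseudo-inverse row for the regressor of interest, after rank-z of all
## columns; shared by the null machinery. Returns list(h, beta, Zy).
rankGlmOperator <- function(y, x, covariates = NULL, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(y))
  ok <- valid & is.finite(y) & is.finite(x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[ok, , drop = FALSE]
    Zc <- vapply(covariates, rankZscore, numeric(sum(ok)))
  } else Zc <- NULL
  Zy <- rankZscore(y[ok])
  Zx <- rankZscore(x[ok])
  D <- cbind(1, Zx, Zc)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("rank-deficient design in null machinery")
  H <- solve(crossprod(D), t(D))
  list(h = H[2, ], Zy = Zy, beta = sum(H[2, ] * Zy))
}

#' Circular-shift null distribution of the group mean weight
#'
#' For shift k = 1..`nShifts`, every subject's behavioral series is rotated
#' by k trials with wrap-around (the same offset for all subjects), the
#' subject-level GLM weights are recomputed, and their group mean is stored.
#' Rotation preserves the value multiset and the circular autocorrelation of
#' each series, so the null respects the behavioral autocorrelation
#' structure. Because ranks are invariant under rotation, the rotated rank-z
#' series is the rotation of the rank-z series, which makes all shifts one
#' matrix product per subject.
#'
#' @param y List of per-subject behavioral series.
#' @param x List of per-subject regressor series.
#' @param covariates Optional list of per-subject covariate data frames.
#' @param valid Optional list of per-subject logical masks.
#' @param nShifts Number of circular shifts (default 350; must not exceed
#'   the smallest per-subject trial count).
#' @param randomOffsets Draw independent random offsets per subject instead
#'   of the common offsets 1..`nShifts` (default FALSE).
#' @param seed Seed used when `randomOffsets = TRUE`.
#' @return List with `group` (numeric vector of `nShifts` group-mean null
#'   weights), `subject` (matrix `nShifts x subjects`), and `observed`
#'   (list with `group` mean and `subject` vector of observed weights).
#' @export
circularNull <- function(y, x, covariates = NULL, valid = NULL,
                         nShifts = 350L, randomOffsets = FALSE, seed = 1L) {
  S <- length(y)
  stopifnot(length(x) == S)
  if (is.null(covariates)) covariates <- vector("list", S)
  if (is.null(valid)) valid <- vector("list", S)
  B <- matrix(NA_real_, nShifts, S)
  obs <- numeric(S)
  for (s in seq_len(S)) {
    op <- rankGlmOperator(y[[s]], x[[s]], covariates[[s]], valid[[s]])
    n <- length(op$Zy)
    if (nShifts > n)
      stop("nShifts must not exceed the per-subject trial count (", n, ")")
    obs[s] <- op$beta
    offsets <- if (randomOffsets)
      localSeed(childSeed(seed, s), sample.int(n, nShifts, replace = TRUE))
    else seq_len(nShifts)
    idx <- outer(seq_len(n), offsets, function(i, k) ((i + k - 1L) %% n) + 1L)
    Y <- matrix(op$Zy[idx], n, nShifts)
    B[, s] <- as.vector(op$h %*% Y)
  }
  list(group = rowMeans(B), subject = B,
       observed = list(group = mean(obs), subject = obs))
}

#' Two-sided percentile significance against a null distribution
#'
#' The observed group mean weight is significant if it exceeds the
#' `100 * (1 - alpha/2)` percentile or falls below the `100 * alpha/2`
#' percentile of the null distribution.
#'
#' @param observed Observed group mean weight.
#' @param null Numeric vector of null weights.
#' @param alpha Two-sided level (default 0.05).
#' @return List with `significant` (logical) and `ci` (the two percentile
#'   bounds).
#' @export
assessSignificance <- function(observed, null, alpha = 0.05) {
  if (!length(null)) stop("null distribution is empty")
  ci <- unname(stats::quantile(null, c(alpha / 2, 1 - alpha / 2)))
  list(significant = observed < ci[1] || observed > ci[2], ci = ci)
}

#' False coverage-statement rate (FCR) correction across frequencies
#'
#' Pass 1 selects the frequencies whose `1 - q` null percentile interval
#' excludes the observed value. Pass 2 rebuilds the intervals for all
#' frequencies at the inflated confidence level `1 - Fs * q / Ft` (`Fs` =
#' number selected, `Ft` = total number of bins tested) and keeps only the
#' selected frequencies still excluded.
#'
#' @param observed Numeric vector of observed group mean weights per
#'   frequency.
#' @param null Matrix `shifts x frequencies` of null weights.
#' @param q Tolerated false coverage rate (default 0.05).
#' @param Ft Total number of frequency bins tested (default
#'   `length(observed)`).
#' @return `data.frame` with columns `observed`, `lo`, `hi`, `selected`,
#'   `lo_fcr`, `hi_fcr`, `significant`, and attribute `fcrLevel`.
#' @export
fcrCorrect <- function(observed, null, q = 0.05, Ft = length(observed)) {
  nF <- length(observed)
  stopifnot(ncol(null) == nF, Ft >= nF)
  ci <- apply(null, 2, stats::quantile, probs = c(q / 2, 1 - q / 2))
  selected <- observed < ci[1, ] | observed > ci[2, ]
  Fs <- sum(selected)
  out <- data.frame(observed = observed, lo = ci[1, ], hi = ci[2, ],
                    selected = selected, lo_fcr = NA_real_,
                    hi_fcr = NA_real_, significant = FALSE)
  level <- NA_real_
  if (Fs > 0) {
    alpha2 <- Fs * q / Ft
    level <- 1 - alpha2
    ci2 <- apply(null, 2, stats::quantile,
                 probs = c(alpha2 / 2, 1 - alpha2 / 2))
    out$lo_fcr <- ci2[1, ]
    out$hi_fcr <- ci2[2, ]
    out$significant <- selected &
      (observed < ci2[1, ] | observed > ci2[2, ])
  }
  attr(out, "fcrLevel") <- level
  out
}

#' Task contrast of regression weights
#'
#' Mean paired difference of per-subject weights between the two tasks,
#' tested against the circular-shift null of paired differences (the same
#' shift index pairs the two tasks' null weights).
#'
#' @param betaA,betaB Per-subject observed weights (equal length).
#' @param nullA,nullB Per-subject null weight matrices `shifts x subjects`
#'   from [circularNull()].
#' @param alpha Two-sided level.
#' @return List with `difference` (mean of `betaA - betaB`), `null`
#'   (vector of null mean differences), `significant`, `ci`.
#' @export
taskContrast <- function(betaA, betaB, nullA, nullB, alpha = 0.05) {
  if (length(betaA) != length(betaB)) stop("subjects must be paired")
  if (!all(dim(nullA) == dim(nullB))) stop("null matrices must be paired")
  d <- mean(betaA - betaB)
  nullD <- rowMeans(nullA - nullB)
  sig <- assessSignificance(d, nullD, alpha)
  list(difference = d, null = nullD, significant = sig$significant,
       ci = sig$ci)
}

#' One-sample exact permutation (sign-flip) test
#'
#' Tests whether the mean of per-subject weights differs from zero by
#' enumerating all sign flips (exact for <= `maxExact` subjects; Monte
#' Carlo beyond that).
#'
#' @param beta Per-subject weights.
#' @param maxExact Maximum subjects for full enumeration (default 16).
#' @param nMC Monte Carlo draws beyond that.
#' @param seed Seed for the Monte Carlo fallback.
#' @return List with `statistic` (mean), `p` (two-sided).
#' @export
exactPermTest <- function(beta, maxExact = 16L, nMC = 10000L, seed = 1L) {
  n <- length(beta)
  m <- mean(beta)
  if (n <= maxExact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    nullM <- as.vector(signs %*% beta) / n
    p <- mean(abs(nullM) >= abs(m) - 1e-12)
  } else {
    nullM <- localSeed(seed, vapply(seq_len(nMC), function(i)
      mean(beta * sample(c(-1, 1), n, replace = TRUE)), numeric(1)))
    p <- (1 + sum(abs(nullM) >= abs(m) - 1e-12)) / (1 + nMC)
  }
  list(statistic = m, p = p)
}

#' Rank-based cross-correlation over trial lags
#'
#' Spearman correlation between the behavioral series and the metric series
#' at integer trial lags. The value at lag `l` is
#' `cor(y[t], x[t + l])`: a peak at a negative lag means the metric leads
#' behavior. The lag-0 value equals the single-predictor [subjectGlm()]
#' weight.
#'
#' @param y Behavioral series.
#' @param x Metric series (same length).
#' @param maxLag Maximum absolute lag in trials.
#' @return `data.frame` with columns `lag` and `r`.
#' @export
crosscorrLag <- function(y, x, maxLag = 10L) {
  n <- length(y)
  stopifnot(length(x) == n, maxLag < n)
  lags <- seq(-maxLag, maxLag)
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      yi <- y[seq_len(n - l)]; xi <- x[seq_len(n - l) + l]
    } else {
      yi <- y[seq_len(n + l) - l]; xi <- x[seq_len(n + l)]
    }
    stats::cor(yi, xi, method = "spearman")
  }, numeric(1))
  data.frame(lag = lags, r = r)
}
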