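## Behavioral time series (moving-average accuracy, decision speed) and the
## rank-based behavior-vs-acoustics regression.

#' Moving-average accuracy
#'
#' Centered moving mean of a binary correctness series with a rectangular
#' unit-height window (default length 4). The window shrinks at the series
#' edges so the output length equals the input length.
#'
#' @param correct Binary (0/1) vector.
#' @param window Window length in trials (>= 1, <= series length).
#' @param align `"center"` (default) or `"trailing"`.
#' @return Numeric vector of the same length as `correct`.
#' @examples
#' movingAccuracy(rep(c(1, 0), 10))  # interior values 0.5
#' @export
movingAccuracy <- function(correct, window = 4L, align = c("center",
                                                           "trailing")) {
  align <- match.arg(align)
  n <- length(correct)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window must not exceed the series length")
  cs <- c(0, cumsum(correct))
  if (align == "center") {
    lo <- pmax(seq_len(n) - floor(window / 2), 1L)
    hi <- pmin(lo + window - 1L, n)
    lo <- pmax(hi - window + 1L, 1L)
  } else {
    hi <- seq_len(n)
    lo <- pmax(hi - window + 1L, 1L)
  }
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Decision speed from response times
#'
#' Decision speed is the reciprocal response time; trials with no response
#' (`NA`) are flagged invalid and excluded downstream.
#'
#' @param rt Response times in seconds; positive or `NA`.
#' @return `data.frame` with columns `speed` (1/s, `NA` where invalid) and
#'   `valid` (logical).
#' @examples
#' decisionSpeed(c(0.5, NA, 0.4))$speed
#' @export
decisionSpeed <- function(rt) {
  if (any(rt <= 0, na.rm = TRUE)) stop("response times must be positive")
  valid <- !is.na(rt)
  data.frame(speed = ifelse(valid, 1 / rt, NA_real_), valid = valid)
}

#' Rank-transform and z-score a series
#'
#' Values are ranked (average ranks for ties) and standardized to mean 0 and
#' SD 1 using the population (1/n) denominator. Any strictly monotone
#' transform of the input gives identical output.
#'
#' @param x Numeric vector with at least 3 finite values.
#' @return Numeric vector of rank z-scores.
#' @examples
#' rankZ(c(3, 1, 2))
#' @export
rankZ <- function(x) {
  if (sum(is.finite(x)) < 3) stop("rankZ needs at least 3 finite values")
  rankZscore(x)
}

#' Regress behavior on acoustic stimulus features
#'
#' Per-subject ordinary least squares of the rank-z behavioral series on
#' rank-z acoustic features plus an intercept; at the group level the mean
#' weight over subjects is tested with a one-sample exact permutation
#' (sign-flip) test.
#'
#' @param y Behavioral series (one subject), or a list of series (one per
#'   subject) for a group-level fit.
#' @param features `data.frame` of acoustic features (columns e.g.
#'   `spectral_center`, `coherence`), or a list of such data frames.
#' @param valid Optional logical mask (or list of masks) of trials to use.
#' @return For a single subject, a named vector of standardized weights.
#'   For a group, a list with `subjectWeights` (matrix subjects x features),
#'   `meanWeights`, and `p` (permutation p-value per feature).
#' @export
behaviorVsAcoustics <- function(y, features, valid = NULL) {
  if (!is.list(y) || is.data.frame(y)) {
    return(fitRankGlm(y, features, valid)$weights)
  }
  if (is.data.frame(features)) features <- rep(list(features), length(y))
  if (is.null(valid)) valid <- vector("list", length(y))
  W <- t(mapply(function(ys, fs, vs) fitRankGlm(ys, fs, vs)$weights,
                y, features, valid))
  p <- apply(W, 2, function(b) exactPermTest(b)$p)
  list(subjectWeights = W, meanWeights = colMeans(W), p = p)
}

## Rank-z OLS fit shared by behaviorVsAcoustics and subjectGlm.
fitRankGlm <- function(y, X, valid = NULL) {
  X <- as.data.frame(X)
  if (is.null(valid)) valid <- rep(TRUE, length(y))
  valid <- valid & is.finite(y) & Reduce(`&`, lapply(X, is.finite))
  y <- y[valid]
  X <- X[valid, , drop = FALSE]
  Zy <- rankZscore(y)
  Zx <- vapply(X, rankZscore, numeric(nrow(X)))
  D <- cbind(`(intercept)` = 1, Zx)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    drop <- setdiff(colnames(D), colnames(D)[qrD$pivot[seq_len(qrD$rank)]])
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qrD, Zy)
  list(weights = beta[-1], intercept = beta[1], n = length(y))
}
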