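## Per-trial all-to-all orthogonalized power-envelope correlation.

#' Orthogonalized power envelope of one signal given another
#'
#' Returns the power envelope of the component of `y` orthogonal to `x` at
#' each time point, `|Im(y * conj(x) / |x|)|^2`. Orthogonalization removes
#' the instantaneous zero-lag component shared between two complex spectral
#' signals, suppressing field-spread / leakage artifacts before envelope
#' correlation.
#'
#' @param x,y Complex spectral series of equal length (same frequency).
#' @return Real vector of orthogonalized power; time points where
#'   `|x| == 0` are `NA` (excluded).
#' @examples
#' x <- complex(real = rnorm(41), imaginary = rnorm(41))
#' max(orthogonalize(x, 2i * x))  # collinear: ~0
#' @export
orthogonalize <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  m <- Mod(x)
  out <- rep(NA_real_, length(x))
  ok <- m > 0
  out[ok] <- Im(y[ok] * Conj(x[ok]) / m[ok])^2
  out
}

#' All-to-all envelope correlation matrix for one trial
#'
#' For each ordered source pair (i, j), the Pearson correlation between the
#' log power of i and the log orthogonalized power of j given i over the
#' analysis time points; the undirected coupling is the mean of the two
#' directions and the matrix is symmetrized. Pairs with a constant envelope
#' get a 0 with a warning.
#'
#' @param X Complex matrix `sources x times` of spectral coefficients at one
#'   frequency (>= 10 time points).
#' @param orthogonalized Use the orthogonalization step (default TRUE); when
#'   FALSE, plain log-power correlations are returned (for leakage
#'   comparisons).
#' @param epsilonFraction Power floor, as a fraction of the trial's maximum
#'   power, applied before the log.
#' @return Symmetric `N x N` matrix with `NA` diagonal.
#' @export
envelopeCorrTrial <- function(X, orthogonalized = TRUE,
                              epsilonFraction = 1e-30) {
  if (!is.matrix(X) || !is.complex(X)) stop("X must be a complex matrix")
  N <- nrow(X); Tn <- ncol(X)
  if (Tn < 10) stop("need at least 10 time points")
  pow <- Mod(X)^2
  eps <- epsilonFraction * max(pow)
  if (eps == 0) eps <- .Machine$double.xmin
  P <- log(pmax(pow, eps))
  hadConstant <- FALSE
  if (!orthogonalized) {
    R <- suppressWarnings(stats::cor(t(P)))
    if (anyNA(R)) { hadConstant <- TRUE; R[is.na(R)] <- 0 }
  } else {
    R <- matrix(0, N, N)
    Xt <- t(X)                            # times x sources
    Pt <- t(P)
    Pc <- Pt - rep(colMeans(Pt), each = Tn)
    Pn <- Pc / rep(sqrt(colSums(Pc^2)), each = Tn)
    anyZero <- any(Mod(X) == 0)
    for (i in seq_len(N)) {
      xi <- Xt[, i]
      m <- Mod(xi)
      if (anyZero) {
        ok <- m > 0
        if (sum(ok) < 10) next
        U <- Im(Xt[ok, , drop = FALSE] * (Conj(xi[ok]) / m[ok]))^2
        Lg <- log(pmax(U, eps))
        r <- suppressWarnings(as.vector(stats::cor(Lg, P[i, ok])))
      } else {
        U <- Im(Xt * (Conj(xi) / m))^2    # column recycling: j given i
        Lg <- log(pmax(U, eps))
        Lc <- Lg - rep(colMeans(Lg), each = Tn)
        r <- colSums(Lc * Pn[, i]) / sqrt(colSums(Lc^2))
      }
      bad <- !is.finite(r)
      bad[i] <- FALSE                     # self-orthogonalized row is void
      if (any(bad)) hadConstant <- TRUE
      r[!is.finite(r)] <- 0
      R[i, ] <- r                         # direction i -> j
    }
    R <- (R + t(R)) / 2
  }
  if (hadConstant)
    warning("constant envelope for some pair(s); correlation recorded as 0")
  diag(R) <- NA_real_
  R
}

#' Per-trial envelope connectivity at one frequency
#'
#' Applies [envelopeCorrTrial()] to every trial of a [TFRSet-class] at the
#' requested frequency.
#'
#' @param tfr A [TFRSet-class].
#' @param frequency Frequency in Hz (must match a grid frequency).
#' @param orthogonalized Use orthogonalization (default TRUE).
#' @return A [ConnectivityStack-class].
#' @export
envelopeConnectivity <- function(tfr, frequency, orthogonalized = TRUE) {
  stopifnot(is(tfr, "TFRSet"))
  k <- which(abs(tfr@freqs - frequency) < 1e-9)
  if (length(k) != 1L)
    stop("frequency not on the grid: ", frequency)
  nT <- dim(tfr@coeffs)[1]
  N <- dim(tfr@coeffs)[2]
  out <- array(NA_real_, dim = c(nT, N, N))
  for (tr in seq_len(nT)) {
    X <- tfr@coeffs[tr, , k, ]
    dim(X) <- c(N, length(tfr@times))
    out[tr, , ] <- envelopeCorrTrial(X, orthogonalized = orthogonalized)
  }
  new("ConnectivityStack", corr = out, frequency = tfr@freqs[k],
      nTimepoints = length(tfr@times))
}
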