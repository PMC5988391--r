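## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without clobbering the caller's
## RNG state. A NULL seed leaves the state alone.
localSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a reproducible child seed from (seed, stream indices), kept well
## below .Machine$integer.max.
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in idx) s <- (s * 69069 + k * 1234567 + 1) %% 2147480000
  as.integer(s)
}

## Rank-transform then z-score with the population (1/n) denominator.
## Constant input -> all zeros with a warning.
rankZscore <- function(x) {
  r <- rank(x, ties.method = "average")
  s <- sqrt(mean((r - mean(r))^2))
  if (s == 0) {
    warning("constant input: rank-z output is all zero")
    return(rep(0, length(x)))
  }
  (r - mean(r)) / s
}

## Symmetric nearest positive semi-definite projection (eigenvalue clipping,
## diagonal restored to 1).
nearestPSD <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  d[d == 0] <- 1
  M <- M / tcrossprod(d)
  diag(M) <- 1
  M
}

## Cholesky factor with PSD fallback (ridge after projection).
safeChol <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(nearestPSD(C) + diag(1e-10, nrow(C)))
  ch
}

## All-pairs BFS distances on a binary adjacency matrix via boolean matrix
## powers; unreachable pairs stay Inf.
bfsDistances <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- (A > 0) | diag(n) > 0
  D[A > 0] <- 1
  k <- 1L
  repeat {
    nxt <- ((reach + 0) %*% (A > 0)) > 0 | reach
    new <- nxt & !reach
    if (!any(new) || k >= n) break
    k <- k + 1L
    D[new] <- k
    reach <- nxt
  }
  D
}
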