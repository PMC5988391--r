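# Independent brute-force oracles for the graph diagnostics. These share no
# code with the package implementation: distances come from Floyd-Warshall,
# modularity from the Q formula and (for small n) exhaustive partition
# search.

floydWarshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bruteGlobalEff <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- floydWarshall(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

bruteNodalEff <- function(A) {
  n <- nrow(A)
  D <- floydWarshall(A)
  vapply(seq_len(n), function(i) {
    v <- D[i, -i]
    mean(ifelse(is.finite(v), 1 / v, 0))
  }, numeric(1))
}

bruteLocalEff <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    bruteGlobalEff(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

# Newman modularity of a given partition, straight from the definition
# Q = sum_c (e_c / m - (d_c / 2m)^2).
bruteModularityQ <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  q <- 0
  for (cc in unique(membership)) {
    idx <- membership == cc
    ec <- sum(A[idx, idx]) / 2
    dc <- sum(A[idx, ])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# All set partitions of n elements as restricted-growth strings.
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxLabel) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (lab in seq_len(maxLabel + 1))
      rec(c(prefix, lab), max(maxLabel, lab))
  }
  rec(integer(0), 0L)
  out
}

bruteBestPartition <- function(A) {
  parts <- allPartitions(nrow(A))
  qs <- vapply(parts, function(p) bruteModularityQ(A, p), numeric(1))
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

bruteWithinZ <- function(A, membership) {
  n <- nrow(A)
  z <- numeric(n)
  for (i in seq_len(n)) {
    idx <- which(membership == membership[i])
    kap <- vapply(idx, function(j) sum(A[j, idx]), numeric(1))
    s <- sqrt(mean((kap - mean(kap))^2))
    ki <- sum(A[i, idx])
    z[i] <- if (s > 0) (ki - mean(kap)) / s else 0
  }
  z
}

bruteParticipation <- function(A, membership) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    ki <- sum(A[i, ])
    if (ki == 0) return(0)
    1 - sum(vapply(unique(membership), function(m)
      (sum(A[i, membership == m]) / ki)^2, numeric(1)))
  }, numeric(1))
}

# Random symmetric binary graph with given edge probability.
randomGraph <- function(n, p, rng = NULL) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  A[ut] <- as.numeric(stats::runif(length(ut)) < p)
  A + t(A)
}

# Random symmetric "correlation-like" matrix for threshold tests.
randomSymmetric <- function(n) {
  M <- matrix(stats::runif(n * n, -1, 1), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 1
  M
}

# Small helper: EpochSet straight from a signal array.
epochsFromArray <- function(sig, sampleRate = 500, window = c(-1, 2)) {
  new("EpochSet", signals = sig, sampleRate = sampleRate, window = window,
      trialData = data.frame(trial = seq_len(dim(sig)[1])))
}
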