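## Fixed-density binary brain graphs and their whole-brain / nodal
## diagnostics. Distances are exact BFS via boolean matrix powers;
## community detection is Louvain (igraph) with restarts.

#' Threshold a correlation matrix at a fixed edge density
#'
#' Keeps the top `floor(density * N(N-1)/2)` upper-triangle entries ranked
#' by absolute correlation; ties are broken by deterministic index order.
#' The retained correlation values are kept for [meanFC()].
#'
#' @param corr Symmetric `N x N` correlation matrix (diagonal ignored).
#' @param density Edge density in (0, 1].
#' @return A [BinaryGraph-class].
#' @examples
#' g <- thresholdDensity(uniformCorrelation(5, 0.3), 0.1)  # one edge
#' @export
thresholdDensity <- function(corr, density = 0.10) {
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  N <- nrow(corr)
  if (N != ncol(corr)) stop("corr must be square")
  if (max(abs(corr - t(corr)), na.rm = TRUE) > 1e-8)
    stop("corr must be symmetric")
  ut <- which(upper.tri(corr))
  v <- corr[ut]
  v[is.na(v)] <- 0
  k <- floor(density * length(ut))
  ord <- order(-abs(v), ut)               # deterministic tie-break
  keep <- ord[seq_len(k)]
  A <- matrix(0, N, N)
  A[ut[keep]] <- 1
  A <- A + t(A)
  new("BinaryGraph", adjacency = A, density = density,
      retainedWeights = v[keep])
}

#' Mean functional connectivity of a sparse graph
#'
#' Arithmetic mean of the correlation values retained by the density
#' threshold.
#'
#' @param g A [BinaryGraph-class] with at least one edge.
#' @return Numeric scalar.
#' @export
meanFC <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  if (!length(g@retainedWeights)) stop("graph has no edges")
  mean(g@retainedWeights)
}

## Accept a BinaryGraph or a plain binary adjacency matrix.
asAdjacency <- function(g) {
  if (is(g, "BinaryGraph")) g@adjacency else as.matrix(g)
}

#' Global network efficiency
#'
#' Mean over ordered node pairs of the inverse shortest path length;
#' disconnected pairs contribute 0. A measure of network integration.
#'
#' @param g A [BinaryGraph-class] or binary adjacency matrix.
#' @return Numeric scalar in [0, 1].
#' @export
globalEfficiency <- function(g) {
  effGlobal(asAdjacency(g))
}

## Fast internal paths on plain adjacency matrices (no S4 dispatch); shared
## by the per-trial loop.
effGlobal <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  inv <- 1 / bfsDistances(A)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

effNodal <- function(A) {
  n <- nrow(A)
  if (n < 2) return(rep(0, n))
  inv <- 1 / bfsDistances(A)
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

effLocal <- function(A) {
  n <- nrow(A)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) >= 2)
      eff[i] <- effGlobal(A[nb, nb, drop = FALSE])
  }
  eff
}

#' Nodal efficiency
#'
#' Per node, the mean inverse distance to all other nodes; captures the
#' integration of each source into the entire network. The average of the
#' nodal efficiencies equals the global efficiency.
#'
#' @param g A [BinaryGraph-class] or binary adjacency matrix.
#' @return Numeric vector, one value per node.
#' @export
nodalEfficiency <- function(g) {
  effNodal(asAdjacency(g))
}

#' Local efficiency
#'
#' Per node, the global efficiency of the subgraph induced by its direct
#' neighbors; nodes with fewer than two neighbors score 0. The mean over
#' nodes is the whole-brain mean local efficiency.
#'
#' @param g A [BinaryGraph-class] or binary adjacency matrix.
#' @return List with `nodal` (per-node values) and `mean`.
#' @export
localEfficiency <- function(g) {
  eff <- effLocal(asAdjacency(g))
  list(nodal = eff, mean = if (length(eff)) mean(eff) else 0)
}

#' Louvain community detection with restarts
#'
#' Newman modularity Q is maximized by the Louvain algorithm with a fixed
#' seed and `restarts` random restarts, keeping the best partition; Q is
#' reported for the returned partition.
#'
#' @param g A [BinaryGraph-class] or binary adjacency matrix with >= 1 edge.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state, which the per-trial loop relies on.
#' @param restarts Number of Louvain restarts (default 10).
#' @return List with `membership` (integer vector) and `Q`.
#' @export
louvainModularity <- function(g, seed = 1L, restarts = 10L) {
  A <- asAdjacency(g)
  if (sum(A) == 0) {
    warning("graph has no edges; every node is its own community, Q = 0")
    return(list(membership = seq_len(nrow(A)), Q = 0))
  }
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  localSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      cl <- igraph::cluster_louvain(ig)
      q <- igraph::modularity(ig, igraph::membership(cl))
      if (is.null(best) || q > best$Q)
        best <- list(membership = as.integer(igraph::membership(cl)), Q = q)
    }
    best
  })
}

#' Within-module degree z-score
#'
#' Standardized within-community degree `z_i = (k_i - mean k) / sd k`, with
#' mean and population SD taken over the nodes of i's module; modules with
#' zero degree SD give z = 0. Measures module segregation of a node.
#'
#' @param g A [BinaryGraph-class] or binary adjacency matrix.
#' @param membership Integer community labels covering all nodes.
#' @return Numeric vector, one value per node.
#' @export
withinModuleZ <- function(g, membership) {
  A <- asAdjacency(g)
  n <- nrow(A)
  if (length(membership) != n) stop("membership must cover all nodes")
  z <- numeric(n)
  for (m in unique(membership)) {
    idx <- which(membership == m)
    kappa <- rowSums(A[idx, idx, drop = FALSE])
    s <- sqrt(mean((kappa - mean(kappa))^2))
    z[idx] <- if (s > 0) (kappa - mean(kappa)) / s else 0
  }
  z
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2`, the degree-weighted spread of node i's
#' edges across communities; isolated nodes score 0.
#'
#' @param g A [BinaryGraph-class] or binary adjacency matrix.
#' @param membership Integer community labels covering all nodes.
#' @return Numeric vector, one value per node.
#' @export
participationCoef <- function(g, membership) {
  A <- asAdjacency(g)
  n <- nrow(A)
  if (length(membership) != n) stop("membership must cover all nodes")
  k <- rowSums(A)
  mods <- sort(unique(membership))
  kim <- vapply(mods, function(m)
    rowSums(A[, membership == m, drop = FALSE]), numeric(n))
  p <- 1 - rowSums((kim / pmax(k, 1))^2)
  p[k == 0] <- 0
  p
}

#' Per-trial graph diagnostics from a connectivity stack
#'
#' Thresholds each trial's correlation matrix at the requested density and
#' computes the whole-brain metrics (mean FC, global efficiency, mean local
#' efficiency, modularity Q) and, optionally, the nodal metrics (strength,
#' local efficiency, within-module z, nodal efficiency, participation).
#'
#' @param stack A [ConnectivityStack-class].
#' @param density Edge density (default 0.10; the 0.05 alternative is the
#'   robustness setting).
#' @param seed Integer seed for community detection.
#' @param nodal Compute nodal metrics as well (default TRUE).
#' @param restarts Louvain restarts per trial.
#' @return A [NetworkSeries-class].
#' @export
networkMetrics <- function(stack, density = 0.10, seed = 1L, nodal = TRUE,
                           restarts = 10L) {
  stopifnot(is(stack, "ConnectivityStack"))
  nT <- dim(stack@corr)[1]
  N <- dim(stack@corr)[2]
  tm <- data.frame(trial = seq_len(nT), mean_fc = NA_real_,
                   global_efficiency = NA_real_,
                   mean_local_efficiency = NA_real_, modularity_q = NA_real_)
  nod <- if (nodal) {
    nm <- c("strength", "local_efficiency", "within_module_z",
            "nodal_efficiency", "participation")
    stats::setNames(replicate(length(nm), matrix(NA_real_, nT, N),
                              simplify = FALSE), nm)
  } else list()
  localSeed(seed, for (tr in seq_len(nT)) {
    C <- stack@corr[tr, , ]
    g <- thresholdDensity(C, density)
    A <- g@adjacency
    tm$mean_fc[tr] <- mean(g@retainedWeights)
    inv <- 1 / bfsDistances(A)
    diag(inv) <- 0
    tm$global_efficiency[tr] <- sum(inv) / (N * (N - 1))
    leNodal <- effLocal(A)
    tm$mean_local_efficiency[tr] <- mean(leNodal)
    mod <- louvainModularity(g, seed = NULL, restarts = restarts)
    tm$modularity_q[tr] <- mod$Q
    if (nodal) {
      nod$strength[tr, ] <- rowSums(A)
      nod$local_efficiency[tr, ] <- leNodal
      nod$within_module_z[tr, ] <- withinModuleZ(A, mod$membership)
      nod$nodal_efficiency[tr, ] <- rowSums(inv) / (N - 1)
      nod$participation[tr, ] <- participationCoef(A, mod$membership)
    }
  })
  new("NetworkSeries", trialMetrics = tm, nodal = nod,
      frequency = stack@frequency, density = density)
}
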