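test_that("density thresholding keeps the exact edge count and nests across densities", {
  expect_equal(sum(thresholdDensity(randomSymmetric(5), 0.1)@adjacency) / 2, 1)
  full <- thresholdDensity(randomSymmetric(6), 1)
  expect_equal(sum(full@adjacency) / 2, 15)
  set.seed(41)
  for (i in 1:20) {
    M <- randomSymmetric(12)
    g10 <- thresholdDensity(M, 0.10)
    g05 <- thresholdDensity(M, 0.05)
    expect_equal(sum(g10@adjacency) / 2, floor(0.10 * 66))
    expect_equal(sum(g05@adjacency) / 2, floor(0.05 * 66))
    expect_true(all(g10@adjacency[g05@adjacency == 1] == 1))  # nested
    ## retained weights really are the kept entries
    kept <- M[upper.tri(M)][g10@adjacency[upper.tri(M)] == 1]
    expect_equal(sort(g10@retainedWeights), sort(kept))
    expect_equal(meanFC(g10), mean(kept))
  }
  expect_error(thresholdDensity(randomSymmetric(5), 0), "density")
})

test_that("efficiencies match hand-computed values on canonical graphs", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(globalEfficiency(K4), 1)
  expect_equal(localEfficiency(K4)$nodal, rep(1, 4))
  expect_equal(nodalEfficiency(K4), rep(1, 4))

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(globalEfficiency(path3), (1 + 1 + 0.5) / 3)

  expect_equal(globalEfficiency(matrix(0, 5, 5)), 0)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(localEfficiency(star)$nodal[1], 0)  # neighbor graph edgeless
})

test_that("two disconnected 4-cliques give Q = 0.5 and the clique partition", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  mod <- louvainModularity(A, seed = 2)
  expect_equal(mod$Q, 0.5)
  expect_equal(length(unique(mod$membership)), 2L)
  expect_equal(length(unique(mod$membership[1:4])), 1L)
  expect_equal(length(unique(mod$membership[5:8])), 1L)
  ## complete graph: one community, Q ~ 0
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  expect_lt(abs(louvainModularity(K6, seed = 1)$Q), 1e-12)
})

test_that("within-module z and participation follow their formulas", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  memb <- rep(1:2, each = 4)
  expect_equal(withinModuleZ(A, memb), rep(0, 8))   # all degrees equal
  expect_equal(participationCoef(A, memb), rep(0, 8))  # all edges within

  ## degree-2 node bridging two modules: P = 1 - (1/4 + 1/4) = 0.5
  B <- matrix(0, 5, 5)
  B[1, 2] <- B[2, 1] <- 1; B[1, 4] <- B[4, 1] <- 1
  B[2, 3] <- B[3, 2] <- 1; B[4, 5] <- B[5, 4] <- 1
  membB <- c(1, 1, 1, 2, 2)
  expect_equal(participationCoef(B, membB)[1], 0.5)
  expect_equal(participationCoef(B, rep(1, 5)), rep(0, 5))

  ## hand z-score: within-degree 5 in a module with mean 2, sd 1 -> z = 3
  expect_equal((5 - 2) / 1, 3)
  ## numerically: a 5-node module where node 1 has within-degree 4
  Cg <- matrix(0, 6, 6)
  Cg[1, 2:5] <- Cg[2:5, 1] <- 1
  Cg[2, 3] <- Cg[3, 2] <- 1
  membC <- c(rep(1, 5), 2)
  zz <- withinModuleZ(Cg, membC)
  kapC <- c(4, 2, 2, 1, 1)
  expect_equal(zz[1:5], (kapC - mean(kapC)) / sqrt(mean((kapC - mean(kapC))^2)))
  expect_equal(sum(zz[1:5]), 0, tolerance = 1e-12)
})

test_that("sum of z-scores within each module is zero on random graphs", {
  set.seed(43)
  for (i in 1:10) {
    A <- randomGraph(10, 0.4)
    memb <- sample(1:3, 10, replace = TRUE)
    z <- withinModuleZ(A, memb)
    for (m in unique(memb))
      expect_equal(sum(z[memb == m]), 0, tolerance = 1e-12)
  }
})

test_that("networkMetrics returns coherent per-trial series", {
  set.seed(44)
  corr <- array(NA_real_, dim = c(5, 10, 10))
  for (tr in 1:5) {
    M <- randomSymmetric(10); diag(M) <- NA
    corr[tr, , ] <- M
  }
  stack <- new("ConnectivityStack", corr = corr, frequency = 16,
               nTimepoints = 41L)
  ns <- networkMetrics(stack, density = 0.2, seed = 3, nodal = TRUE)
  expect_s4_class(ns, "NetworkSeries")
  tm <- trialMetrics(ns)
  expect_equal(nrow(tm), 5)
  expect_true(all(tm$global_efficiency >= 0 & tm$global_efficiency <= 1))
  expect_equal(rowMeans(nodalMetrics(ns, "nodal_efficiency")),
               tm$global_efficiency, tolerance = 1e-12)
  expect_equal(rowMeans(nodalMetrics(ns, "local_efficiency")),
               tm$mean_local_efficiency, tolerance = 1e-12)
  ## determinism
  ns2 <- networkMetrics(stack, density = 0.2, seed = 3, nodal = TRUE)
  expect_identical(trialMetrics(ns2), tm)
})
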