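test_that("orthogonalization removes collinear components and keeps orthogonal ones", {
  set.seed(11)
  x <- complex(real = rnorm(41), imaginary = rnorm(41))
  ## real-coefficient mixtures (instantaneous leakage) are removed exactly
  expect_true(all(orthogonalize(x, 1.7 * x) < 1e-24))
  expect_true(all(orthogonalize(x, -0.4 * x) < 1e-24))
  y90 <- x * 1i                      # equal magnitude, 90 degrees away
  expect_equal(orthogonalize(x, y90), Mod(y90)^2, tolerance = 1e-12)
  ## independent signals keep half their power on average
  x2 <- complex(real = rnorm(5000), imaginary = rnorm(5000))
  y2 <- complex(real = rnorm(5000), imaginary = rnorm(5000))
  expect_equal(mean(orthogonalize(x2, y2)), mean(Mod(y2)^2) / 2,
               tolerance = 0.1)
  ## zero-magnitude reference points are excluded
  x3 <- x; x3[5] <- 0
  expect_true(is.na(orthogonalize(x3, y90)[5]))
})

test_that("per-trial envelope correlation matrices are symmetric, bounded and leakage-suppressed", {
  set.seed(12)
  X <- matrix(complex(real = rnorm(6 * 41), imaginary = rnorm(6 * 41)), 6, 41)
  X[2, ] <- X[1, ] * 0.8             # duplicated (leaked) source
  R <- suppressWarnings(envelopeCorrTrial(X))
  expect_true(all(is.na(diag(R))))
  off <- R[!is.na(R)]
  expect_true(all(off >= -1 & off <= 1))
  expect_equal(R, t(R))
  expect_equal(sum(!is.na(R[upper.tri(R)])), 6 * 5 / 2)
  Rnaive <- suppressWarnings(envelopeCorrTrial(X, orthogonalized = FALSE))
  expect_gt(Rnaive[1, 2], 0.9)       # naive sees the leaked copy
  expect_lt(abs(R[1, 2]), 0.3)       # orthogonalization suppresses it
})

test_that("planted log-envelope coupling is recovered and ranks above unplanted pairs", {
  C <- diag(6)
  C[1, 2] <- C[2, 1] <- 0.9
  m <- couplingModel(nSources = 6, envelopeCorr = C)
  ep <- simulateEpochs(m, 300, seed = 13)
  g <- new("FrequencyGrid", freqs = 2^4.5, cycles = 6, bandwidthOct = 0.5)
  tfr <- waveletTransform(ep, g)
  cs <- envelopeConnectivity(tfr, 2^4.5)
  expect_s4_class(cs, "ConnectivityStack")
  avg <- apply(cs@corr, c(2, 3), mean)
  unplanted <- avg[upper.tri(avg)]
  unplanted <- unplanted[-1]         # drop the (1,2) entry
  expect_gt(avg[1, 2], 0)
  expect_gt(avg[1, 2], max(unplanted))
})

test_that("estimated couplings increase monotonically in the planted value", {
  rhos <- c(0, 0.3, 0.6, 0.9)
  est <- vapply(seq_along(rhos), function(i) {
    C <- diag(4)
    C[1, 2] <- C[2, 1] <- rhos[i]
    m <- couplingModel(nSources = 4, envelopeCorr = C)
    ep <- simulateEpochs(m, 500, seed = 14)   # same seed: paired comparison
    g <- new("FrequencyGrid", freqs = 2^4.5, cycles = 6, bandwidthOct = 0.5)
    cs <- envelopeConnectivity(waveletTransform(ep, g), 2^4.5)
    mean(cs@corr[, 1, 2])
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
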