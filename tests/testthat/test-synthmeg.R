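test_that("coupling models validate and project non-PSD targets", {
  C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  C <- rbind(cbind(C, 0), c(0, 0, 0, 1))      # 4 sources, non-PSD block
  expect_warning(m <- couplingModel(nSources = 4, envelopeCorr = C),
                 "positive semi-definite")
  ev <- eigen(m@envelopeCorr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_error(couplingModel(nSources = 2), "nSources")
})

test_that("epochs have the documented geometry and are seed-deterministic", {
  m <- couplingModel(nSources = 4)
  ep <- simulateEpochs(m, 3, seed = 21)
  expect_equal(dim(ep@signals), c(3L, 4L, 1500L))
  expect_true(all(is.finite(ep@signals)))
  expect_equal(sampleRate(ep), 500)
  expect_equal(ep@window, c(-1, 2))
  ep2 <- simulateEpochs(m, 3, seed = 21)
  expect_identical(ep@signals, ep2@signals)
})

test_that("independent sources give near-zero estimated couplings", {
  m <- couplingModel(nSources = 5, envelopeCorr = diag(5))
  ep <- simulateEpochs(m, 200, seed = 22)
  g <- new("FrequencyGrid", freqs = 2^4.5, cycles = 6, bandwidthOct = 0.5)
  cs <- envelopeConnectivity(waveletTransform(ep, g), 2^4.5)
  avg <- apply(cs@corr, c(2, 3), mean)
  expect_lt(max(abs(avg[upper.tri(avg)])), 0.1)
})

test_that("zero-SNR signals are background only with no couplings", {
  C <- diag(4); C[1, 2] <- C[2, 1] <- 0.9
  m <- couplingModel(nSources = 4, envelopeCorr = C, snr = 0)
  ep <- simulateEpochs(m, 100, seed = 23)
  g <- new("FrequencyGrid", freqs = 2^4.5, cycles = 6, bandwidthOct = 0.5)
  cs <- envelopeConnectivity(waveletTransform(ep, g), 2^4.5)
  expect_lt(abs(mean(cs@corr[, 1, 2])), 0.1)
})

test_that("behavior couples to the planted statistic with the closed-form correlation", {
  m <- couplingModel(nSources = 4, behaviorSlope = 0.3, behaviorNoiseSd = 1)
  set.seed(123)
  stat <- rnorm(4000)
  ## baseSpeed far from the positivity floor keeps the affine model exact
  b <- simulateBehavior(m, stat, seed = 24, noResponseRate = 0,
                        baseSpeed = 5)
  speed <- 1 / b$response_time
  rho <- 0.3 / sqrt(0.09 + 1)                  # 0.287
  expect_lt(abs(cor(speed, stat) - rho), 2.5 * 1 / sqrt(4000))

  m0 <- couplingModel(nSources = 4, behaviorSlope = 0)
  b0 <- simulateBehavior(m0, stat, seed = 25, noResponseRate = 0)
  expect_lt(abs(cor(1 / b0$response_time, stat)), 0.05)
})

test_that("simulated accuracy converges to the target and inputs are validated", {
  m <- couplingModel(nSources = 4)
  accs <- vapply(1:10, function(s)
    mean(simulateBehavior(m, rnorm(384), targetAccuracy = 0.70,
                          seed = s)$correct), numeric(1))
  expect_lte(abs(mean(accs) - 0.70), 0.02)
  expect_true(all(abs(accs - 0.70) <= 0.075))
  expect_error(simulateBehavior(m, rnorm(10), targetAccuracy = 0.4),
               "targetAccuracy")
  expect_error(simulateBehavior(m, c(1, NA, 2)), "finite")
  b <- simulateBehavior(m, rnorm(2000), seed = 3, noResponseRate = 0.05)
  expect_gt(sum(is.na(b$response_time)), 0)
  expect_true(all(b$response_time > 0, na.rm = TRUE))
})
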