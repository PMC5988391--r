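test_that("the analysis grid has 12 frequencies from 1 to 32 Hz", {
  g <- buildGrid()
  f <- frequencies(g)
  expect_length(f, 12)
  expect_equal(f[1:4], c(1, 2, 4, 8))
  expect_equal(f[12], 32)
  expect_equal(f[4:12], 2^seq(3, 5, by = 0.25))
})

test_that("a pure 20-Hz tone peaks at the adjacent grid bins", {
  t <- -1 + (0:1499) / 500
  sig <- array(cos(2 * pi * 20 * t), dim = c(1, 1, 1500))
  tfr <- waveletTransform(epochsFromArray(sig))
  pow <- rowMeans(Mod(tfr@coeffs[1, 1, , ])^2)
  f <- frequencies(buildGrid())
  expect_true(f[which.max(pow)] %in% c(2^4.25, 2^4.5))
  expect_gt(max(pow), 10 * pow[1])
})

test_that("the transform is linear and zero on zero signals", {
  set.seed(8)
  sig <- array(rnorm(2 * 2 * 1500), dim = c(2, 2, 1500))
  tfr1 <- waveletTransform(epochsFromArray(sig))
  tfr2 <- waveletTransform(epochsFromArray(2 * sig))
  expect_equal(Mod(tfr2@coeffs)^2, 4 * Mod(tfr1@coeffs)^2, tolerance = 1e-10)
  z <- waveletTransform(epochsFromArray(array(0, dim = c(1, 1, 1500))))
  expect_true(all(Mod(z@coeffs) == 0))
})

test_that("the default analysis window enumerates exactly 41 time points", {
  expect_length(seq(-0.5, 1.5, by = 0.05), 41)
  sig <- array(rnorm(1500), dim = c(1, 1, 1500))
  tfr <- waveletTransform(epochsFromArray(sig))
  expect_equal(dim(tfr@coeffs)[4], 41L)
  expect_equal(range(tfr@times), c(-0.5, 1.5))
})

test_that("mirror extension only affects the sub-8-Hz bins", {
  set.seed(9)
  sig <- array(rnorm(3 * 2 * 1500), dim = c(3, 2, 1500))
  ep <- epochsFromArray(sig)
  full <- waveletTransform(ep, buildGrid(), mirror = TRUE)
  high <- waveletTransform(ep, buildGrid(lowFreqs = numeric(0)),
                           mirror = FALSE)
  expect_lt(max(Mod(full@coeffs[, , 4:12, ] - high@coeffs)), 1e-8)
  ## forcing the extension everywhere leaves >= 8 Hz bins essentially
  ## unchanged (the wavelets are compact inside the epoch)
  allMirror <- waveletTransform(ep, buildGrid(), mirror = TRUE,
                                mirrorBelow = 33)
  rel <- Mod(allMirror@coeffs[, , 4:12, ] - full@coeffs[, , 4:12, ]) /
    max(Mod(full@coeffs[, , 4:12, ]))
  expect_lt(max(rel), 1e-3)
})

test_that("white-noise wavelet power is flat across bins", {
  set.seed(10)
  sig <- array(rnorm(80 * 1 * 1500), dim = c(80, 1, 1500))
  tfr <- waveletTransform(epochsFromArray(sig))
  pw <- apply(Mod(tfr@coeffs)^2, 3, mean)
  expect_true(all(abs(pw / mean(pw) - 1) < 0.2))
})

test_that("baseline-corrected log power behaves under stationarity and amplitude steps", {
  t <- -1 + (0:1499) / 500
  sig <- array(cos(2 * pi * 16 * t), dim = c(1, 1, 1500))
  tfr <- waveletTransform(epochsFromArray(sig))
  lp <- logPowerBaseline(tfr)
  k <- which(frequencies(buildGrid()) == 16)
  expect_true(all(abs(lp[1, 1, k, ]) < 1e-6))

  amp <- ifelse(t >= 0.2, 2, 1)
  sig2 <- array(amp * cos(2 * pi * 16 * t), dim = c(1, 1, 1500))
  lp2 <- logPowerBaseline(waveletTransform(epochsFromArray(sig2)))
  late <- lp2[1, 1, k, seq(-0.5, 1.5, 0.05) >= 0.5]
  expect_equal(mean(late), log(4), tolerance = 0.01)

  ## baseline over the full epoch on a stationary signal: zero mean
  lp3 <- logPowerBaseline(tfr, baselineWindow = c(-0.5, 1.5))
  expect_equal(mean(lp3[1, 1, k, ]), 0, tolerance = 1e-12)
})
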