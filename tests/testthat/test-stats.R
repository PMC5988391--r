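test_that("subject GLM recovers exact, null and Spearman-equivalent weights", {
  set.seed(51)
  x <- rnorm(100)
  expect_equal(subjectGlm(x, x), 1, tolerance = 1e-10)
  y <- rnorm(100)
  expect_lt(abs(subjectGlm(y, x)), 0.25)
  cov <- data.frame(c1 = rnorm(100), c2 = rnorm(100))
  b <- subjectGlm(y, x, covariates = cov)
  expect_true(is.finite(b))
  expect_error(subjectGlm(y[1:5], x[1:5]), "valid trials")
})

test_that("circular shifts preserve the value multiset and the circular ACF", {
  set.seed(52)
  n <- 60
  y <- as.vector(arima.sim(list(ar = 0.6), n))
  rot <- function(v, k) v[((seq_along(v) + k - 1) %% length(v)) + 1]
  expect_equal(sort(rot(y, 17)), sort(y))
  expect_equal(rot(y, n), y)                      # full rotation = identity
  cacf <- function(v) Re(fft(Mod(fft(v - mean(v)))^2, inverse = TRUE))
  expect_equal(cacf(rot(y, 23)), cacf(y), tolerance = 1e-8)
})

test_that("the null distribution matches brute-force shifted refits", {
  set.seed(53)
  S <- 3
  y <- replicate(S, rnorm(40), simplify = FALSE)
  x <- replicate(S, rnorm(40), simplify = FALSE)
  out <- circularNull(y, x, nShifts = 10)
  expect_length(out$group, 10)
  rot <- function(v, k) v[((seq_along(v) + k - 1) %% length(v)) + 1]
  brute <- vapply(1:10, function(k)
    mean(vapply(1:S, function(s) subjectGlm(rot(y[[s]], k), x[[s]]),
                numeric(1))), numeric(1))
  expect_equal(out$group, brute, tolerance = 1e-10)
  expect_equal(out$observed$subject,
               vapply(1:S, function(s) subjectGlm(y[[s]], x[[s]]),
                      numeric(1)), tolerance = 1e-10)
  expect_error(circularNull(y, x, nShifts = 50), "nShifts")
})

test_that("percentile significance flags extremes and not the median", {
  null <- rnorm(350)
  expect_false(assessSignificance(median(null), null)$significant)
  expect_true(assessSignificance(max(null) + 1, null)$significant)
  expect_true(assessSignificance(min(null) - 1, null)$significant)
  ci <- assessSignificance(0, null)$ci
  expect_lt(ci[1], ci[2])
})

test_that("FCR correction follows the printed adjustment formula", {
  expect_equal(1 - 2 * 0.05 / 14, 0.9928571, tolerance = 1e-6)
  set.seed(54)
  null <- matrix(rnorm(350 * 14, 0, 0.2), 350, 14)
  obs <- rep(0, 14)
  obs[c(3, 7)] <- c(1, -1)                        # clearly selected
  out <- fcrCorrect(obs, null, q = 0.05, Ft = 14)
  expect_equal(sum(out$selected), 2)
  expect_equal(attr(out, "fcrLevel"), 1 - 2 * 0.05 / 14)
  ## adjusted CIs contain the unadjusted ones
  expect_true(all(out$lo_fcr <= out$lo + 1e-12))
  expect_true(all(out$hi_fcr >= out$hi - 1e-12))
  expect_true(all(out$significant[c(3, 7)]))
  ## Fs = Ft: no inflation
  outAll <- fcrCorrect(rep(10, 14), null, q = 0.05, Ft = 14)
  expect_equal(attr(outAll, "fcrLevel"), 0.95)
  ## Fs = 0: empty selection, no second pass
  out0 <- fcrCorrect(rep(0, 14), null, q = 0.05, Ft = 14)
  expect_false(any(out0$selected))
  expect_true(all(is.na(out0$lo_fcr)))
})

test_that("task contrasts detect constructed differences and pair correctly", {
  set.seed(55)
  S <- 6
  betaA <- rnorm(S, 0.3, 0.02)
  nullA <- matrix(rnorm(100 * S, 0, 0.02), 100, S)
  same <- taskContrast(betaA, betaA, nullA, nullA)
  expect_equal(same$difference, 0)
  expect_false(same$significant)
  flip <- taskContrast(betaA, -betaA, nullA, nullA)
  expect_equal(flip$difference, 2 * mean(betaA))
  expect_true(flip$significant)
  expect_error(taskContrast(betaA, betaA[-1], nullA, nullA), "paired")
})

test_that("planted task-specific effects are recovered by the contrast machinery", {
  detected <- vapply(1:20, function(r) {
    set.seed(600 + r)
    S <- 8; n <- 80
    x <- replicate(S, as.vector(arima.sim(list(ar = 0.3), n)),
                   simplify = FALSE)
    yA <- lapply(x, function(v) 0.4 * v + rnorm(n))   # effect in task A only
    yB <- replicate(S, rnorm(n), simplify = FALSE)
    fitA <- circularNull(yA, x, nShifts = 60)
    fitB <- circularNull(yB, x, nShifts = 60)
    taskContrast(fitA$observed$subject, fitB$observed$subject,
                 fitA$subject, fitB$subject)$significant
  }, logical(1))
  expect_gte(mean(detected), 0.8)
})

test_that("rank-based lag cross-correlation locates constructed shifts", {
  set.seed(56)
  n <- 120
  y <- as.vector(arima.sim(list(ar = 0.7), n))
  x <- c(y[4:n], rnorm(3))                # x[t] = y[t + 3]: the metric leads
  cc <- crosscorrLag(y, x, maxLag = 6)
  expect_equal(cc$lag[which.max(cc$r)], -3)
  ## independent series: everything small
  cc0 <- crosscorrLag(rnorm(300), rnorm(300), maxLag = 5)
  expect_true(all(abs(cc0$r) < 0.2))
  ## lag 0 equals the single-predictor GLM weight
  x2 <- rnorm(n)
  cc2 <- crosscorrLag(y, x2, maxLag = 2)
  expect_equal(cc2$r[cc2$lag == 0], subjectGlm(y, x2), tolerance = 1e-10)
})

test_that("the stats layer is invariant to monotone transforms of behavior", {
  set.seed(57)
  y <- replicate(3, rexp(50), simplify = FALSE)
  x <- replicate(3, rnorm(50), simplify = FALSE)
  f1 <- circularNull(y, x, nShifts = 20)
  f2 <- circularNull(lapply(y, function(v) log(v + 1)), x, nShifts = 20)
  expect_equal(f1$group, f2$group, tolerance = 1e-12)
  expect_equal(f1$observed$group, f2$observed$group, tolerance = 1e-12)
})

test_that("exact sign-flip permutation p-values behave at and away from the null", {
  set.seed(58)
  strong <- exactPermTest(rep(0.3, 8) + rnorm(8, 0, 0.01))
  expect_lt(strong$p, 0.01)
  nulls <- vapply(1:200, function(i) exactPermTest(rnorm(10))$p, numeric(1))
  expect_gt(mean(nulls < 0.05), 0.0)   # occurs
  expect_lt(mean(nulls < 0.05), 0.12)  # near nominal rate
})
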