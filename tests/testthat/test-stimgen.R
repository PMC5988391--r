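test_that("spectral centers follow the semitone formula and round to the printed set", {
  expect_equal(round(spectralCenters(707.1, -2)), 630)
  expect_equal(round(spectralCenters(707.1, 2)), 794)
  expect_equal(spectralCenters(707.1, 0), 707.1)
  expect_equal(round(spectralCenters(707.1)),
               c(630, 667, 687, 697, 717, 728, 749, 794))
  expect_true(!is.unsorted(spectralCenters(707.1)))
  expect_error(spectralCenters(-1), "positive")
})

test_that("textures have the specified sweep counts and coherent structure", {
  stim <- makeTexture(textureSpec(), seed = 1)
  expect_equal(nrow(stim@sweeps), 72)
  expect_true(all(stim@sweeps$is_coherent))
  expect_equal(length(unique(stim@sweeps$slope)), 1L)

  stim25 <- makeTexture(textureSpec(coherence = 0.25), seed = 2)
  expect_equal(sum(stim25@sweeps$is_coherent), round(0.25 * 72))  # 18
  expect_equal(length(unique(stim25@sweeps$slope[stim25@sweeps$is_coherent])),
               1L)
  expect_true(all(abs(stim25@sweeps$slope) == 3.3))

  sp <- textureSpec(coherence = 0.5, semitoneDeviation = -1,
                    coherentDirection = "down")
  expect_identical(makeTexture(sp, seed = 9)@sweeps,
                   makeTexture(sp, seed = 9)@sweeps)
  expect_true(all(makeTexture(sp, seed = 9)@sweeps$slope[
    makeTexture(sp, seed = 9)@sweeps$is_coherent] == -3.3))
})

test_that("sweep onsets stay inside the stimulus and start frequencies are log-uniform", {
  sw <- do.call(rbind, lapply(1:20, function(s)
    makeTexture(textureSpec(semitoneDeviation = 0.5), seed = s)@sweeps))
  expect_true(all(sw$onset >= 0 & sw$onset <= 0.3))
  center <- 707.1 * 2^(0.5 / 12)
  u <- (log2(sw$start_freq / center) + 1.5) / 3
  expect_true(nrow(sw) >= 1000)
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("audio rendering has the right length, silence and ridge behavior", {
  stim <- makeTexture(textureSpec(), seed = 3)
  x <- synthesizeAudio(stim, 44100)
  expect_length(x, 17640)
  expect_lte(max(abs(x)), 1)

  silent <- stim
  silent@sweeps <- silent@sweeps[0, , drop = FALSE]
  silent@spec@nSweeps <- 0L
  expect_identical(synthesizeAudio(silent, 44100), numeric(17640))

  ## one long up-sweep: the spectrogram peak frequency must increase
  one <- textureSpec(nSweeps = 1L, sweepDuration = 0.4, coherence = 1,
                     slopeMagnitude = 3.3)
  s1 <- makeTexture(one, seed = 4)
  s1@sweeps$onset <- 0
  s1@sweeps$start_freq <- 500
  y <- synthesizeAudio(s1, 8000)
  win <- 256
  hamming <- 0.54 - 0.46 * cos(2 * pi * seq_len(win) / win)
  hops <- seq(1, length(y) - win, by = win)
  peak <- vapply(hops, function(h) {
    sp <- Mod(stats::fft(y[h:(h + win - 1)] * hamming))[1:(win / 2)]
    which.max(sp)
  }, numeric(1))
  expect_true(all(diff(peak) >= 0))
  expect_gt(peak[length(peak)], peak[1])
})

test_that("blocks are balanced, sized 128 and alternate tasks", {
  d <- makeDesign(6, seed = 1)
  expect_equal(nrow(d), 6 * 128)
  expect_equal(as.vector(table(d$task)), c(384L, 384L))
  for (b in 1:6) {
    blk <- d[d$block == b, ]
    expect_equal(nrow(blk), 128)
    expect_equal(length(unique(blk$task)), 1L)
    cells <- table(blk$direction, blk$coherence, blk$spectral_center)
    expect_true(all(cells == 2))
  }
  taskPerBlock <- tapply(d$task, d$block, unique)
  expect_true(all(taskPerBlock[-1] != taskPerBlock[-6]))
  expect_identical(makeDesign(2, seed = 7), makeDesign(2, seed = 7))
})

test_that("a single repeat per cell gives the 64-trial factorial block", {
  cells <- expand.grid(direction = 1:2, coherence = 1:4, center = 1:8)
  expect_equal(nrow(cells), 64)
  d <- makeDesign(1, seed = 1)
  expect_equal(nrow(unique(d[, c("direction", "coherence",
                                 "spectral_center")])), 64)
})

test_that("WAV export writes a well-formed PCM header", {
  f <- tempfile(fileext = ".wav")
  on.exit(unlink(f))
  writeWav(sin(2 * pi * 440 * seq_len(4410) / 44100), f, 44100)
  con <- file(f, "rb")
  on.exit(close(con), add = TRUE, after = FALSE)
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), size = 4))
  expect_identical(readChar(con, 4), "WAVE")
  expect_equal(file.size(f), 44 + 2 * 4410)
})
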