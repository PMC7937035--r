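test_that("shuffling conserves songs, lengths and per-song type multisets", {
  single <- recordingFromSequences("one", list("A"))
  expect_equal(songSequences(shuffleWithinSongs(single, seed = 1)),
               songSequences(single))

  set.seed(21)
  for (i in 1:20) {
    r <- randomRecording(paste0("r", i), nSongs = 5L)
    sh <- shuffleWithinSongs(r)
    s0 <- songSequences(r)
    s1 <- songSequences(sh)
    expect_equal(lengths(s1), lengths(s0))
    for (k in seq_along(s0)) expect_equal(sort(s1[[k]]), sort(s0[[k]]))
    expect_true(validObject(sh))
  }
})

test_that("acoustic measurements travel with their tokens", {
  r <- recordingFromSequences("r", list(c("A", "B", "C")),
                              meanFreqs = c(A = 2000, B = 5000, C = 8000))
  sh <- shuffleWithinSongs(r, seed = 4)
  tok <- tokens(sh)
  expect_equal(tok$mean_freq_hz,
               c(A = 2000, B = 5000, C = 8000)[tok$type_id],
               ignore_attr = TRUE)
})

test_that("a two-token song is reversed half the time", {
  r <- recordingFromSequences("ab", list(c("A", "B")))
  set.seed(31)
  hits <- sum(vapply(1:2000, function(i) {
    songSequences(shuffleWithinSongs(r))[[1]][1] == "B"
  }, logical(1L)))
  # 3 SD binomial band around 0.5
  expect_lt(abs(hits / 2000 - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("identical seeds give bit-identical null distributions", {
  set.seed(41)
  r <- randomRecording("rep", nSongs = 6L)
  a <- nullDistribution(r, "average_degree", nReps = 20, seed = 99)
  b <- nullDistribution(r, "average_degree", nReps = 20, seed = 99)
  expect_identical(a, b)
  c <- nullDistribution(r, "average_degree", nReps = 20, seed = 100)
  expect_false(identical(a$null_mean, c$null_mean))
})

test_that("one-vs-null Cohen's d follows its definition", {
  expect_equal(songnet:::.dOneVsNull(2, c(1, 2, 3))$d, 0)
  st <- songnet:::.dOneVsNull(4, c(1, 2, 3))
  expect_equal(st$d, 2)
  expect_equal(st$var_d, (1 + 4 / 6) * 4 / 3)
  degenerate <- songnet:::.dOneVsNull(4, c(2, 2, 2))
  expect_true(is.na(degenerate$d))
})

test_that("two-sample Cohen's d uses the pooled SD", {
  st <- songnet:::.dTwoSample(c(2, 4), c(1, 3))
  expect_equal(st$d, 1 / sqrt(2))
  expect_equal(st$var_d, 4 / 4 + (1 / 2) / 8)
  expect_equal(songnet:::.dTwoSample(c(1, 2), c(1, 2))$d, 0)
})

test_that("meta-analytic pooling reproduces hand-computed DL results", {
  equal <- poolEffectSizes(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))
  expect_equal(equal$pooled_d, 0.5)
  expect_equal(equal$tau2, 0)

  sym <- poolEffectSizes(c(0, 1), c(0.1, 0.1))
  expect_equal(sym$pooled_d, 0.5)

  # frozen from an explicit inverse-variance + DL spreadsheet calculation
  dl <- poolEffectSizes(c(0.2, 0.4, 0.9), c(0.04, 0.04, 0.16))
  expect_equal(dl$tau2, 0.015, tolerance = 1e-10)
  expect_equal(dl$pooled_d, 0.381481, tolerance = 1e-5)
  expect_equal(dl$se, 0.154160, tolerance = 1e-5)
  expect_equal(dl$ci_low, 0.079333, tolerance = 1e-4)
  expect_equal(dl$ci_high, 0.683630, tolerance = 1e-4)

  expect_error(poolEffectSizes(0.5, 0.1), "at least 2")
  expect_warning(poolEffectSizes(c(0.5, 0.2, NA), c(0.1, 0.1, 0.1)),
                 "excluded")
})

test_that("a rigidly ordered grammar departs from its null in the known directions", {
  # deterministic cycle songs: every song walks A->B->...->H->A
  cyc <- lapply(1:10, function(i) LETTERS[c(seq(i %% 8 + 1, 8), 1:(i %% 8 + 1))])
  r <- recordingFromSequences("cycle", cyc)
  for (s in c(5, 17)) {
    dPath <- nullDistribution(r, "average_shortest_path", nReps = 50,
                              seed = s)$d
    dDeg <- nullDistribution(r, "average_degree", nReps = 50, seed = s)$d
    expect_gt(dPath, 0)
    expect_lt(dDeg, 0)
  }
})

test_that("exchangeable sequences pool to a null-covering effect", {
  set.seed(55)
  recs <- lapply(1:30, function(i) {
    recordingFromSequences(paste0("iid", i),
                           randomSongs(nSongs = 8L, maxLen = 10L, nTypes = 6L))
  })
  eff <- networkNullTest(recs, metrics = "average_degree", nReps = 40,
                         seed = 3)
  pm <- suppressWarnings(poolEffectSizes(eff))
  expect_lt(pm$ci_low, 0)
  expect_gt(pm$ci_high, 0)
})

test_that("frequency shifts are within-song consecutive differences", {
  r <- recordingFromSequences("f", list(c("A", "B", "C")),
                              meanFreqs = c(A = 1000, B = 3000, C = 2000))
  expect_equal(freqShiftSeries(r), c(2000, 1000))

  twoSingles <- recordingFromSequences("g", list("A", "B"))
  expect_length(freqShiftSeries(twoSingles), 0L)

  set.seed(61)
  for (i in 1:10) {
    rr <- randomRecording(paste0("c", i))
    expect_length(freqShiftSeries(rr),
                  sum(lengths(songSequences(rr)) - 1L))
  }
})

test_that("identical series yield zero frequency-shift effect", {
  # all tokens share one frequency: any shuffle gives the same series
  r <- recordingFromSequences("flat", list(c("A", "B", "A", "B")),
                              meanFreqs = c(A = 4000, B = 4000))
  expect_true(is.na(freqShiftEffect(r, seed = 2)$d))
})
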