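tokenRow <- function(rec = "r1", ind = "m1", year = 2005L, song = 0L,
                     pos = 0L, type = "A", mf = 4000, bw = 2000) {
  data.frame(recording_id = rec, individual_id = ind, year = year,
             song_index = song, position = pos, type_id = type,
             duration_s = 0.1, min_freq_hz = mf - bw / 2,
             max_freq_hz = mf + bw / 2, mean_freq_hz = mf,
             bandwidth_hz = bw)
}

writeFixture <- function(rows) {
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("a flat table parses into recordings with ordered songs", {
  rows <- rbind(tokenRow(pos = 0L, type = "A"),
                tokenRow(pos = 1L, type = "B"),
                tokenRow(pos = 2L, type = "A"))
  recs <- readSyllableTable(writeFixture(rows))
  expect_length(recs, 1L)
  r <- recs[["r1"]]
  expect_equal(nSongs(r), 1L)
  expect_equal(nSyllables(r), 3L)
  expect_equal(repertoireSize(r), 2L)
  expect_equal(songSequences(r)[[1]], c("A", "B", "A"))
})

test_that("header-only input yields an empty collection with a warning", {
  path <- writeFixture(tokenRow()[0, ])
  expect_warning(recs <- readSyllableTable(path), "no rows")
  expect_length(recs, 0L)
})

test_that("song indices may have gaps but positions may not", {
  rows <- rbind(tokenRow(song = 0L, pos = 0L), tokenRow(song = 0L, pos = 1L),
                tokenRow(song = 2L, pos = 0L), tokenRow(song = 2L, pos = 1L))
  recs <- readSyllableTable(writeFixture(rows))
  expect_equal(nSongs(recs[[1]]), 2L)

  bad <- rbind(tokenRow(pos = 0L), tokenRow(pos = 2L))
  expect_error(readSyllableTable(writeFixture(bad)), "positions")
})

test_that("schema and invariant violations are reported precisely", {
  rows <- tokenRow()
  expect_error(readSyllableTable(writeFixture(rows[, -6])), "type_id")

  bad <- tokenRow()
  bad$mean_freq_hz <- bad$max_freq_hz + 100
  expect_error(readSyllableTable(writeFixture(bad)), "row 1")

  bad <- tokenRow()
  bad$bandwidth_hz <- bad$bandwidth_hz + 5
  expect_error(readSyllableTable(writeFixture(bad)), "bandwidth")

  dup <- rbind(tokenRow(pos = 0L), tokenRow(pos = 0L))
  expect_error(readSyllableTable(writeFixture(dup)), "duplicate")
})

test_that("write-then-read round-trips token-identical data", {
  set.seed(42)
  recs <- lapply(c("a", "b", "c"), randomRecording, nSongs = 4L)
  names(recs) <- c("a", "b", "c")
  path <- tempfile(fileext = ".csv")
  writeSyllableTable(recs, path)
  back <- readSyllableTable(path)
  expect_equal(names(back), names(recs))
  for (id in names(recs)) {
    expect_equal(tokens(back[[id]])$type_id, tokens(recs[[id]])$type_id)
    expect_equal(tokens(back[[id]])$mean_freq_hz,
                 tokens(recs[[id]])$mean_freq_hz, tolerance = 1e-8)
  }
  # token count equals the sum of song lengths
  for (r in back)
    expect_equal(nSyllables(r), sum(lengths(songSequences(r))))
})

test_that("truncateSongs keeps the first n songs and is idempotent", {
  set.seed(7)
  r <- randomRecording("r", nSongs = 25L)
  t20 <- truncateSongs(r, 20)
  expect_equal(nSongs(t20), 20L)
  expect_equal(songSequences(t20), songSequences(r)[1:20])
  expect_equal(truncateSongs(t20, 20), t20)

  short <- randomRecording("s", nSongs = 12L)
  expect_warning(kept <- truncateSongs(short, 20), "only 12")
  expect_equal(kept, short)
  expect_error(truncateSongs(r, 0), "nSongs")
})

test_that("arrival standardization centres on the yearly median", {
  tr <- data.frame(year = 2000L, arrival_raw = c(100, 102, 110))
  expect_equal(standardizeArrival(tr)$arrival_std, c(-2, 0, 8))

  one <- data.frame(year = 2001L, arrival_raw = 95)
  expect_equal(standardizeArrival(one)$arrival_std, 0)

  # a uniform shift of a whole year leaves the standardized values intact
  y1 <- data.frame(year = 2000L, arrival_raw = c(100, 104, 111, 120))
  y2 <- data.frame(year = 2001L, arrival_raw = y1$arrival_raw + 7)
  both <- standardizeArrival(rbind(y1, y2))
  expect_equal(both$arrival_std[1:4], both$arrival_std[5:8])

  # yearly medians are zero after standardization
  expect_equal(as.numeric(tapply(both$arrival_std, both$year, median)),
               c(0, 0))
})

test_that("condition helper returns size-corrected mass residuals", {
  set.seed(1)
  tarsus <- rnorm(30, 19, 0.5)
  weight <- 2 * tarsus + rnorm(30, 0, 0.3)
  ci <- bodyConditionIndex(weight, tarsus)
  expect_equal(mean(ci), 0, tolerance = 1e-10)
  expect_lt(abs(cor(ci, tarsus)), 1e-10)
})
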