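# Motif-type detection in syllable sequences and original-vs-randomized
# comparison.

.SEP <- "\x1f"

#' Count motif types in a recording
#'
#' A motif type of length L is a contiguous run of L syllable types that
#' occurs (as an exact substring, no gaps or mismatches) in at least two
#' distinct songs of the recording. Repetition of a run inside a single
#' song counts as presence in that song only, so by default it does not by
#' itself make a motif; the alternative rule (`rule = "any_repeat"`)
#' accepts any run occurring at least twice in the recording, within-song
#' repeats included.
#'
#' @param recording a [SyllableRecording-class].
#' @param minLen,maxLen motif length range (default 2-10).
#' @param rule `"cross_song"` (default) or `"any_repeat"`, see Details.
#' @return data.frame with one row per length: `recording_id`, `length`,
#'   `n_motif_types` (number of distinct qualifying runs), `has_motif`.
#' @examples
#' r <- recordingFromSequences("r1", list(c("A","B","C"), c("A","B","D")))
#' findMotifs(r, 2, 3)
#' @export
findMotifs <- function(recording, minLen = 2L, maxLen = 10L,
                       rule = c("cross_song", "any_repeat")) {
  rule <- match.arg(rule)
  if (minLen < 2L || minLen > maxLen) stop("need 2 <= minLen <= maxLen")
  seqs <- songSequences(recording)
  counts <- integer(maxLen - minLen + 1L)
  for (L in minLen:maxLen) {
    perSong <- lapply(seqs, function(s) {
      if (length(s) < L) return(character())
      subs <- vapply(seq_len(length(s) - L + 1L),
                     function(i) paste(s[i:(i + L - 1L)], collapse = .SEP),
                     character(1L))
      if (rule == "cross_song") unique(subs) else subs
    })
    tab <- table(unlist(perSong, use.names = FALSE))
    counts[L - minLen + 1L] <- sum(tab >= 2L)
  }
  data.frame(recording_id = recordingId(recording), length = minLen:maxLen,
             n_motif_types = counts, has_motif = counts >= 1L,
             stringsAsFactors = FALSE)
}

#' Motif tables for many recordings
#'
#' @param recordings list of [SyllableRecording-class] objects.
#' @inheritParams findMotifs
#' @return data.frame stacking [findMotifs()] rows for all recordings.
#' @export
motifTable <- function(recordings, minLen = 2L, maxLen = 10L,
                       rule = "cross_song") {
  out <- do.call(rbind, lapply(recordings, findMotifs, minLen = minLen,
                               maxLen = maxLen, rule = rule))
  rownames(out) <- NULL
  out
}

#' Compare motif counts between original and randomized sequences
#'
#' Matched-pair comparison per motif length: for each length the number of
#' motif types in every original recording is paired with the count in its
#' randomized (within-song shuffled) counterpart and tested with the
#' Wilcoxon signed-rank test (two-sided; W = sum of ranks of positive
#' differences, normal approximation since counts tie heavily). Lengths at
#' which every paired difference is zero are reported with NA test
#' statistics. Per-arm summaries (mean, SD, percent of recordings with at
#' least one motif) accompany each test.
#'
#' @param originalTable,randomizedTable data.frames from [motifTable()];
#'   matched by `recording_id` (every original id must occur in the
#'   randomized table).
#' @return data.frame, one row per length: per-arm summaries, `W`, `p`.
#' @export
compareMotifCounts <- function(originalTable, randomizedTable) {
  lens <- sort(unique(originalTable$length))
  rows <- lapply(lens, function(L) {
    o <- originalTable[originalTable$length == L, ]
    r <- randomizedTable[randomizedTable$length == L, ]
    m <- match(o$recording_id, r$recording_id)
    if (anyNA(m)) stop("randomized table lacks recording(s): ",
                       paste(o$recording_id[is.na(m)], collapse = ", "))
    x <- o$n_motif_types
    y <- r$n_motif_types[m]
    if (all(x == y)) {
      W <- NA_real_; p <- NA_real_
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                exact = FALSE))
      W <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(length = L, n_pairs = length(x),
               mean_original = mean(x), sd_original = stats::sd(x),
               pct_with_motif_original = 100 * mean(x >= 1),
               mean_randomized = mean(y), sd_randomized = stats::sd(y),
               pct_with_motif_randomized = 100 * mean(y >= 1),
               W = W, p = p)
  })
  do.call(rbind, rows)
}
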