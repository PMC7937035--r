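#' @import methods
NULL

.TOKEN_COLS <- c("song_index", "position", "type_id", "duration_s",
                 "min_freq_hz", "max_freq_hz", "mean_freq_hz", "bandwidth_hz")

#' SyllableRecording: one individual's sampled song bout
#'
#' A `SyllableRecording` holds the ordered songs of one field recording of a
#' single singing male. Each song is an ordered run of syllable tokens; each
#' token carries its type label and the classical acoustic measurements
#' (duration, minimum/maximum/mean frequency, bandwidth). Adjacency between
#' syllable types is only ever defined within a song, so the song structure
#' is part of the data, not a display convenience.
#'
#' Validity enforces the measurement invariants (`min_freq_hz <=
#' mean_freq_hz <= max_freq_hz`, `bandwidth_hz == max_freq_hz -
#' min_freq_hz` within 1e-6) and the positional convention: within every
#' song, positions run 0, 1, 2, ... with no gaps or duplicates. Song
#' indices themselves need not be consecutive (songs may be dropped
#' upstream for quality); their ascending order defines song order.
#'
#' @slot recordingId character(1), unique recording identifier.
#' @slot individualId character(1), ring/colour identity of the male.
#' @slot year integer(1), year of the recording (NA allowed).
#' @slot tokens data.frame with one row per syllable token and columns
#'   `song_index`, `position`, `type_id`, `duration_s`, `min_freq_hz`,
#'   `max_freq_hz`, `mean_freq_hz`, `bandwidth_hz`, sorted by
#'   (`song_index`, `position`).
#'
#' @seealso [SyllableRecording()] for the user constructor,
#'   [recordingFromSequences()] for building one from bare type sequences.
#' @export
setClass("SyllableRecording",
  representation(
    recordingId  = "character",
    individualId = "character",
    year         = "integer",
    tokens       = "data.frame"
  )
)

setValidity("SyllableRecording", function(object) {
  msgs <- character()
  tok <- object@tokens
  if (length(object@recordingId) != 1L || is.na(object@recordingId) ||
      !nzchar(object@recordingId))
    msgs <- c(msgs, "recordingId must be a single non-empty string")
  missing <- setdiff(.TOKEN_COLS, names(tok))
  if (length(missing))
    return(paste0("tokens lacks column(s): ", paste(missing, collapse = ", ")))
  if (nrow(tok) == 0L)
    return("a recording must contain at least one token")
  bad <- which(!(tok$min_freq_hz <= tok$mean_freq_hz + 1e-9 &
                 tok$mean_freq_hz <= tok$max_freq_hz + 1e-9))
  if (length(bad))
    msgs <- c(msgs, paste0("min <= mean <= max frequency violated at token row ",
                           bad[1L]))
  bad <- which(abs(tok$bandwidth_hz - (tok$max_freq_hz - tok$min_freq_hz)) > 1e-6)
  if (length(bad))
    msgs <- c(msgs, paste0("bandwidth != max - min frequency at token row ", bad[1L]))
  if (any(tok$duration_s <= 0))
    msgs <- c(msgs, "all durations must be > 0")
  for (s in split(tok$position, tok$song_index)) {
    if (!identical(as.integer(sort(s)), seq_len(length(s)) - 1L)) {
      msgs <- c(msgs, "positions within each song must be consecutive from 0")
      break
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a SyllableRecording
#'
#' Tokens are re-sorted by (`song_index`, `position`) and validated; see
#' [SyllableRecording-class] for the invariants.
#'
#' @param recordingId character(1) recording identifier.
#' @param individualId character(1) individual identifier (defaults to the
#'   recording id).
#' @param year integer(1) recording year, NA allowed.
#' @param tokens data.frame of syllable tokens (one row per token).
#' @return A [SyllableRecording-class] object.
#' @examples
#' tok <- data.frame(song_index = 0L, position = 0:2,
#'                   type_id = c("A", "B", "A"), duration_s = 0.1,
#'                   min_freq_hz = 3000, max_freq_hz = 5000,
#'                   mean_freq_hz = 4000, bandwidth_hz = 2000)
#' SyllableRecording("rec1", "male1", 2005L, tok)
#' @export
SyllableRecording <- function(recordingId, individualId = recordingId,
                              year = NA_integer_, tokens) {
  tokens <- tokens[order(tokens$song_index, tokens$position), , drop = FALSE]
  rownames(tokens) <- NULL
  tokens$type_id <- as.character(tokens$type_id)
  new("SyllableRecording",
      recordingId  = as.character(recordingId),
      individualId = as.character(individualId),
      year         = as.integer(year),
      tokens       = tokens)
}

#' Build a recording from bare type sequences
#'
#' Convenience constructor when only the syllable-type order matters (e.g.
#' worked examples, fixtures): each song is a character vector of type
#' labels. Acoustic measurements are filled in per type, either from
#' `meanFreqs` (named Hz vector) or deterministically spread over 2-8 kHz.
#'
#' @param recordingId,individualId,year passed to [SyllableRecording()].
#' @param sequences list of character vectors, one per song, in song order.
#' @param meanFreqs optional named numeric vector of per-type mean
#'   frequencies (Hz); types not named get deterministic defaults.
#' @param bandwidth single bandwidth (Hz) applied to every type.
#' @return A [SyllableRecording-class] object.
#' @examples
#' recordingFromSequences("r1", sequences = list(c("A","B","C"), c("A","B","D")))
#' @export
recordingFromSequences <- function(recordingId, sequences,
                                   individualId = recordingId,
                                   year = NA_integer_,
                                   meanFreqs = NULL, bandwidth = 2000) {
  stopifnot(is.list(sequences), length(sequences) >= 1L)
  types <- sort(unique(unlist(sequences)))
  mf <- seq(2000, 8000, length.out = max(2L, length(types)))[seq_along(types)]
  names(mf) <- types
  if (!is.null(meanFreqs)) mf[names(meanFreqs)] <- meanFreqs
  rows <- lapply(seq_along(sequences), function(i) {
    s <- as.character(sequences[[i]])
    data.frame(song_index = i - 1L, position = seq_along(s) - 1L,
               type_id = s, duration_s = 0.1,
               min_freq_hz = mf[s] - bandwidth / 2,
               max_freq_hz = mf[s] + bandwidth / 2,
               mean_freq_hz = mf[s], bandwidth_hz = bandwidth)
  })
  SyllableRecording(recordingId, individualId, year, do.call(rbind, rows))
}

#' SyllableNetwork: directed syllable-type transition network
#'
#' The summed first-order adjacency structure of one recording: node labels
#' are the distinct syllable types, and `weightMatrix[A, B]` counts how
#' often a type-A token was immediately followed by a type-B token within
#' any song (never across song boundaries). The matrix is directed
#' (asymmetric: A-then-B and B-then-A are different cells) and always
#' retains diagonal (self-transition) counts; the `includeSelfLoops` flag
#' records whether the derived unweighted directed graph, on which the
#' network metrics are computed, keeps or drops those diagonal edges.
#'
#' @slot nodeLabels character vector of distinct type ids (row/col order of
#'   the matrix).
#' @slot weightMatrix square non-negative integer matrix of transition
#'   counts, dimnames equal to `nodeLabels`.
#' @slot includeSelfLoops logical(1), graph convention recorded at build
#'   time.
#' @seealso [buildNetwork()], [asGraph()], [computeMetrics()]
#' @export
setClass("SyllableNetwork",
  representation(
    nodeLabels       = "character",
    weightMatrix     = "matrix",
    includeSelfLoops = "logical"
  )
)

setValidity("SyllableNetwork", function(object) {
  W <- object@weightMatrix
  n <- length(object@nodeLabels)
  if (nrow(W) != n || ncol(W) != n)
    return("weightMatrix must be square with dimension = number of node labels")
  if (!identical(rownames(W), object@nodeLabels) ||
      !identical(colnames(W), object@nodeLabels))
    return("weightMatrix dimnames must equal nodeLabels")
  if (any(W < 0) || !.isWholeNumber(as.vector(W)))
    return("weights must be non-negative integers")
  if (anyDuplicated(object@nodeLabels))
    return("node labels must be distinct")
  TRUE
})
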