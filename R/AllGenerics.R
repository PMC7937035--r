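#' @rdname SyllableRecording-class
#' @param object,x a `SyllableRecording` or `SyllableNetwork`.
#' @export
setGeneric("recordingId", function(x) standardGeneric("recordingId"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("individualId", function(x) standardGeneric("individualId"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("recordingYear", function(x) standardGeneric("recordingYear"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("songSequences", function(x) standardGeneric("songSequences"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("nSongs", function(x) standardGeneric("nSongs"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("nSyllables", function(x) standardGeneric("nSyllables"))
#' @rdname SyllableRecording-class
#' @export
setGeneric("repertoireSize", function(x) standardGeneric("repertoireSize"))

#' @rdname SyllableNetwork-class
#' @param x a `SyllableNetwork`.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname SyllableNetwork-class
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname SyllableNetwork-class
#' @export
setGeneric("includeSelfLoops", function(x) standardGeneric("includeSelfLoops"))
#' @rdname SyllableNetwork-class
#' @export
setGeneric("asGraph", function(x) standardGeneric("asGraph"))

setMethod("recordingId", "SyllableRecording", function(x) x@recordingId)
setMethod("individualId", "SyllableRecording", function(x) x@individualId)
setMethod("recordingYear", "SyllableRecording", function(x) x@year)
setMethod("tokens", "SyllableRecording", function(x) x@tokens)
setMethod("songSequences", "SyllableRecording", function(x) {
  lapply(split(x@tokens$type_id, x@tokens$song_index), as.character)
})
setMethod("nSongs", "SyllableRecording",
          function(x) length(unique(x@tokens$song_index)))
setMethod("nSyllables", "SyllableRecording", function(x) nrow(x@tokens))
setMethod("repertoireSize", "SyllableRecording",
          function(x) length(unique(x@tokens$type_id)))

setMethod("show", "SyllableRecording", function(object) {
  cat("SyllableRecording", object@recordingId,
      sprintf("(individual %s, year %s)\n", object@individualId,
              ifelse(is.na(object@year), "?", object@year)))
  cat(" ", nSongs(object), "songs,", nSyllables(object), "syllables,",
      repertoireSize(object), "syllable types\n")
})

setMethod("nodeLabels", "SyllableNetwork", function(x) x@nodeLabels)
setMethod("weightMatrix", "SyllableNetwork", function(x) x@weightMatrix)
setMethod("includeSelfLoops", "SyllableNetwork", function(x) x@includeSelfLoops)

setMethod("show", "SyllableNetwork", function(object) {
  A <- .unweightedAdjacency(object)
  cat("SyllableNetwork:", length(object@nodeLabels), "syllable types,",
      sum(A), "directed edges",
      sprintf("(self-loops %s)\n",
              if (object@includeSelfLoops) "included" else "excluded"))
  cat("  total transitions:", sum(object@weightMatrix), "\n")
})
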