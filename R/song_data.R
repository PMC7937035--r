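# Tabular I/O and validation for syllable sequences and male traits.

.SYLLABLE_FILE_COLS <- c("recording_id", "individual_id", "year", .TOKEN_COLS)
.TRAIT_FILE_COLS <- c("individual_id", "year", "age", "arrival_raw",
                      "condition", "pairing_success", "survival_next_year")

#' Read a flat syllable table into recordings
#'
#' Ingests the product of upstream segmentation/classification: a flat
#' CSV/TSV with one row per performed syllable, carrying the recording and
#' individual identifiers, the song index, the 0-based position within the
#' song, the type label and the five classical acoustic measurements.
#' Rows are grouped by `recording_id`, songs ordered by `song_index` and
#' tokens by `position`; every [SyllableRecording-class] invariant is
#' enforced on the way in.
#'
#' @param path file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return Named list of [SyllableRecording-class] objects (names =
#'   recording ids). A header-only file yields an empty list with a
#'   warning.
#' @details Schema errors name the missing column; invariant violations
#'   (e.g. `mean_freq_hz > max_freq_hz`, duplicated
#'   `(recording, song, position)`) report the offending file row.
#' @seealso [writeSyllableTable()], [readTraitsTable()]
#' @export
readSyllableTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.SYLLABLE_FILE_COLS, names(df))
  if (length(missing))
    stop("syllable table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("syllable table ", path, " has a header but no rows")
    return(structure(list(), names = character()))
  }
  key <- paste(df$recording_id, df$song_index, df$position, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (recording, song, position) at file row ",
         which(duplicated(key))[1L])
  bad <- which(!(df$min_freq_hz <= df$mean_freq_hz + 1e-9 &
                 df$mean_freq_hz <= df$max_freq_hz + 1e-9))
  if (length(bad))
    stop("min <= mean <= max frequency violated at file row ", bad[1L])
  bad <- which(abs(df$bandwidth_hz - (df$max_freq_hz - df$min_freq_hz)) > 1e-6)
  if (length(bad))
    stop("bandwidth != max - min frequency at file row ", bad[1L])
  out <- lapply(split(df, df$recording_id), function(d) {
    SyllableRecording(d$recording_id[1L], d$individual_id[1L],
                      d$year[1L], d[, .TOKEN_COLS, drop = FALSE])
  })
  out[unique(df$recording_id)]
}

#' Write recordings back to the flat syllable table
#'
#' @param recordings list of [SyllableRecording-class] objects.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeSyllableTable <- function(recordings, path, sep = ",") {
  rows <- lapply(recordings, function(r) {
    cbind(data.frame(recording_id = recordingId(r),
                     individual_id = individualId(r),
                     year = recordingYear(r)),
          tokens(r))
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the male-trait table
#'
#' One row per (individual, year): age in years, raw arrival day-of-year,
#' body condition score and the two binary fitness proxies (pairing
#' success; recapture the next year). Optional `weight_g` and `tarsus_mm`
#' columns are retained if present so [bodyConditionIndex()] can be applied.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame of traits.
#' @export
readTraitsTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.TRAIT_FILE_COLS, names(df))
  if (length(missing))
    stop("traits table is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("pairing_success", "survival_next_year")) {
    v <- df[[col]]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop(col, " must be binary 0/1")
  }
  if (any(df$age < 1, na.rm = TRUE)) stop("age must be >= 1 year")
  df
}

#' Keep only the first n songs of a recording
#'
#' Sample-size standardisation: recordings are trimmed to their first
#' `nSongs` songs (in `song_index` order) so that every recording
#' contributes the same number of songs. A recording with fewer songs is
#' returned unchanged with a warning.
#'
#' @param recording a [SyllableRecording-class].
#' @param nSongs number of songs to keep (>= 1).
#' @return A [SyllableRecording-class] with at most `nSongs` songs.
#' @export
truncateSongs <- function(recording, nSongs) {
  if (!is.numeric(nSongs) || length(nSongs) != 1L || nSongs < 1)
    stop("nSongs must be a single number >= 1")
  idx <- sort(unique(tokens(recording)$song_index))
  if (length(idx) <= nSongs) {
    if (length(idx) < nSongs)
      warning("recording ", recordingId(recording), " has only ",
              length(idx), " songs (requested ", nSongs, ")")
    return(recording)
  }
  keep <- idx[seq_len(nSongs)]
  tok <- tokens(recording)
  SyllableRecording(recordingId(recording), individualId(recording),
                    recordingYear(recording),
                    tok[tok$song_index %in% keep, , drop = FALSE])
}

#' Centre arrival dates on the yearly population median
#'
#' Adds/overwrites `arrival_std`: raw arrival day-of-year minus the median
#' arrival of all males recorded in the same year, so 0 marks the median
#' arriver of each season and the values are comparable across years.
#' Missing `arrival_raw` values are excluded from the median and flagged
#' (their `arrival_std` stays NA).
#'
#' @param traits data.frame with columns `year` and `arrival_raw`.
#' @return The traits data.frame with an `arrival_std` column.
#' @examples
#' standardizeArrival(data.frame(year = 2000, arrival_raw = c(100, 102, 110)))
#' @export
standardizeArrival <- function(traits) {
  stopifnot(all(c("year", "arrival_raw") %in% names(traits)))
  med <- tapply(traits$arrival_raw, traits$year,
                function(v) stats::median(v, na.rm = TRUE))
  traits$arrival_std <- traits$arrival_raw - as.numeric(med[as.character(traits$year)])
  if (anyNA(traits$arrival_raw))
    message(sum(is.na(traits$arrival_raw)),
            " record(s) lack arrival_raw; excluded from medians")
  traits
}

#' Body-condition index from weight and tarsus
#'
#' Size-corrected mass: residuals of an ordinary least-squares regression
#' of body weight on tarsus length, so positive values mark males heavier
#' than expected for their skeletal size. Provided as an optional helper;
#' the analysis functions accept any precomputed `condition` column.
#'
#' @param weight numeric, body weight (g).
#' @param tarsus numeric, tarsus length (mm).
#' @return Numeric vector of residuals (mean 0).
#' @export
bodyConditionIndex <- function(weight, tarsus) {
  stopifnot(length(weight) == length(tarsus))
  as.numeric(stats::resid(stats::lm(weight ~ tarsus, na.action = stats::na.exclude)))
}
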