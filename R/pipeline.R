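# End-to-end orchestration: simulate/load -> validate -> networks ->
# null models -> motifs -> size correction -> repeatability -> trait and
# fitness models, with CSV artifacts and a reproducibility manifest.

.writeArtifact <- function(df, outDir, name) {
  path <- file.path(outDir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full syllable-network analysis pipeline
#'
#' Executes every stage of the analysis and writes one CSV artifact per
#' stage plus a JSON manifest (configuration, seed, package version) that
#' suffices to reproduce the run bit-for-bit. Inputs are either flat
#' tables ([readSyllableTable()] / [readTraitsTable()]) or, when
#' `syllablePath` is NULL, a synthetic population generated by
#' [simulatePopulation()] from `config` (the corpus is then also written
#' out as `syllables.csv` / `traits.csv`).
#'
#' Stages: song truncation, network metrics, descriptive connection
#' statistics, permutation null test with meta-analytic pooling,
#' frequency-shift contrast, motif detection and original-vs-randomized
#' comparison, variable inter-correlations, size correction, repeatability
#' (simulated corpora, or individuals with two recordings in file mode),
#' and quality/fitness models. A missing trait table skips the trait
#' stages with a warning; earlier artifacts are kept. Any stage failure
#' aborts with an error naming the stage.
#'
#' @param outDir output directory (created if needed).
#' @param config a [simulationConfig()]; used for simulation and as the
#'   source of the seed.
#' @param syllablePath,traitsPath optional input tables; NULL simulates.
#' @param nNullReps randomized sequences per recording (default 100).
#' @param nBoot bootstrap iterations for repeatability (default 1000).
#' @param songsPerRecording songs kept per recording (default 20).
#' @param motifLengths motif length range (default 2:10).
#' @param includeSelfLoops,swMode network-metric options.
#' @return Invisibly, a list with the in-memory results (metrics, effects,
#'   pooled meta table, motif tests, repeatability, model reports) and the
#'   artifact paths.
#' @export
runPipeline <- function(outDir, config = simulationConfig(),
                        syllablePath = NULL, traitsPath = NULL,
                        nNullReps = 100L, nBoot = 1000L,
                        songsPerRecording = 20L, motifLengths = 2:10,
                        includeSelfLoops = FALSE, swMode = "analytic") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  artifacts <- character()
  res <- list()

  # --- inputs -------------------------------------------------------------
  repeats <- NULL
  if (is.null(syllablePath)) {
    pop <- stage("simulate", simulatePopulation(config))
    recordings <- pop$recordings
    traits <- pop$traits
    repeats <- pop$repeats
    artifacts["syllables"] <- .writeArtifact(
      do.call(rbind, lapply(unname(recordings), function(r)
        cbind(data.frame(recording_id = recordingId(r),
                         individual_id = individualId(r),
                         year = recordingYear(r)), tokens(r)))),
      outDir, "syllables.csv")
    artifacts["traits"] <- .writeArtifact(traits, outDir, "traits.csv")
  } else {
    recordings <- stage("read", readSyllableTable(syllablePath))
    traits <- NULL
    if (!is.null(traitsPath) && file.exists(traitsPath)) {
      traits <- stage("read", readTraitsTable(traitsPath))
      if (!"arrival_std" %in% names(traits))
        traits <- standardizeArrival(traits)
    } else if (!is.null(traitsPath)) {
      warning("traits table not found at ", traitsPath,
              "; trait stages skipped")
    }
  }

  # --- per-recording descriptors ------------------------------------------
  recordings <- stage("truncate", lapply(recordings, function(r)
    suppressWarnings(truncateSongs(r, songsPerRecording))))
  res$metrics <- stage("metrics",
                       metricsTable(recordings, includeSelfLoops, swMode))
  artifacts["metrics"] <- .writeArtifact(res$metrics, outDir, "metrics.csv")

  res$descriptives <- stage("descriptives", {
    d <- do.call(rbind, lapply(recordings, function(r)
      descriptiveStats(buildNetwork(r, includeSelfLoops))))
    cbind(data.frame(recording_id = res$metrics$recording_id), d)
  })
  artifacts["descriptives"] <- .writeArtifact(res$descriptives, outDir,
                                              "descriptives.csv")

  # --- null models ---------------------------------------------------------
  res$effects <- stage("nulltest",
                       networkNullTest(recordings, nReps = nNullReps,
                                       seed = config$seed,
                                       includeSelfLoops = includeSelfLoops,
                                       swMode = swMode))
  artifacts["effects"] <- .writeArtifact(res$effects, outDir, "effects.csv")

  res$freqShift <- stage("freqshift", do.call(rbind, lapply(
    unname(recordings), freqShiftEffect, seed = config$seed + 1L)))
  artifacts["freqshift"] <- .writeArtifact(res$freqShift, outDir,
                                           "freqshift.csv")

  res$meta <- stage("meta", {
    byVar <- rbind(res$effects, res$freqShift)
    out <- do.call(rbind, lapply(split(byVar, byVar$variable), function(e)
      cbind(data.frame(variable = e$variable[1L]),
            suppressWarnings(poolEffectSizes(e)))))
    rownames(out) <- NULL
    out
  })
  artifacts["meta"] <- .writeArtifact(res$meta, outDir, "meta.csv")

  # --- motifs --------------------------------------------------------------
  res$motifs <- stage("motifs", {
    orig <- motifTable(recordings, min(motifLengths), max(motifLengths))
    shuffled <- lapply(recordings, shuffleWithinSongs,
                       seed = config$seed + 2L)
    rand <- motifTable(shuffled, min(motifLengths), max(motifLengths))
    orig$arm <- "original"
    rand$arm <- "randomized"
    list(table = rbind(orig, rand), tests = compareMotifCounts(orig, rand))
  })
  artifacts["motifs"] <- .writeArtifact(res$motifs$table, outDir, "motifs.csv")
  artifacts["motif_tests"] <- .writeArtifact(res$motifs$tests, outDir,
                                             "motif_tests.csv")

  # --- size correction and correlations ------------------------------------
  res$metrics <- stage("residualize",
                       residualizeMetrics(res$metrics,
                                          logTransform = "small_worldness"))
  sixVars <- c("repertoire_size", "n_syllables", .METRIC_NAMES)
  res$correlations <- stage("correlations",
                            correlationMatrix(res$metrics[, sixVars]))
  artifacts["correlations"] <- .writeArtifact(
    data.frame(variable = rownames(res$correlations$rho),
               round(res$correlations$rho, 4)),
    outDir, "correlations.csv")

  # --- repeatability --------------------------------------------------------
  residVars <- paste0(.METRIC_NAMES, "_resid")
  res$repeatability <- stage("repeatability", {
    if (!is.null(repeats)) {
      do.call(rbind, lapply(names(repeats), function(scale) {
        pairs <- repeats[[scale]]
        if (length(pairs) < 2L) return(NULL)
        recs <- unlist(lapply(pairs, function(p) list(p$first, p$second)),
                       recursive = FALSE)
        mt <- metricsTable(recs, includeSelfLoops, swMode)
        mt$age <- unlist(lapply(pairs, function(p)
          c(p$age_first, p$age_second)))
        mt <- residualizeMetrics(mt, logTransform = "small_worldness")
        repeatabilityTable(mt, residVars, timeScale = scale, nBoot = nBoot,
                           seed = config$seed + 3L)
      }))
    } else {
      counts <- table(res$metrics$individual_id)
      dup <- names(counts)[counts >= 2L]
      if (length(dup) < 2L) {
        warning("fewer than 2 individuals with repeated recordings; ",
                "repeatability skipped")
        NULL
      } else {
        mt <- res$metrics[res$metrics$individual_id %in% dup, ]
        mt <- do.call(rbind, lapply(split(mt, mt$individual_id),
                                    function(d) d[1:2, ]))
        repeatabilityTable(mt, residVars, timeScale = "repeated_recordings",
                           nBoot = nBoot, seed = config$seed + 3L)
      }
    }
  })
  if (!is.null(res$repeatability))
    artifacts["repeatability"] <- .writeArtifact(res$repeatability, outDir,
                                                 "repeatability.csv")

  # --- trait and fitness models ---------------------------------------------
  if (!is.null(traits)) {
    merged <- stage("merge", merge(res$metrics, traits,
                                   by = "individual_id",
                                   suffixes = c("", ".trait")))
    eligible <- residVars
    if (!is.null(res$repeatability)) {
      sig <- unique(res$repeatability$variable[res$repeatability$significant])
      if (length(sig)) eligible <- intersect(residVars, sig)
    }
    res$qualityModels <- stage("quality_models", lapply(eligible, function(v)
      fitQualityModel(merged, v, bonferroniN = length(eligible))))
    qrows <- do.call(rbind, lapply(res$qualityModels, function(m)
      cbind(data.frame(response = m$response, r2 = m$r2, n = m$n), m$terms)))
    artifacts["quality_models"] <- .writeArtifact(qrows, outDir,
                                                  "quality_models.csv")
    res$fitnessModels <- stage("fitness_models", Filter(Negate(is.null), lapply(
      c("pairing_success", "survival_next_year"), function(y)
        tryCatch(fitFitnessModel(merged, y, networkVars = eligible,
                                 bonferroniN = 2L),
                 error = function(e) {
                   if (!grepl("degenerate", conditionMessage(e))) stop(e)
                   warning("fitness model for ", y,
                           " skipped: constant response")
                   NULL
                 }))))
    frows <- do.call(rbind, lapply(res$fitnessModels, function(m)
      cbind(data.frame(response = m$response, pseudo_r2 = m$pseudo_r2,
                       n = m$n), m$terms)))
    if (!is.null(frows))
      artifacts["fitness_models"] <- .writeArtifact(frows, outDir,
                                                    "fitness_models.csv")
  } else {
    warning("no trait table; quality and fitness model stages skipped")
  }

  # --- manifest --------------------------------------------------------------
  manifest <- list(
    package = "songnet",
    version = as.character(utils::packageVersion("songnet")),
    seed = config$seed,
    n_null_reps = nNullReps, n_boot = nBoot,
    songs_per_recording = songsPerRecording,
    motif_lengths = range(motifLengths),
    include_self_loops = includeSelfLoops, sw_mode = swMode,
    config = config[setdiff(names(config), "traitCoefficients")],
    trait_coefficients = config$traitCoefficients,
    artifacts = as.list(artifacts))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$artifacts <- c(artifacts, manifest = file.path(outDir, "manifest.json"))
  invisible(res)
}
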