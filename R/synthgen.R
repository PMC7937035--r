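# Synthetic song corpus generator: individual grammars, recordings,
# repeated recordings and trait tables with known ground truth.

#' Configuration for the synthetic song generator
#'
#' Collects every tunable of the generator with defaults chosen to emulate
#' a field corpus of territorial flycatcher song: repertoire sizes drawn
#' from a truncated normal with mean 47 and SD 19.8 on [12, 105], 20 songs
#' per recording, song lengths around 7 syllables plus spliced motifs so
#' that recordings total roughly 100-350 syllables, and 176 individuals in
#' the primary sample. Individual song grammars are sparse first-order
#' transition graphs (a backbone cycle through the repertoire plus
#' Poisson-distributed extra branches), optionally biased toward
#' frequency-alternating transitions, with a private library of fixed
#' motifs spliced into songs.
#'
#' @param nIndividuals number of individuals in the primary sample.
#' @param songsPerRecording songs per recording.
#' @param songLengthMean,songLengthSD Gaussian song length (syllables),
#'   clipped at 2, before motif splicing.
#' @param repertoireMean,repertoireSD,repertoireMin,repertoireMax
#'   truncated-normal repertoire-size distribution.
#' @param branchRate mean number of extra out-neighbours per syllable type
#'   beyond the backbone cycle (Poisson rate at age 1).
#' @param ageEffectOnBranching additive change in the branch rate per year
#'   of age above 1; negative values make older males' grammars sparser
#'   (lower average degree).
#' @param motifCount motifs in each individual's library.
#' @param motifLengthRange inclusive length range of library motifs.
#' @param pMotif probability that a song receives one spliced motif.
#' @param freqAlternationWeight bias `beta >= 0`: transition probabilities
#'   are reweighted proportional to `exp(beta * |delta mean freq| / 1000)`,
#'   favouring large frequency jumps between consecutive syllables.
#' @param grammarNoise named vector of within-individual grammar
#'   perturbation rates per time scale (probability that a syllable type's
#'   branches are redrawn between the two recordings); 0 = identical
#'   grammar, 1 = fully redrawn.
#' @param nRepeatIndividuals named vector: individuals with repeated
#'   recordings per time scale.
#' @param traitCoefficients list of logistic coefficient vectors
#'   (`intercept`, `age`, `arrival`, `condition`) for the two binary
#'   fitness proxies.
#' @param years candidate recording years.
#' @param seed integer seed; the seed plus this configuration fully
#'   determine the corpus.
#' @return A list of class `songnetSimConfig`.
#' @export
simulationConfig <- function(nIndividuals = 176L,
                             songsPerRecording = 20L,
                             songLengthMean = 7,
                             songLengthSD = 2.5,
                             repertoireMean = 47,
                             repertoireSD = 19.8,
                             repertoireMin = 12L,
                             repertoireMax = 105L,
                             branchRate = 0.75,
                             ageEffectOnBranching = -0.1,
                             motifCount = 3L,
                             motifLengthRange = c(5L, 8L),
                             pMotif = 0.5,
                             freqAlternationWeight = 0.5,
                             grammarNoise = c(within_day = 0.05,
                                              between_days = 0.15,
                                              between_years = 0.4),
                             nRepeatIndividuals = c(within_day = 34L,
                                                    between_days = 24L,
                                                    between_years = 13L),
                             traitCoefficients = list(
                               pairing_success = c(intercept = 1.5, age = 0.3,
                                                   arrival = -0.08,
                                                   condition = 0),
                               survival_next_year = c(intercept = -0.5,
                                                      age = 0, arrival = 0,
                                                      condition = 0.3)),
                             years = 1999:2012,
                             seed = 1L) {
  cfg <- list(nIndividuals = as.integer(nIndividuals),
              songsPerRecording = as.integer(songsPerRecording),
              songLengthMean = songLengthMean, songLengthSD = songLengthSD,
              repertoireMean = repertoireMean, repertoireSD = repertoireSD,
              repertoireMin = as.integer(repertoireMin),
              repertoireMax = as.integer(repertoireMax),
              branchRate = branchRate,
              ageEffectOnBranching = ageEffectOnBranching,
              motifCount = as.integer(motifCount),
              motifLengthRange = as.integer(motifLengthRange),
              pMotif = pMotif,
              freqAlternationWeight = freqAlternationWeight,
              grammarNoise = grammarNoise,
              nRepeatIndividuals = nRepeatIndividuals,
              traitCoefficients = traitCoefficients,
              years = as.integer(years),
              seed = as.integer(seed))
  stopifnot(cfg$nIndividuals >= 1L, cfg$songsPerRecording >= 1L,
            cfg$branchRate >= 0, cfg$pMotif >= 0, cfg$pMotif <= 1,
            cfg$freqAlternationWeight >= 0,
            all(cfg$grammarNoise >= 0), all(cfg$grammarNoise <= 1),
            cfg$repertoireMin >= 2L,
            cfg$repertoireMin <= cfg$repertoireMax,
            all(cfg$motifLengthRange >= 2L),
            diff(cfg$motifLengthRange) >= 0)
  class(cfg) <- "songnetSimConfig"
  cfg
}

# draw branch targets and transition probabilities for one node
.drawBranches <- function(i, R, lambda, freqs, beta) {
  backbone <- if (i < R) i + 1L else 1L
  others <- setdiff(seq_len(R), c(i, backbone))
  nExtra <- min(stats::rpois(1L, lambda), length(others))
  succ <- c(backbone,
            if (nExtra > 0L) others[sample.int(length(others), nExtra)]
            else integer())
  w <- exp(beta * abs(freqs[succ] - freqs[i]) / 1000)
  list(succ = succ, prob = w / sum(w))
}

#' Simulate one individual's song grammar
#'
#' A grammar is a sparse first-order transition structure over the
#' individual's repertoire: a backbone cycle through all syllable types
#' (so any walk can continue indefinitely) plus, for each type, a Poisson
#' number of extra out-neighbours with rate
#' `max(0, branchRate + ageEffectOnBranching * (age - 1))`. Each syllable
#' type carries a mean frequency drawn uniformly on 2-8 kHz, a duration
#' and a bandwidth; when `freqAlternationWeight > 0` the transition
#' probabilities out of each type favour targets with distant mean
#' frequency. A private motif library of fixed random type sequences is
#' attached. Uses the current RNG state.
#'
#' @param config a [simulationConfig()].
#' @param age the individual's age in years (>= 1).
#' @return A list of class `songnetGrammar`: `repertoire`, `types`
#'   (data.frame of per-type acoustics), `succ`/`prob` (per-type branch
#'   lists), `motifs`, `age`, `lambda`.
#' @export
simulateIndividualGrammar <- function(config, age = 1L) {
  R <- as.integer(round(.rtruncnorm1(config$repertoireMean,
                                     config$repertoireSD,
                                     config$repertoireMin,
                                     config$repertoireMax)))
  types <- data.frame(
    type_id = sprintf("T%03d", seq_len(R)),
    mean_freq_hz = stats::runif(R, 2000, 8000),
    duration_s = stats::runif(R, 0.04, 0.25),
    bandwidth_hz = stats::runif(R, 500, 4000))
  lambda <- max(0, config$branchRate +
                   config$ageEffectOnBranching * (age - 1))
  beta <- config$freqAlternationWeight
  branches <- lapply(seq_len(R), .drawBranches, R = R, lambda = lambda,
                     freqs = types$mean_freq_hz, beta = beta)
  lens <- sample(seq(config$motifLengthRange[1L], config$motifLengthRange[2L]),
                 config$motifCount, replace = TRUE)
  motifs <- lapply(lens, function(L) {
    m <- sample.int(R, L, replace = R < L)
    # avoid immediate repeats inside a motif
    for (k in which(diff(m) == 0)) {
      alt <- setdiff(seq_len(R), m[k])
      m[k + 1L] <- alt[sample.int(length(alt), 1L)]
    }
    m
  })
  structure(list(repertoire = R, types = types,
                 succ = lapply(branches, `[[`, "succ"),
                 prob = lapply(branches, `[[`, "prob"),
                 motifs = motifs, age = age, lambda = lambda),
            class = "songnetGrammar")
}

#' Perturb a grammar between repeated recordings
#'
#' Models within-individual drift: each syllable type's branch set (and
#' transition probabilities) is redrawn with probability `epsilon`, and
#' each library motif is replaced with probability `epsilon`. The
#' repertoire and per-type acoustics are kept. `epsilon = 0` returns the
#' grammar unchanged; `epsilon = 1` redraws the whole transition
#' structure.
#'
#' @param grammar a `songnetGrammar`.
#' @param epsilon perturbation probability in [0, 1].
#' @param config the [simulationConfig()] that produced the grammar.
#' @return A perturbed `songnetGrammar`.
#' @export
perturbGrammar <- function(grammar, epsilon, config) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon == 0) return(grammar)
  R <- grammar$repertoire
  freqs <- grammar$types$mean_freq_hz
  beta <- config$freqAlternationWeight
  redraw <- stats::runif(R) < epsilon
  for (i in which(redraw)) {
    b <- .drawBranches(i, R, grammar$lambda, freqs, beta)
    grammar$succ[[i]] <- b$succ
    grammar$prob[[i]] <- b$prob
  }
  for (k in seq_along(grammar$motifs)) {
    if (stats::runif(1L) < epsilon) {
      L <- length(grammar$motifs[[k]])
      m <- sample.int(R, L, replace = R < L)
      for (j in which(diff(m) == 0)) {
        alt <- setdiff(seq_len(R), m[j])
        m[j + 1L] <- alt[sample.int(length(alt), 1L)]
      }
      grammar$motifs[[k]] <- m
    }
  }
  grammar
}

#' Simulate one recording from a grammar
#'
#' Generates `songsPerRecording` songs: each is a random walk over the
#' grammar from a uniform start (length Gaussian, clipped at 2), and with
#' probability `pMotif` one library motif is spliced in at a uniform
#' position. Tokens carry the type's acoustic values with small jitter
#' (frequency SD 30 Hz, duration 5%); min/max frequency are placed
#' symmetrically around the jittered mean so the measurement invariants
#' hold exactly. Uses the current RNG state.
#'
#' @param grammar a `songnetGrammar`.
#' @param config a [simulationConfig()].
#' @param recordingId,individualId,year recording metadata.
#' @return A [SyllableRecording-class].
#' @export
simulateRecording <- function(grammar, config, recordingId,
                              individualId = recordingId,
                              year = NA_integer_) {
  R <- grammar$repertoire
  songs <- vector("list", config$songsPerRecording)
  for (k in seq_len(config$songsPerRecording)) {
    L <- max(2L, as.integer(round(stats::rnorm(1L, config$songLengthMean,
                                               config$songLengthSD))))
    s <- integer(L)
    s[1L] <- sample.int(R, 1L)
    for (t in seq_len(L - 1L)) {
      sc <- grammar$succ[[s[t]]]
      s[t + 1L] <- if (length(sc) == 1L) sc else
        sample(sc, 1L, prob = grammar$prob[[s[t]]])
    }
    if (length(grammar$motifs) && stats::runif(1L) < config$pMotif) {
      m <- grammar$motifs[[sample.int(length(grammar$motifs), 1L)]]
      pos <- sample.int(L + 1L, 1L) - 1L
      s <- append(s, m, after = pos)
    }
    songs[[k]] <- s
  }
  ty <- grammar$types
  rows <- lapply(seq_along(songs), function(k) {
    s <- songs[[k]]
    n <- length(s)
    mf <- ty$mean_freq_hz[s] + stats::rnorm(n, 0, 30)
    bw <- pmax(100, ty$bandwidth_hz[s] * exp(stats::rnorm(n, 0, 0.05)))
    data.frame(song_index = k - 1L, position = seq_len(n) - 1L,
               type_id = ty$type_id[s],
               duration_s = ty$duration_s[s] * exp(stats::rnorm(n, 0, 0.05)),
               min_freq_hz = mf - bw / 2, max_freq_hz = mf + bw / 2,
               mean_freq_hz = mf, bandwidth_hz = bw)
  })
  SyllableRecording(recordingId, individualId, year, do.call(rbind, rows))
}

#' Simulate a full study population
#'
#' Produces the complete synthetic corpus: one primary recording per
#' individual, repeated-recording pairs at three time scales (grammar
#' perturbed with the scale-specific `grammarNoise`; the between-year
#' repeat ages the bird by one year), and a trait table. Ages follow a
#' shifted geometric distribution with mean about 1.9 years (truncated at
#' 7); arrival dates are Gaussian day-of-year values centred per year by
#' [standardizeArrival()]; condition is a standard-normal score; the
#' binary fitness proxies are Bernoulli draws from the configured logistic
#' models (network variables have no direct effect on fitness under the
#' default ground truth).
#'
#' @param config a [simulationConfig()]; `config$seed` determines the
#'   corpus completely.
#' @return List with elements `recordings` (named list of
#'   [SyllableRecording-class]), `repeats` (per-scale lists of recording
#'   pairs), `traits` (data.frame) and `groundTruth` (list: config, ages,
#'   per-individual lambda, trait linear predictors).
#' @export
simulatePopulation <- function(config = simulationConfig()) {
  set.seed(config$seed)
  n <- config$nIndividuals
  ages <- pmin(1L + stats::rgeom(n, prob = 1 / 1.9), 7L)
  years <- sample(config$years, n, replace = TRUE)
  ids <- sprintf("M%03d", seq_len(n))
  grammars <- lapply(seq_len(n), function(i)
    simulateIndividualGrammar(config, age = ages[i]))
  recordings <- lapply(seq_len(n), function(i)
    simulateRecording(grammars[[i]], config, sprintf("R%03d", i), ids[i],
                      years[i]))
  names(recordings) <- vapply(recordings, recordingId, character(1L))

  repeats <- lapply(names(config$nRepeatIndividuals), function(scale) {
    k <- min(config$nRepeatIndividuals[[scale]], n)
    eps <- config$grammarNoise[[scale]]
    out <- lapply(seq_len(k), function(i) {
      g1 <- grammars[[i]]
      age2 <- if (scale == "between_years") ages[i] + 1L else ages[i]
      year2 <- if (scale == "between_years") years[i] + 1L else years[i]
      g2 <- perturbGrammar(g1, eps, config)
      list(first = simulateRecording(g1, config,
                                     sprintf("%s_%03d_a", scale, i), ids[i],
                                     years[i]),
           second = simulateRecording(g2, config,
                                      sprintf("%s_%03d_b", scale, i), ids[i],
                                      year2),
           age_first = ages[i], age_second = age2)
    })
    names(out) <- ids[seq_len(k)]
    out
  })
  names(repeats) <- names(config$nRepeatIndividuals)

  traits <- data.frame(individual_id = ids, year = years, age = ages,
                       arrival_raw = as.integer(round(stats::rnorm(n, 125, 7))),
                       condition = stats::rnorm(n))
  traits <- standardizeArrival(traits)
  linpred <- lapply(config$traitCoefficients, function(b) {
    b["intercept"] + b["age"] * ages + b["arrival"] * traits$arrival_std +
      b["condition"] * traits$condition
  })
  traits$pairing_success <- stats::rbinom(n, 1L,
                                          stats::plogis(linpred$pairing_success))
  traits$survival_next_year <- stats::rbinom(
    n, 1L, stats::plogis(linpred$survival_next_year))

  groundTruth <- list(config = config, ages = ages,
                      lambda = vapply(grammars, `[[`, numeric(1L), "lambda"),
                      repertoire = vapply(grammars, `[[`, integer(1L),
                                          "repertoire"),
                      linear_predictors = linpred)
  list(recordings = recordings, repeats = repeats, traits = traits,
       groundTruth = groundTruth)
}
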