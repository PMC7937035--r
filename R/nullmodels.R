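# Within-song permutation null models, per-recording effect sizes and
# random-effects meta-analytic pooling.

# Cohen's d for one observation against a null sample, with the sampling
# variance of a 1-vs-n two-group contrast.
.dOneVsNull <- function(observed, null) {
  m <- mean(null)
  s <- stats::sd(null)
  n <- length(null)
  if (!is.finite(s) || s == 0) {
    return(list(d = NA_real_, var_d = NA_real_, null_mean = m, null_sd = s,
                n_null = n))
  }
  d <- (observed - m) / s
  var_d <- (1 + d^2 / (2 * n)) * (n + 1) / n
  list(d = d, var_d = var_d, null_mean = m, null_sd = s, n_null = n)
}

# Two-sample Cohen's d with pooled SD and its standard sampling variance.
.dTwoSample <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 == 0) return(list(d = NA_real_, var_d = NA_real_))
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  var_d <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  list(d = d, var_d = var_d)
}

#' Randomize syllable order within songs
#'
#' The bout-preserving null model: each song's tokens are independently and
#' uniformly permuted, so song count, song lengths and each song's
#' multiset of syllable types are exactly conserved while the order - the
#' quantity under study - is destroyed. Acoustic measurements travel with
#' their tokens.
#'
#' @param recording a [SyllableRecording-class].
#' @param seed optional integer; if supplied, seeds the RNG (combined with
#'   the recording id so substreams are order-independent). With `NULL`
#'   the current RNG state is used.
#' @return A shuffled [SyllableRecording-class].
#' @export
shuffleWithinSongs <- function(recording, seed = NULL) {
  if (!is.null(seed)) set.seed(.hashSeed(seed, recordingId(recording)))
  tok <- tokens(recording)
  parts <- split(seq_len(nrow(tok)), tok$song_index)
  ord <- unlist(lapply(parts, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix))]
  }), use.names = FALSE)
  out <- tok[ord, , drop = FALSE]
  out$position <- unlist(lapply(parts, function(ix) seq_along(ix) - 1L),
                         use.names = FALSE)
  SyllableRecording(recordingId(recording), individualId(recording),
                    recordingYear(recording), out)
}

.metricFun <- function(metric, includeSelfLoops, swMode) {
  force(metric)
  function(rec) {
    net <- buildNetwork(rec, includeSelfLoops)
    switch(metric,
           average_degree = averageDegree(net),
           average_shortest_path = averageShortestPath(net),
           clustering_coefficient = clusteringCoefficient(net),
           small_worldness = smallWorldness(net, mode = swMode),
           stop("unknown metric: ", metric))
  }
}

#' Effect size of one recording against its permutation null
#'
#' Computes the chosen network variable on the original recording and on
#' `nReps` within-song shuffles, then summarises the departure from the
#' null as Cohen's d: `(observed - null mean) / null SD` (null sample SD),
#' with the sampling variance of a one-observation-versus-group contrast,
#' `var_d = (1 + d^2 / (2 n)) * (n + 1) / n`. Shuffles on which the metric
#' is undefined are dropped from the null sample.
#'
#' @param recording a [SyllableRecording-class].
#' @param metric one of `"average_degree"`, `"average_shortest_path"`,
#'   `"clustering_coefficient"`, `"small_worldness"`.
#' @param nReps number of randomized sequences (default 100).
#' @param seed optional integer seed (per-recording substream).
#' @param includeSelfLoops,swMode metric options, see [computeMetrics()].
#' @return One-row data.frame: recording id, variable, observed, null
#'   mean/SD, n_null, d, var_d. `d` is NA when the null SD is zero; such
#'   recordings are excluded from pooling with a warning there.
#' @export
nullDistribution <- function(recording, metric = .METRIC_NAMES, nReps = 100L,
                             seed = NULL, includeSelfLoops = FALSE,
                             swMode = "analytic") {
  metric <- match.arg(metric)
  if (nReps < 2L) stop("nReps must be >= 2")
  f <- .metricFun(metric, includeSelfLoops, swMode)
  observed <- f(recording)
  if (!is.null(seed)) set.seed(.hashSeed(seed, recordingId(recording)))
  nulls <- vapply(seq_len(nReps),
                  function(i) f(shuffleWithinSongs(recording)), numeric(1L))
  nulls <- nulls[is.finite(nulls)]
  st <- .dOneVsNull(observed, nulls)
  data.frame(recording_id = recordingId(recording), variable = metric,
             observed = observed, null_mean = st$null_mean,
             null_sd = st$null_sd, n_null = st$n_null, d = st$d,
             var_d = st$var_d, stringsAsFactors = FALSE)
}

#' Null-model effect sizes for many recordings and all network variables
#'
#' Efficient batch version of [nullDistribution()]: each shuffled copy is
#' built once and all requested variables are measured on it. Every
#' recording gets its own RNG substream derived from `seed` and its id, so
#' results do not depend on processing order.
#'
#' @param recordings list of [SyllableRecording-class] objects.
#' @param metrics character vector of variables to test.
#' @param nReps randomized sequences per recording (default 100).
#' @param seed integer seed.
#' @param includeSelfLoops,swMode metric options.
#' @return data.frame with one row per recording x variable (columns as in
#'   [nullDistribution()]).
#' @export
networkNullTest <- function(recordings, metrics = .METRIC_NAMES,
                            nReps = 100L, seed = 1L,
                            includeSelfLoops = FALSE, swMode = "analytic") {
  metrics <- match.arg(metrics, .METRIC_NAMES, several.ok = TRUE)
  funs <- lapply(metrics, .metricFun, includeSelfLoops = includeSelfLoops,
                 swMode = swMode)
  names(funs) <- metrics
  rows <- lapply(recordings, function(rec) {
    obs <- vapply(funs, function(f) f(rec), numeric(1L))
    set.seed(.hashSeed(seed, recordingId(rec)))
    nulls <- matrix(NA_real_, nReps, length(metrics),
                    dimnames = list(NULL, metrics))
    for (b in seq_len(nReps)) {
      sh <- shuffleWithinSongs(rec)
      nulls[b, ] <- vapply(funs, function(f) f(sh), numeric(1L))
    }
    do.call(rbind, lapply(metrics, function(mname) {
      nv <- nulls[, mname]
      st <- .dOneVsNull(obs[[mname]], nv[is.finite(nv)])
      data.frame(recording_id = recordingId(rec), variable = mname,
                 observed = obs[[mname]], null_mean = st$null_mean,
                 null_sd = st$null_sd, n_null = st$n_null, d = st$d,
                 var_d = st$var_d, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool per-recording effect sizes meta-analytically
#'
#' Random-effects pooling of Cohen's d values weighted by their sampling
#' variances: between-recording heterogeneity tau^2 by DerSimonian-Laird,
#' weights `1 / (var_d + tau^2)`, 95% CI = pooled +/- 1.96 se. Recordings
#' with undefined d or var_d are dropped with a warning.
#'
#' @param d numeric vector of effect sizes, or a data.frame with columns
#'   `d` and `var_d` (e.g. one variable's rows of [networkNullTest()]).
#' @param var_d numeric vector of sampling variances (ignored when `d` is
#'   a data.frame).
#' @param method heterogeneity estimator passed to [metafor::rma()]
#'   (default `"DL"`; `"FE"` gives a fixed-effect model).
#' @return One-row data.frame: `k`, `pooled_d`, `se`, `ci_low`, `ci_high`,
#'   `tau2`.
#' @examples
#' poolEffectSizes(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1))
#' @export
poolEffectSizes <- function(d, var_d = NULL, method = "DL") {
  if (is.data.frame(d)) {
    var_d <- d$var_d
    d <- d$d
  }
  ok <- is.finite(d) & is.finite(var_d) & var_d > 0
  if (any(!ok))
    warning(sum(!ok), " effect size(s) undefined; excluded from pooling")
  d <- d[ok]
  var_d <- var_d[ok]
  if (length(d) < 2L) stop("need at least 2 usable effect sizes to pool")
  fit <- metafor::rma(yi = d, vi = var_d, method = method)
  data.frame(k = fit$k, pooled_d = as.numeric(fit$beta), se = fit$se,
             ci_low = fit$ci.lb, ci_high = fit$ci.ub, tau2 = fit$tau2)
}

#' Frequency shifts between consecutive syllables
#'
#' Absolute differences in mean frequency (Hz) between consecutive tokens
#' within each song; no cross-song pairs. The series length equals the sum
#' over songs of (song length - 1).
#'
#' @param recording a [SyllableRecording-class].
#' @return Numeric vector (possibly empty) of |delta mean frequency| in Hz.
#' @export
freqShiftSeries <- function(recording) {
  tok <- tokens(recording)
  unlist(lapply(split(tok$mean_freq_hz, tok$song_index), function(f) {
    if (length(f) < 2L) numeric() else abs(diff(f))
  }), use.names = FALSE)
}

#' Effect size of the consecutive-syllable frequency shift
#'
#' Compares the frequency-shift series of the original sequences against
#' the series from a single within-song shuffle (the many syllable pairs
#' within one recording make one randomization sufficient), as a
#' two-sample Cohen's d with pooled SD;
#' `var_d = (n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))`. Positive d means
#' consecutive syllables differ more in frequency than chance ordering of
#' the same syllables would produce.
#'
#' @param recording a [SyllableRecording-class].
#' @param seed optional integer seed (per-recording substream).
#' @return One-row data.frame in the same layout as [nullDistribution()],
#'   with `variable = "freq_shift"`; d is NA when the pooled SD is zero.
#' @export
freqShiftEffect <- function(recording, seed = NULL) {
  x <- freqShiftSeries(recording)
  if (!length(x)) stop("recording has no consecutive syllable pair")
  if (!is.null(seed)) set.seed(.hashSeed(seed, recordingId(recording)))
  y <- freqShiftSeries(shuffleWithinSongs(recording))
  st <- .dTwoSample(x, y)
  data.frame(recording_id = recordingId(recording), variable = "freq_shift",
             observed = mean(x), null_mean = mean(y), null_sd = stats::sd(y),
             n_null = length(y), d = st$d, var_d = st$var_d,
             stringsAsFactors = FALSE)
}
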