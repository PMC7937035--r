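# Inter-correlations, size correction, and repeatability of the network
# variables.

#' Pairwise Pearson correlations with Bonferroni adjustment
#'
#' Correlates every pair of columns and multiplies each raw p value by the
#' number of tests (capped at 1). The default family size is the number of
#' pairs, e.g. 15 for the six song variables. Zero-variance columns yield
#' NA for their pairs.
#'
#' @param x data.frame or matrix of numeric variables (rows =
#'   recordings).
#' @param nTests Bonferroni family size; default `choose(ncol(x), 2)`.
#' @return List of three symmetric matrices: `rho`, `p_raw`, `p_adj`.
#' @export
correlationMatrix <- function(x, nTests = NULL) {
  x <- as.data.frame(x)
  k <- ncol(x)
  if (nrow(x) < 3L) stop("need at least 3 rows")
  if (is.null(nTests)) nTests <- choose(k, 2)
  rho <- p_raw <- matrix(NA_real_, k, k, dimnames = list(names(x), names(x)))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      xi <- x[[i]]; xj <- x[[j]]
      ok <- is.finite(xi) & is.finite(xj)
      if (sum(ok) < 3L || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0)
        next
      ct <- stats::cor.test(xi[ok], xj[ok], method = "pearson")
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p_raw[i, j] <- p_raw[j, i] <- ct$p.value
    }
  }
  diag(rho) <- 1
  p_adj <- p_raw
  p_adj[] <- pmin(1, p_raw * nTests)
  list(rho = rho, p_raw = p_raw, p_adj = p_adj)
}

#' Remove the confounding of repertoire size and sample size
#'
#' Network descriptors are not independent of how many syllable types and
#' tokens a recording contains. Each requested variable is regressed (OLS,
#' with intercept) on repertoire size and syllable number, and the
#' residuals - the size-independent part of the variable - are appended as
#' `<variable>_resid` columns. Variables named in `logTransform` are
#' log-transformed first (used for small-worldness, whose distribution is
#' strongly right-skewed); zeros are lifted by half the smallest positive
#' value before the log.
#'
#' @param metricsTable data.frame from [metricsTable()] (needs
#'   `repertoire_size` and `n_syllables`).
#' @param vars variables to residualize.
#' @param logTransform subset of `vars` to log-transform first.
#' @return `metricsTable` with `<var>_resid` columns appended (NA where
#'   the variable itself is NA).
#' @export
residualizeMetrics <- function(metricsTable,
                               vars = .METRIC_NAMES,
                               logTransform = character()) {
  stopifnot(all(c("repertoire_size", "n_syllables") %in% names(metricsTable)))
  if (nrow(metricsTable) < 4L) stop("need at least 4 recordings")
  for (v in vars) {
    y <- metricsTable[[v]]
    if (v %in% logTransform) {
      pos <- y[is.finite(y) & y > 0]
      eps <- if (length(pos)) min(pos) / 2 else 1e-6
      y <- log(pmax(y, 0) + eps)
    }
    fit <- stats::lm(y ~ repertoire_size + n_syllables, data = metricsTable,
                     na.action = stats::na.exclude)
    if (anyNA(stats::coef(fit)))
      warning("collinear covariates when residualizing ", v,
              "; redundant term dropped")
    metricsTable[[paste0(v, "_resid")]] <- as.numeric(stats::resid(fit))
  }
  metricsTable
}

#' Repeatability of a variable from repeated recordings
#'
#' Decomposes the variance of a variable measured twice per individual
#' into between-individual and within-individual components with a
#' random-intercept linear mixed model (REML), optionally adjusting for
#' age as a fixed covariate, and reports
#' `R = V_between / (V_between + V_within)`. The confidence interval is a
#' fully parametric bootstrap: responses are re-simulated from the fitted
#' Gaussian components (random effects and residuals both redrawn), the
#' model refitted, and the 2.5/97.5 percentiles of the refitted R taken
#' (`ciType = "basic"` gives the basic bootstrap interval instead,
#' truncated to [0, 1]). R is considered significantly above zero when
#' the lower CI bound exceeds ~0 (1e-6).
#'
#' A singular fit (between-individual variance estimated at 0) yields
#' R = 0, not an error. Bootstrap replicates that fail to refit are
#' dropped and counted in `n_failed`.
#'
#' @param values numeric response (one entry per recording).
#' @param individualIds individual identifier per entry; every individual
#'   must appear exactly twice (balanced two-recording design).
#' @param ages optional numeric age covariate per entry.
#' @param nBoot bootstrap iterations (default 1000).
#' @param seed optional integer seed.
#' @param ciType `"percentile"` (default) or `"basic"`.
#' @return One-row data.frame: `v_between`, `v_within`, `r`, `ci_low`,
#'   `ci_high`, `significant`, `n_individuals`, `n_boot`, `n_failed`.
#' @export
repeatability <- function(values, individualIds, ages = NULL, nBoot = 1000L,
                          seed = NULL, ciType = c("percentile", "basic")) {
  ciType <- match.arg(ciType)
  counts <- table(individualIds)
  if (length(counts) < 2L)
    stop("need at least 2 individuals")
  if (any(counts != 2L))
    stop("every individual must have exactly 2 records (balanced design)")
  df <- data.frame(y = values, id = factor(individualIds))
  form <- if (is.null(ages)) y ~ 1 + (1 | id) else y ~ age + (1 | id)
  if (!is.null(ages)) df$age <- ages
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE,
                                     control = lme4::lmerControl(calc.derivs = FALSE)))
  rFrom <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    vb <- vc$vcov[vc$grp == "id"]
    vw <- vc$vcov[vc$grp == "Residual"]
    if (vb + vw <= 0) return(c(NA_real_, NA_real_, NA_real_))
    c(vb, vw, vb / (vb + vw))
  }
  est <- rFrom(fit)
  if (!is.null(seed)) set.seed(seed)
  sims <- stats::simulate(fit, nsim = nBoot, use.u = FALSE)
  rBoot <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    rb <- tryCatch(
      suppressMessages(suppressWarnings(rFrom(lme4::refit(fit, sims[[b]]))))[3L],
      error = function(e) NA_real_)
    rBoot[b] <- rb
  }
  nFailed <- sum(is.na(rBoot))
  rBoot <- rBoot[!is.na(rBoot)]
  if (ciType == "percentile") {
    ci <- stats::quantile(rBoot, c(0.025, 0.975), names = FALSE)
  } else {
    q <- stats::quantile(rBoot, c(0.975, 0.025), names = FALSE)
    ci <- pmin(1, pmax(0, 2 * est[3L] - q))
  }
  data.frame(v_between = est[1L], v_within = est[2L], r = est[3L],
             ci_low = ci[1L], ci_high = ci[2L],
             significant = is.finite(ci[1L]) && ci[1L] > 1e-6,
             n_individuals = length(counts), n_boot = nBoot,
             n_failed = nFailed)
}

#' Repeatability of every network variable at one time scale
#'
#' Convenience wrapper running [repeatability()] over the (residualized)
#' network-variable columns of a paired metrics table.
#'
#' @param pairedMetrics data.frame with two rows per individual (needs an
#'   `individual_id` column and optionally `age`).
#' @param vars columns to analyse.
#' @param timeScale label stored in the output (e.g. `"within_day"`).
#' @inheritParams repeatability
#' @return data.frame, one row per variable.
#' @export
repeatabilityTable <- function(pairedMetrics, vars, timeScale = NA_character_,
                               nBoot = 1000L, seed = NULL) {
  rows <- lapply(vars, function(v) {
    res <- repeatability(pairedMetrics[[v]], pairedMetrics$individual_id,
                         ages = pairedMetrics$age, nBoot = nBoot, seed = seed)
    cbind(data.frame(variable = v, time_scale = timeScale), res)
  })
  do.call(rbind, rows)
}
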