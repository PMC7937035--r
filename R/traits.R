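# Quality and fitness models for (size-corrected) network variables.

.lrtTerm <- function(full, reduced) {
  chi2 <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
  chi2 <- max(0, chi2)
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(reduced), "df")
  c(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Quality model: network variable vs male traits
#'
#' Gaussian linear model of one (typically size-corrected) network
#' variable on body condition, age and standardized arrival date as
#' continuous fixed effects, with year as a discrete fixed effect to
#' absorb between-year differences. Each term is tested with a
#' likelihood-ratio test (model with vs without the term); Bonferroni
#' adjustment multiplies the raw p by the number of network variables
#' analysed (`bonferroniN`, default 2).
#'
#' @param data data.frame with the response and predictor columns
#'   (complete cases are used).
#' @param response name of the response column.
#' @param predictors continuous fixed-effect columns.
#' @param yearCol year column name (term dropped, with a warning, when a
#'   single year is present); set NULL to omit.
#' @param bonferroniN multiple-testing family size.
#' @return List with `terms` (term, estimate, statistic, chi2, df, p_raw,
#'   p_bonferroni), `r2`, `n`, `family`, and the fitted `model`.
#' @export
fitQualityModel <- function(data, response,
                            predictors = c("condition", "age", "arrival_std"),
                            yearCol = "year", bonferroniN = 2L) {
  cols <- c(response, predictors, yearCol)
  data <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  useYear <- !is.null(yearCol)
  if (useYear && length(unique(data[[yearCol]])) < 2L) {
    warning("only one year present; year term dropped")
    useYear <- FALSE
  }
  terms <- predictors
  rhs <- terms
  if (useYear) rhs <- c(rhs, sprintf("factor(%s)", yearCol))
  form <- stats::reformulate(rhs, response = response)
  full <- stats::lm(form, data = data)
  co <- summary(full)$coefficients
  rows <- lapply(terms, function(tm) {
    red <- stats::update(full, stats::as.formula(paste(". ~ . -", tm)))
    lrt <- .lrtTerm(full, red)
    data.frame(term = tm, estimate = co[tm, "Estimate"],
               statistic = co[tm, "t value"], chi2 = lrt["chi2"],
               df = lrt["df"], p_raw = lrt["p"],
               p_bonferroni = min(1, lrt["p"] * bonferroniN))
  })
  if (useYear) {
    red <- stats::update(full,
                         stats::as.formula(paste(". ~ . - factor(", yearCol, ")")))
    lrt <- .lrtTerm(full, red)
    rows <- c(rows, list(data.frame(term = yearCol, estimate = NA_real_,
                                    statistic = NA_real_, chi2 = lrt["chi2"],
                                    df = lrt["df"], p_raw = lrt["p"],
                                    p_bonferroni = min(1, lrt["p"] * bonferroniN))))
  }
  terms <- do.call(rbind, rows)
  rownames(terms) <- NULL
  list(response = response, terms = terms, r2 = summary(full)$r.squared,
       n = nrow(data), family = "gaussian", model = full)
}

#' Fitness model: binary fitness proxy vs network variables and traits
#'
#' Binomial GLM (logit link) of a binary fitness component (pairing
#' success or survival to the next year) on the network variables (entered
#' together) plus age, standardized arrival date and body condition, with
#' year as a discrete fixed effect. Terms are tested by likelihood-ratio
#' (deviance difference); the pseudo-R^2 reported is McFadden's
#' `1 - deviance / null deviance`. Complete separation is flagged and the
#' per-term statistics set to NA (no penalized refit is attempted).
#'
#' @param data data.frame with all columns (complete cases used).
#' @param response binary 0/1 response column name.
#' @param networkVars network-variable column names (both entered).
#' @param covariates continuous covariate columns.
#' @param yearCol year column name (NULL to omit; dropped if single year).
#' @param bonferroniN multiple-testing family size.
#' @return List as in [fitQualityModel()] with `pseudo_r2` and a
#'   `separation` flag.
#' @export
fitFitnessModel <- function(data, response, networkVars,
                            covariates = c("age", "arrival_std", "condition"),
                            yearCol = "year", bonferroniN = 2L) {
  cols <- c(response, networkVars, covariates, yearCol)
  data <- data[stats::complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  yv <- data[[response]]
  if (!all(yv %in% c(0, 1))) stop(response, " must be binary 0/1")
  if (length(unique(yv)) < 2L)
    stop("degenerate response: ", response, " is constant")
  useYear <- !is.null(yearCol)
  if (useYear && length(unique(data[[yearCol]])) < 2L) {
    warning("only one year present; year term dropped")
    useYear <- FALSE
  }
  terms <- c(networkVars, covariates)
  rhs <- terms
  if (useYear) rhs <- c(rhs, sprintf("factor(%s)", yearCol))
  form <- stats::reformulate(rhs, response = response)
  separated <- FALSE
  full <- withCallingHandlers(
    stats::glm(form, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  pseudoR2 <- 1 - full$deviance / full$null.deviance
  co <- summary(full)$coefficients
  mkRow <- function(tm, isYear = FALSE) {
    if (separated) {
      return(data.frame(term = tm, estimate = NA_real_, statistic = NA_real_,
                        chi2 = NA_real_, df = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_))
    }
    drop <- if (isYear) paste("factor(", yearCol, ")") else tm
    red <- suppressWarnings(
      stats::update(full, stats::as.formula(paste(". ~ . -", drop))))
    chi2 <- max(0, red$deviance - full$deviance)
    df <- red$df.residual - full$df.residual
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    data.frame(term = tm,
               estimate = if (isYear) NA_real_ else co[tm, "Estimate"],
               statistic = if (isYear) NA_real_ else co[tm, "z value"],
               chi2 = chi2, df = df, p_raw = p,
               p_bonferroni = min(1, p * bonferroniN))
  }
  rows <- lapply(terms, mkRow)
  if (useYear) rows <- c(rows, list(mkRow(yearCol, isYear = TRUE)))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(response = response, terms = tab, pseudo_r2 = pseudoR2,
       n = nrow(data), family = "binomial", separation = separated,
       model = full)
}

#' Paired within-individual change test
#'
#' Paired t test on the within-individual change of a variable between two
#' recordings (e.g. two years): differences are `second - first`, so a
#' negative t means the variable decreased. A one-sided alternative is
#' available via `tail`. Constant nonzero differences have zero SD and the
#' statistic is reported as NA; identical pairs give t = 0, p = 1.
#'
#' @param first,second paired numeric vectors (matched by individual).
#' @param tail `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the mean difference `second - first`.
#' @return One-row data.frame: `t`, `df`, `p`, `tail`, `mean_diff`.
#' @examples
#' pairedWithinIndividualTest(c(3, 4, 5), c(2.5, 3.8, 4.2))
#' @export
pairedWithinIndividualTest <- function(first, second,
                                       tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  stopifnot(length(first) == length(second))
  d <- second - first
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(data.frame(t = 0, df = n - 1L, p = 1, tail = tail, mean_diff = 0))
    }
    return(data.frame(t = NA_real_, df = n - 1L, p = NA_real_, tail = tail,
                      mean_diff = m))
  }
  t <- m / (s / sqrt(n))
  df <- n - 1L
  p <- switch(tail,
              two.sided = 2 * stats::pt(-abs(t), df),
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE))
  data.frame(t = t, df = df, p = p, tail = tail, mean_diff = m)
}
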