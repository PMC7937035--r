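simTraits <- function(n, seed) {
  set.seed(seed)
  data.frame(age = pmin(1 + rgeom(n, 1 / 1.9), 7),
             arrival_std = rnorm(n, 0, 6),
             condition = rnorm(n),
             year = sample(2000:2005, n, TRUE))
}

test_that("a perfectly linear response gives R squared one", {
  tr <- simTraits(80, 1)
  tr$resp <- 1 + 0.5 * tr$age - 0.2 * tr$arrival_std + tr$condition
  fit <- suppressWarnings(fitQualityModel(tr, "resp"))
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$n, 80)
  expect_equal(fit$family, "gaussian")
})

test_that("LRT chi-square is non-negative and year df is levels minus one", {
  tr <- simTraits(100, 2)
  tr$resp <- rnorm(100)
  fit <- fitQualityModel(tr, "resp")
  expect_true(all(fit$terms$chi2 >= 0))
  yearRow <- fit$terms[fit$terms$term == "year", ]
  expect_equal(yearRow$df, length(unique(tr$year)) - 1)
  expect_true(all(fit$terms$df[fit$terms$term != "year"] == 1))
  expect_true(all(fit$terms$p_bonferroni >= fit$terms$p_raw))
})

test_that("a single year drops the year term with a warning", {
  tr <- simTraits(40, 3)
  tr$year <- 2000L
  tr$resp <- rnorm(40)
  expect_warning(fit <- fitQualityModel(tr, "resp"), "year term dropped")
  expect_false("year" %in% fit$terms$term)
})

test_that("a strong negative age effect is detected and signed correctly", {
  hits <- 0L
  for (s in 1:10) {
    tr <- simTraits(176, 100 + s)
    tr$resp <- -0.3 * tr$age + rnorm(176)
    fit <- fitQualityModel(tr, "resp")
    row <- fit$terms[fit$terms$term == "age", ]
    if (row$estimate < 0 && row$p_raw < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("gaussian LRT p agrees with the F test at moderate n", {
  tr <- simTraits(150, 5)
  tr$resp <- 0.1 * tr$age + rnorm(150)
  fit <- fitQualityModel(tr, "resp", yearCol = NULL)
  f <- anova(lm(resp ~ condition + age + arrival_std, data = tr))
  fp <- drop1(lm(resp ~ condition + age + arrival_std, data = tr),
              test = "F")["age", "Pr(>F)"]
  lp <- fit$terms$p_raw[fit$terms$term == "age"]
  expect_equal(lp, fp, tolerance = 0.25 * fp)
})

test_that("binomial fitness model reports LRT terms and pseudo R squared", {
  tr <- simTraits(176, 6)
  tr$deg <- rnorm(176)
  tr$sw <- rnorm(176)
  tr$paired <- rbinom(176, 1, plogis(1 - 0.5 * tr$arrival_std / 6))
  fit <- fitFitnessModel(tr, "paired", networkVars = c("deg", "sw"))
  expect_equal(fit$family, "binomial")
  expect_false(fit$separation)
  expect_true(all(na.omit(fit$terms$chi2) >= 0))
  expect_gt(fit$pseudo_r2, 0)
  expect_lt(fit$pseudo_r2, 1)
  arr <- fit$terms[fit$terms$term == "arrival_std", ]
  expect_lt(arr$estimate, 0)
})

test_that("a negative arrival effect on pairing is usually recovered", {
  hits <- 0L
  for (s in 1:10) {
    tr <- simTraits(176, 200 + s)
    tr$deg <- rnorm(176)
    tr$sw <- rnorm(176)
    tr$paired <- rbinom(176, 1, plogis(0.5 - 0.5 * tr$arrival_std / 6))
    fit <- fitFitnessModel(tr, "paired", networkVars = c("deg", "sw"),
                           yearCol = NULL)
    row <- fit$terms[fit$terms$term == "arrival_std", ]
    if (row$estimate < 0 && row$p_raw < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("degenerate and separated responses are handled", {
  tr <- simTraits(40, 7)
  tr$deg <- rnorm(40)
  tr$sw <- rnorm(40)
  tr$dead <- 0
  expect_error(fitFitnessModel(tr, "dead", networkVars = c("deg", "sw")),
               "degenerate")

  tr$sep <- as.integer(tr$deg > 0)
  fit <- suppressWarnings(
    fitFitnessModel(tr, "sep", networkVars = c("deg", "sw"), yearCol = NULL))
  expect_true(fit$separation)
  expect_true(all(is.na(fit$terms$p_raw)))
})

test_that("paired within-individual test matches the t reference", {
  same <- pairedWithinIndividualTest(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- pairedWithinIndividualTest(c(3, 4, 5), c(2, 3, 4))
  expect_true(is.na(const$t))

  set.seed(8)
  x <- rnorm(13); y <- x - 0.5 + rnorm(13, sd = 0.8)
  ours <- pairedWithinIndividualTest(x, y)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)

  # the t = -2, df = 12 reference point: one-sided 0.034, two-sided 0.069
  expect_equal(pt(-2, 12), 0.0343, tolerance = 1e-3)
  expect_equal(2 * pt(-2, 12), 0.0686, tolerance = 1e-3)
})
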