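# published 90-patient cohort 2x2 tables (low/high expression columns)
tab3 <- list(
  age = rbind(c(25, 15), c(32, 18)),
  sex = rbind(c(4, 6), c(53, 27)),
  tnm = rbind(c(44, 19), c(13, 14)),
  size = rbind(c(23, 13), c(34, 20)),
  afp = rbind(c(36, 12), c(21, 21)))
tab3p <- c(age = 0.883, sex = 0.104, tnm = 0.050, size = 0.929,
           afp = 0.014)

test_that("uncorrected chi-square reproduces the published cohort table", {
  for (nm in names(tab3))
    expect_equal(round(chisq2x2(tab3[[nm]])$p, 3), unname(tab3p[nm]))

  # identical row proportions: statistic 0, p 1
  res <- chisq2x2(rbind(c(10, 20), c(5, 10)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_error(chisq2x2(rbind(c(0, 0), c(3, 4))), "zero marginal")

  # the Yates-corrected variant is available but differs
  expect_false(round(chisq2x2(tab3$afp, correct = TRUE)$p, 3) ==
               round(chisq2x2(tab3$afp)$p, 3))
})

test_that("IHC percent binning follows the four-group rule", {
  res <- binIHCScore(c(10, 24.9, 25, 49, 50, 74.9, 75, 100))
  expect_equal(res$score, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(res$class, c("low", "low", "low", "low",
                            "high", "high", "high", "high"))
  # boundary convention is configurable
  expect_equal(binIHCScore(25, boundaryUp = FALSE)$score, 1L)
  expect_error(binIHCScore(140), "\\[0, 100\\]")
})

test_that("Kaplan-Meier estimate matches the product-limit oracle", {
  # all censored: flat at 1
  allc <- data.frame(time = 1:5, event = 0L)
  expect_true(all(kmEstimate(allc)$surv == 1))

  # two events, no censoring
  two <- data.frame(time = c(1, 2), event = 1L)
  km <- kmEstimate(two)
  expect_equal(km$surv, c(0.5, 0))

  # 20-record fixture against a brute-force product over event times
  set.seed(44)
  rec <- data.frame(time = round(rexp(20, 0.1), 2) + 0.1,
                    event = rbinom(20, 1, 0.7))
  km2 <- kmEstimate(rec)
  times <- sort(unique(rec$time))
  s <- 1
  oracle <- vapply(times, function(tt) {
    d <- sum(rec$time == tt & rec$event == 1)
    n <- sum(rec$time >= tt)
    s <<- s * (1 - d / n)
    s
  }, numeric(1))
  expect_equal(km2$surv, oracle[match(km2$time, times)],
               tolerance = 1e-12)
})

test_that("log-rank test: identity, oracle, and power", {
  rec <- data.frame(time = c(3, 5, 7, 9), event = c(1, 1, 0, 1))
  dup <- rbind(rec, rec)
  res <- logrankTest(dup, rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # 12-record fixture vs the hand-summed O-E / V statistic
  rec12 <- data.frame(
    time = c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10),
    event = c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 0, 1),
    g = rep(c("a", "b"), 6))
  o <- 0; e <- 0; v <- 0
  for (tt in sort(unique(rec12$time[rec12$event == 1]))) {
    at <- rec12$time >= tt
    n <- sum(at); n1 <- sum(at & rec12$g == "a")
    d <- sum(rec12$time == tt & rec12$event == 1)
    d1 <- sum(rec12$time == tt & rec12$event == 1 & rec12$g == "a")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- (o - e)^2 / v
  res12 <- logrankTest(rec12[c("time", "event")], rec12$g)
  expect_equal(res12$statistic, oracle, tolerance = 1e-8)

  # power at HR = 3, 200 per arm
  reject <- vapply(1:50, function(s) {
    d <- simulateSurvival(rep(c(0, 1), each = 200),
                          list(baselineHazard = 0.05,
                               betaSurv = log(3),
                               censoringRate = 0.2), seed = 500 + s)
    logrankTest(d, d$x)$p < 0.01
  }, logical(1))
  expect_gte(sum(reject), 48L)

  expect_error(logrankTest(rec, rep("a", 4)), "2 groups")
})

test_that("Cox fit: partial-likelihood oracle on six records", {
  rec <- data.frame(time = c(2, 4, 6, 8, 10, 12),
                    event = c(1, 1, 1, 1, 1, 0),
                    x = c(1, 0, 1, 0, 1, 0))
  fit <- coxFit(rec, "x", mode = "univariate")
  # brute-force Breslow partial log-likelihood, maximized numerically
  pll <- function(b) {
    ll <- 0
    for (i in which(rec$event == 1)) {
      rs <- rec$time >= rec$time[i]
      ll <- ll + b * rec$x[i] - log(sum(exp(b * rec$x[rs])))
    }
    ll
  }
  bhat <- optimize(pll, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(fit$beta, bhat, tolerance = 1e-4)
  expect_equal(fit$loglik, pll(bhat), tolerance = 1e-6)
  expect_true(fit$ci_low < fit$HR && fit$HR < fit$ci_high)
  expect_error(coxFit(rec, "nope", mode = "univariate"), "no such")
  expect_error(coxFit(transform(rec, x = 1), "x"), "constant")
})

test_that("Cox fit: null coverage and parameter recovery", {
  # null: the 95% CI contains HR = 1 at roughly nominal coverage
  cover <- vapply(1:100, function(s) {
    d <- simulateSurvival(rep(c(0, 1), each = 250),
                          list(baselineHazard = 0.05, betaSurv = 0,
                               censoringRate = 0.2), seed = 900 + s)
    f <- coxFit(d, "x", mode = "univariate")
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.89)
  expect_lte(mean(cover), 0.99)

  # planted ln HR = ln 2 recovered within 2 SE
  d <- simulateSurvival(rep(c(0, 1), each = 250),
                        list(baselineHazard = 0.05, betaSurv = log(2),
                             censoringRate = 0.25), seed = 31)
  f <- coxFit(d, "x", mode = "univariate")
  se <- (log(f$ci_high) - log(f$ci_low)) / (2 * 1.96)
  expect_lt(abs(f$beta - log(2)), 2 * se)

  # multivariate mode returns one row per covariate of a joint model
  d$z <- rnorm(nrow(d))
  fm <- coxFit(d, c("x", "z"), mode = "multivariate")
  expect_equal(nrow(fm), 2L)
  expect_equal(unique(fm$model), "multivariate")
})

test_that("expression dichotomization rules", {
  expect_equal(dichotomizeExpression(c(1, 2, 3, 4)),
               c("low", "low", "high", "high"))
  # ties at the median go low
  expect_equal(dichotomizeExpression(c(1, 2, 2, 4)),
               c("low", "low", "low", "high"))
  # monotone-transform invariance of the median rule
  set.seed(3)
  v <- rnorm(31)
  expect_identical(dichotomizeExpression(v),
                   dichotomizeExpression(exp(v)))
  # IHC rule delegates to the score binning
  expect_equal(dichotomizeExpression(c(10, 80), rule = "ihc_score"),
               c("low", "high"))
  expect_error(dichotomizeExpression(rep(2, 5)), "constant")
})

test_that("association table assembles published-style layout", {
  clin <- data.frame(
    afp = rep(c("<=300", ">300"), times = c(48, 42)),
    tnm = rep(c("I", "II-IV", "I", "II-IV"),
              times = c(44, 13, 19, 14)))
  classes <- rep(c("low", "high"), times = c(57, 33))
  # arrange rows so the low/high split matches the published counts
  clin$afp <- c(rep("<=300", 36), rep(">300", 21),
                rep("<=300", 12), rep(">300", 21))
  clin$tnm <- c(rep("I", 44), rep("II-IV", 13),
                rep("I", 19), rep("II-IV", 14))
  tabl <- clinicalAssociationTable(clin, classes,
                                   covariates = c("tnm", "afp"))
  expect_equal(round(tabl$p[tabl$covariate == "afp" &
                            !is.na(tabl$p)], 3), 0.014)
  expect_equal(round(tabl$p[tabl$covariate == "tnm" &
                            !is.na(tabl$p)], 3), 0.050)
  expect_equal(tabl$n_low[tabl$covariate == "afp"], c(36, 21))
})
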