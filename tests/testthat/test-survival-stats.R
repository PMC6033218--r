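test_that("Kaplan-Meier estimate matches the hand product-limit values", {
  km <- kmEstimate(recs(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0)))
  expect_equal(kmSurvivalAt(km, c(1, 3, 4)),
               c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  # all censored -> S(t) = 1 everywhere
  flat <- kmEstimate(recs(1:4, rep(0, 4)))
  expect_true(all(kmSurvivalAt(flat, c(0.5, 2, 10)) == 1))
  # duplicating every record leaves the curve unchanged
  dup <- kmEstimate(recs(rep(c(1, 2, 3, 4, 5), 2), rep(c(1, 0, 1, 1, 0), 2)))
  expect_equal(kmSurvivalAt(dup, c(1, 3, 4)), kmSurvivalAt(km, c(1, 3, 4)))
  # properties: starts at 1, non-increasing, drops only at event times
  expect_true(all(diff(km$curve$surv) <= 0))
  expect_equal(kmSurvivalAt(km, 0.99), 1)
  expect_error(kmEstimate(recs(numeric(0), integer(0))), "empty")
})

test_that("log-rank test matches hand risk-set enumeration", {
  r <- recs(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 0, 1))
  g <- rep(c("A", "B"), each = 3)
  lr <- logrankTest(r, g)
  # hand enumeration: O_A = 2, E_A = 1.4, V = 0.74 -> 0.6^2/0.74
  expect_equal(lr$statistic, 0.36 / 0.74, tolerance = 1e-3)
  expect_equal(lr$df, 1L)
  # identical time/event multisets in both groups -> statistic 0
  r2 <- recs(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  expect_lt(logrankTest(r2, rep(c("A", "B"), each = 3))$statistic, 1e-12)
  expect_error(logrankTest(r, factor(rep("A", 6), levels = c("A", "B"))),
               "2 non-empty groups")
})

test_that("log-rank statistic is invariant to monotone time transforms", {
  set.seed(41)
  r <- recs(rexp(40) + 0.1, rbinom(40, 1, 0.7))
  g <- rep(c("A", "B"), 20)
  s1 <- logrankTest(r, g)$statistic
  r2 <- recs(log(r$time + 1), r$event)
  expect_equal(logrankTest(r2, g)$statistic, s1, tolerance = 1e-12)
})

test_that("Cox coefficient matches a grid search of the partial likelihood", {
  r <- recs(c(1, 4, 2, 3, 5), c(1, 1, 1, 0, 1))
  x <- c(1, 1, 0, 0, 0)
  fit <- fitCox(r, data.frame(x = x))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, efron_loglik, numeric(1),
               time = r$time, event = r$event, x = x)
  expect_equal(fit@table$coef, grid[which.max(ll)], tolerance = 1e-3)
  # reporting contract: HR = exp(coef), CI brackets HR
  expect_equal(fit@table$hr, exp(fit@table$coef))
  expect_true(fit@table$lower <= fit@table$hr &
                fit@table$hr <= fit@table$upper)
})

test_that("duplicating a dataset preserves the Cox estimate, shrinks SE", {
  set.seed(13)
  n <- 80
  x <- rnorm(n)
  tt <- rexp(n, exp(0.8 * x))
  r <- recs(tt, rep(1, n))
  # Breslow ties: duplication rescales the partial likelihood exactly,
  # so the maximizer is unchanged (Efron's tie correction would not be)
  f1 <- fitCox(r, data.frame(x = x), ties = "breslow")
  r2 <- recs(rep(tt, 2), rep(1, 2 * n))
  f2 <- fitCox(r2, data.frame(x = rep(x, 2)), ties = "breslow")
  expect_equal(f2@table$coef, f1@table$coef, tolerance = 1e-6)
  expect_equal(f2@table$se / f1@table$se, 1 / sqrt(2), tolerance = 0.02)
})

test_that("degenerate Cox inputs are flagged, not estimated", {
  r <- recs(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_error(fitCox(r, data.frame(x = rep(0, 4))), "constant")
  # stratified fit requires events in every stratum
  expect_error(fitCox(r, data.frame(x = c(1, 0, 1, 0)),
                      strataBy = factor(c("a", "a", "b", "a"),
                                        levels = c("a", "b"))),
               "zero events")
})

test_that("stratified and unstratified Cox share the estimator code path", {
  set.seed(29)
  n <- 120
  x <- rnorm(n)
  strat <- rep(c("u", "v"), each = n / 2)
  tt <- rexp(n, 0.5 * exp(x + 0.7 * (strat == "v")))
  r <- recs(pmin(tt, 4), as.integer(tt <= 4))
  plain <- fitCox(r, data.frame(x = x))
  strata_fit <- fitCox(r, data.frame(x = x), strataBy = strat)
  expect_identical(strata_fit@strata, ".strata")
  # both recover a positive effect; stratified one is not confounded
  expect_gt(plain@table$coef, 0)
  expect_gt(strata_fit@table$coef, 0)
})

test_that("Harrell's c-index equals the all-pairs double loop", {
  # perfectly anti-ordered risk (higher risk -> earlier event), no censoring
  r <- recs(c(5, 4, 3, 2, 1), rep(1, 5))
  expect_equal(harrellC(r, risk = 1:5), 1.0)
  # all scores tied -> 0.5
  expect_equal(harrellC(r, risk = rep(2, 5)), 0.5)

  set.seed(53)
  n <- 30
  tt <- rexp(n); ev <- rbinom(n, 1, 0.6); sc <- rnorm(n)
  r2 <- recs(tt, ev)
  brute <- local({
    conc <- 0; comp <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      # the pair is comparable iff the earlier time is an event
      first <- if (tt[i] < tt[j]) i else j
      second <- if (tt[i] < tt[j]) j else i
      if (tt[i] == tt[j]) next
      if (ev[first] == 0) next
      comp <- comp + 1
      if (sc[first] > sc[second]) conc <- conc + 1
      else if (sc[first] == sc[second]) conc <- conc + 0.5
    }
    conc / comp
  })
  expect_equal(harrellC(r2, sc), brute, tolerance = 1e-12)
})

test_that("analysis of deviance compares nested Cox models", {
  set.seed(61)
  n <- 100
  x <- rnorm(n); z <- rnorm(n)
  tt <- rexp(n, exp(0.9 * x))
  r <- recs(pmin(tt, 3), as.integer(tt <= 3))
  f1 <- fitCox(r, data.frame(x = x))
  f2 <- fitCox(r, data.frame(x = x, z = z))
  out <- likelihoodRatioTest(f1, f2)
  expect_equal(out$df, 1L)
  expect_gte(out$chisq, 0)
  expect_equal(out$chisq, 2 * (f2@loglik[2] - f1@loglik[2]))
  # identical models -> chi2 0, p 1
  same <- likelihoodRatioTest(f1, fitCox(r, data.frame(x = x)))
  expect_equal(same$chisq, 0, tolerance = 1e-10)
  expect_equal(same$p, 1)
  # non-nested models are rejected
  f3 <- fitCox(r, data.frame(z = z))
  expect_error(likelihoodRatioTest(f3, f1), "not nested")
})

test_that("cut-off discovery recovers a planted score gap", {
  set.seed(2)
  n <- 100
  sc <- c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1))
  haz <- ifelse(sc < 0.5, 2.0, 0.4)
  r <- recs(rexp(n, haz), rep(1, n))
  cut <- findCutoff(sc, r, B = 200, seed = 9)
  expect_gt(cutoffValue(cut), 0.4)
  expect_lt(cutoffValue(cut), 0.6)
  expect_lt(cut@pAdjusted, 0.05)
  # threshold lies inside the candidate quantile range
  q <- quantile(sc, cut@quantileRange)
  expect_gte(cutoffValue(cut), q[1]); expect_lte(cutoffValue(cut), q[2])
})

test_that("the selected cutpoint attains the maximal statistic (exhaustive scan)", {
  set.seed(73)
  n <- 60
  sc <- rnorm(n)
  tt <- rexp(n, exp(-sc))
  r <- recs(pmin(tt, 3), as.integer(tt <= 3))
  cut <- findCutoff(sc, r, B = 50, seed = 2, minGroupSize = 8)

  # independent scan: standardized linear log-rank statistic per candidate
  km_fit <- survival::survfit(survival::Surv(r$time, r$event) ~ 1)
  H <- stats::stepfun(km_fit$time, c(0, cumsum(km_fit$n.event / km_fit$n.risk)))
  a <- r$event - H(r$time)
  abar <- mean(a); s2 <- sum((a - abar)^2)
  splits <- sort(unique(sc))
  stats_at <- vapply(splits[-length(splits)], function(cp) {
    m <- sum(sc <= cp)
    if (m < 8 || n - m < 8) return(NA_real_)
    if (cp < quantile(sc, 0.10) || cp > quantile(sc, 0.90)) return(NA_real_)
    S <- sum(a[sc <= cp])
    abs(S - m * abar) / sqrt(m * (n - m) / (n * (n - 1)) * s2)
  }, numeric(1))
  best_stat <- max(stats_at, na.rm = TRUE)
  expect_equal(cut@statistic, best_stat, tolerance = 1e-9)
  # group sizes respect the minimum on the returned threshold
  expect_gte(min(sum(sc <= cutoffValue(cut)), sum(sc > cutoffValue(cut))), 8)
})

test_that("cut-off discovery rejects inadmissible inputs", {
  r <- recs(1:10, rep(1, 10))
  expect_error(findCutoff(rep(1, 10), r, minGroupSize = 2), "constant")
  expect_error(findCutoff(rnorm(10), r, minGroupSize = 10), "minGroupSize")
})

test_that("clinical covariates are recoded per the grade/metastasis rules", {
  cl <- data.frame(
    sample_id = sprintf("p%d", 1:10),
    T = c("1", "2", "3", "4", "1", "3", "2", "1", "3", "1"),
    N = c("0", "1", "2", "0", "X", "0", "0", "0", "1", "0"),
    M = c("0", "0", "1", "0", "0", "X", "0", "0", "1", "0"),
    G = c("1", "2", "3", "4", "2-3", "2", "X", NA, "2–3", "1"))
  out <- recodeCovariates(cl)
  # MX and missing/X grade records are excluded with reasons
  expect_setequal(out$excluded$sample_id, c("p6", "p7", "p8"))
  expect_identical(out$excluded$reason[out$excluded$sample_id == "p6"], "MX")
  expect_true(all(out$excluded$reason[out$excluded$sample_id %in%
                                        c("p7", "p8")] == "missing_grade"))
  d <- out$data
  # G2-3 and G4 merge into G3 (ASCII and en-dash spellings alike)
  expect_equal(d$G3[d$sample_id == "p5"], 1L)
  expect_equal(d$G3[d$sample_id == "p9"], 1L)
  expect_equal(d$G3[d$sample_id == "p4"], 1L)
  # reference row T1/N0/M0/G1: all indicators 0
  ref_row <- d[d$sample_id == "p1", -1]
  expect_true(all(ref_row == 0))
  expect_equal(d$M1[d$sample_id == "p3"], 1L)
  expect_equal(d$T3[d$sample_id == "p3"], 1L)
})
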