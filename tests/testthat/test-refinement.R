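test_that("assays that failed at least once are excluded, exactly those", {
  set.seed(3)
  v <- matrix(runif(300, 18, 30), 30, 10,
              dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  clean <- ExpressionMatrix(v, "qpcr_ct")
  expect_identical(filterFailedAssays(clean)$retained, geneIds(clean))

  # one missing Ct in one sample drops the gene
  v1 <- v; v1["g7", "s2"] <- NA
  fa1 <- filterFailedAssays(ExpressionMatrix(v1, "qpcr_ct"))
  expect_false("g7" %in% fa1$retained)
  expect_equal(fa1$report$failures[fa1$report$gene == "g7"], 1L)

  # planted failures in known genes: exactly those dropped
  planted <- c("g2", "g11", "g25")
  v2 <- v
  for (g in planted) v2[g, sample(10, sample(3, 1))] <- NA
  fa2 <- filterFailedAssays(ExpressionMatrix(v2, "qpcr_ct"))
  expect_setequal(setdiff(geneIds(clean), fa2$retained), planted)

  # invariant to gene and sample order
  perm <- ExpressionMatrix(v2[sample(30), sample(10)], "qpcr_ct")
  expect_setequal(filterFailedAssays(perm)$retained, fa2$retained)
})

test_that("comparability filter drops planted mean-shift and variance genes", {
  set.seed(8)
  g <- sprintf("g%d", 1:20)
  a <- matrix(rnorm(20 * 30, 8, 1), 20, 30, dimnames = list(g, sprintf("a%d", 1:30)))
  b <- a + matrix(rnorm(20 * 30, 0, 0.05), 20, 30)
  colnames(b) <- sprintf("b%d", 1:30)
  ok <- comparabilityFilter(em(a, genes = g), em(b, "qpcr_norm", genes = g))
  expect_setequal(ok$retained, g)

  # +10 pooled-SD mean shift on one platform
  b_shift <- b; b_shift["g5", ] <- b_shift["g5", ] + 10 * sd(a["g5", ])
  cf <- comparabilityFilter(em(a, genes = g),
                            em(b_shift, "qpcr_norm", genes = g))
  expect_false("g5" %in% cf$retained)
  expect_match(cf$report$reason[cf$report$gene == "g5"], "mean_shift")

  # SD inflated 5x (ratio 5 > 2); hand-check the reported ratio
  b_var <- b
  b_var["g9", ] <- mean(b["g9", ]) + 5 * (b["g9", ] - mean(b["g9", ]))
  cf2 <- comparabilityFilter(em(a, genes = g),
                             em(b_var, "qpcr_norm", genes = g))
  expect_false("g9" %in% cf2$retained)
  r9 <- cf2$report[cf2$report$gene == "g9", ]
  expect_match(r9$reason, "sd_ratio")
  expect_gt(r9$sd_qpcr / r9$sd_dev, 2)
  expect_error(comparabilityFilter(em(a[, 1:2], genes = g),
                                   em(b, "qpcr_norm", genes = g)),
               "3 samples")
})

test_that("stepwise selection recovers an exactly planted linear model", {
  set.seed(42)
  X <- matrix(rnorm(10 * 200), 10, 200,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:200)))
  y <- 2 * X["g1", ] + 1
  model <- selectLinearModel(X, y)
  expect_identical(names(coef(model)), "g1")
  expect_equal(unname(coef(model)[["g1"]]), 2, tolerance = 1e-6)
  expect_equal(model@intercept, 1, tolerance = 1e-6)
  expect_gt(model@r2, 1 - 1e-10)
})

test_that("stepwise AIC is no better than exhaustive best-subset at its size", {
  set.seed(19)
  p <- 8; n <- 60
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%d", 1:p), sprintf("s%d", 1:n)))
  y <- 1.2 * X["g2", ] - 0.7 * X["g5", ] + rnorm(n, 0, 0.5)
  model <- selectLinearModel(X, y)
  sel <- names(coef(model))
  df <- data.frame(y = y, t(X))
  aic_of <- function(vars) AIC(lm(stats::reformulate(vars, "y"), df))
  step_aic <- aic_of(sel)
  best <- min(apply(utils::combn(rownames(X), length(sel)), 2, aic_of))
  expect_gte(step_aic, best - 1e-8)
  # and exhaustive search over ALL sizes never beats it by much: the greedy
  # result must at least contain the dominant planted gene
  expect_true("g2" %in% sel)
})

test_that("selection is reproducible and reports collinear candidates", {
  set.seed(7)
  X <- matrix(rnorm(6 * 80), 6, 80,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:80)))
  X["g6", ] <- 2 * X["g1", ] - X["g2", ]   # exactly collinear candidate
  y <- X["g1", ] - X["g2", ] + rnorm(80, 0, 0.3)
  m1 <- selectLinearModel(X, y)
  m2 <- selectLinearModel(X, y)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1@intercept, m2@intercept)
  sel <- names(coef(m1))
  if (all(c("g1", "g2") %in% sel)) expect_true("g6" %in% attr(m1, "collinear"))
})

test_that("the lasso route caps the support and refits unpenalized", {
  set.seed(23)
  X <- matrix(rnorm(20 * 150), 20, 150,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:150)))
  y <- 1.5 * X["g1", ] - X["g2", ] + 0.8 * X["g3", ] + rnorm(150, 0.1)
  model <- selectLinearModel(X, y, method = "lasso", maxTerms = 3)
  expect_lte(length(coef(model)), 3)
  expect_setequal(names(coef(model)), c("g1", "g2", "g3"))
  # unpenalized refit: coefficients match lm on the support
  df <- data.frame(y = y, t(X[names(coef(model)), , drop = FALSE]))
  ref <- lm(y ~ ., df)
  expect_equal(unname(coef(model)), unname(coef(ref)[-1]), tolerance = 1e-8)
})

test_that("linear models apply by intercept + weighted expression", {
  model <- LinearScoreModel(intercept = 1, coefficients = c(g1 = 2))
  m0 <- em(matrix(0, 2, 3), genes = c("g1", "g2"))
  expect_equal(unname(applyLinearModel(model, m0)), rep(1, 3))
  m3 <- em(matrix(c(3, 9), 2, 1), genes = c("g1", "g2"))
  expect_equal(unname(applyLinearModel(model, m3)), 7)
  expect_error(applyLinearModel(model, em(matrix(1, 1, 1), genes = "g9")),
               "absent.*g1")
  mna <- em(matrix(NA_real_, 1, 1), genes = "g1")
  expect_error(applyLinearModel(model, mna), "missing values")
})

test_that("applying a model to its training matrix reproduces fitted values", {
  set.seed(12)
  X <- matrix(rnorm(5 * 100), 5, 100,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:100)))
  y <- 0.5 * X["g1", ] + 2 * X["g4", ] + rnorm(100, 0, 0.2)
  model <- selectLinearModel(X, y)
  df <- data.frame(y = y, t(X[names(coef(model)), , drop = FALSE]))
  fitted_lm <- unname(stats::fitted(lm(y ~ ., df)))
  expect_equal(unname(applyLinearModel(model, em(X, genes = rownames(X)))),
               fitted_lm, tolerance = 1e-9)
})

test_that("score concordance is a rank correlation with sample matching", {
  a <- setNames(c(1, 2, 3, 4, 5, 6), letters[1:6])
  expect_equal(scoreConcordance(a, a)$rho, 1)
  expect_equal(scoreConcordance(a, -a)$rho, -1)
  b <- setNames(c(2, 1, 4, 3, 6, 5), letters[1:6])
  expect_equal(scoreConcordance(a, b)$rho, 1 - 6 * 6 / (6 * 35),
               tolerance = 1e-12)
  # matched by name even when order differs
  expect_equal(scoreConcordance(a, rev(b))$rho, scoreConcordance(a, b)$rho)
  expect_error(scoreConcordance(a, setNames(1:6, LETTERS[1:6])),
               "mismatched")
  expect_error(scoreConcordance(1:2, 1:2), "n >= 3")
})

test_that("linear score models serialize to JSON and back exactly", {
  model <- LinearScoreModel(intercept = 0.123456789012345,
                            coefficients = c(gA = -0.987654321098765,
                                             gB = 2.5e-7),
                            method = "stepwise_aic", r2 = 0.91,
                            normalizationGenes = c("h1", "h2"))
  path <- withr::local_tempfile(fileext = ".json")
  writeLinearScoreModel(model, path)
  back <- readLinearScoreModel(path)
  expect_identical(coef(back), coef(model))
  expect_identical(back@intercept, model@intercept)
  expect_identical(back@normalizationGenes, model@normalizationGenes)
})
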