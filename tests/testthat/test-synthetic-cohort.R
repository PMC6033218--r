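test_that("the generator is deterministic given a seed and sensitive to it", {
  cfg <- generatorConfig(seed = 101, n_samples = 40)
  refs1 <- makeReferenceProfiles(cfg)
  refs2 <- makeReferenceProfiles(cfg)
  expect_identical(exprValues(refs1), exprValues(refs2))
  refs3 <- makeReferenceProfiles(generatorConfig(seed = 102, n_samples = 40))
  expect_true(any(exprValues(refs1) != exprValues(refs3)))

  t1 <- simulateTumors(cfg, refs1)
  t2 <- simulateTumors(cfg, refs1)
  expect_identical(exprValues(t1$expr), exprValues(t2$expr))
  expect_identical(t1$purity, t2$purity)
  expect_identical(simulateSurvival(cfg, t1$purity),
                   simulateSurvival(cfg, t1$purity))
  q1 <- toQpcr(cfg, t1$expr)
  q2 <- toQpcr(cfg, t1$expr)
  expect_identical(exprValues(q1$ct), exprValues(q2$ct))
  m1 <- makeMetastases(cfg, t1$expr, sampleIds(t1$expr)[1:3])
  m2 <- makeMetastases(cfg, t1$expr, sampleIds(t1$expr)[1:3])
  expect_identical(exprValues(m1$expr), exprValues(m2$expr))
})

test_that("reference regions are distinct: pairwise correlations below 0.8", {
  cfg <- generatorConfig(seed = 5)
  refs <- makeReferenceProfiles(cfg)
  cc <- cor(exprValues(refs)[cfg$signature_genes, ], method = "spearman")
  expect_lt(max(cc[upper.tri(cc)]), 0.8)
})

test_that("tumors approach the origin profile in the pure, noise-free limit", {
  cfg <- generatorConfig(seed = 15, n_samples = 5, noise_sd = 0,
                         purity_shape1 = 1e7, purity_shape2 = 1e-3)
  refs <- makeReferenceProfiles(cfg)
  tum <- simulateTumors(cfg, refs)
  expect_true(all(tum$purity > 0.999))
  origin <- exprValues(refs)[, originRegion(refs)]
  for (s in sampleIds(tum$expr))
    expect_equal(unname(exprValues(tum$expr)[, s]), unname(origin),
                 tolerance = 1e-2)
})

test_that("survival depends on similarity exactly as configured", {
  cfg0 <- generatorConfig(seed = 25, n_samples = 500, beta = 0)
  w <- setNames(rbeta(500, 5, 2), sprintf("S%03d", 1:500))
  s0 <- simulateSurvival(cfg0, w)
  expect_lt(abs(cor(w, s0$time, method = "spearman")), 0.15)

  # beta = 2, effectively no censoring: Cox recovers the effect
  cfg2 <- generatorConfig(seed = 26, beta = 2, censor_horizon = 1e6)
  s2 <- simulateSurvival(cfg2, w)
  expect_true(all(s2$event == 1))          # horizon -> infinity: all events
  fit <- fitCox(s2, data.frame(w = unname(w)))
  expect_gt(fit@table$coef, -2.4); expect_lt(fit@table$coef, -1.6)
})

test_that("qRT-PCR re-measurement has the configured failure and noise", {
  cfg <- generatorConfig(seed = 35, n_genes = 100, n_signature = 100,
                         n_samples = 100, failure_rate = 0.02)
  refs <- makeReferenceProfiles(cfg)
  tum <- simulateTumors(cfg, refs)
  qp <- toQpcr(cfg, tum$expr)
  missing_n <- sum(is.na(exprValues(qp$ct)[cfg$signature_genes, ]))
  # binomial 99% interval around 0.02 * 100 * 100 = 200
  expect_gte(missing_n, 120); expect_lte(missing_n, 280)

  cfg0 <- generatorConfig(seed = 36, n_samples = 30, failure_rate = 0,
                          ct_noise_sd = 0)
  refs0 <- makeReferenceProfiles(cfg0)
  tum0 <- simulateTumors(cfg0, refs0)
  qp0 <- toQpcr(cfg0, tum0$expr)
  expect_false(anyNA(exprValues(qp0$ct)))
  # slope 1, no noise: -Ct preserves each gene's rank order across samples
  g <- cfg0$signature_genes[7]
  expect_identical(order(-exprValues(qp0$ct)[g, ]),
                   order(exprValues(tum0$expr)[g, ]))
  expect_identical(signatureGenes(qp0$panel), cfg0$signature_genes)
  expect_length(normalizationGenes(qp0$panel), 5L)
})

test_that("metastases are small perturbations of their primaries", {
  cfg <- generatorConfig(seed = 45, n_samples = 20, met_sd = 0)
  refs <- makeReferenceProfiles(cfg)
  tum <- simulateTumors(cfg, refs)
  m0 <- makeMetastases(cfg, tum$expr, sampleIds(tum$expr)[1:2])
  expect_equal(exprValues(m0$expr)[, "S001_met"],
               exprValues(tum$expr)[, "S001"], ignore_attr = TRUE)

  cfg1 <- generatorConfig(seed = 46, n_samples = 20)   # met_sd 0.1
  tum1 <- simulateTumors(cfg1, makeReferenceProfiles(cfg1))
  m1 <- makeMetastases(cfg1, tum1$expr, sampleIds(tum1$expr)[1:4],
                       regions = c(1, 1, 1, 4))
  d <- exprValues(m1$expr)[, "S001_met"] - exprValues(tum1$expr)[, "S001"]
  expect_gt(sd(d), 0.08); expect_lt(sd(d), 0.12)   # within 20% of met_sd
  expect_equal(sum(m1$roles$role == "metastasis_region"), 4L)
  expect_equal(ncol(m1$expr), 7L)
})

test_that("simulateCohort writes a complete plain-text fixture set", {
  dir <- withr::local_tempdir()
  cfg <- generatorConfig(seed = 55, n_samples = 12, n_genes = 40,
                         n_signature = 20)
  out <- simulateCohort(cfg, dir)
  files <- c("reference_profiles.tsv", "reference_profiles.tsv.json",
             "tumors_rnaseq.tsv", "tumors_qpcr_ct.tsv",
             "metastases_rnaseq.tsv", "gene_panel.json", "clinical.csv",
             "truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  refs_back <- readReferenceProfiles(file.path(dir, "reference_profiles.tsv"))
  expect_equal(exprValues(refs_back), exprValues(out$refs), tolerance = 1e-9)
  expect_identical(originRegion(refs_back), originRegion(out$refs))
  clin <- readClinicalTable(file.path(dir, "clinical.csv"))
  expect_equal(nrow(clin), 12L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unlist(truth$purity), out$tumors$purity, tolerance = 1e-12)
})
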