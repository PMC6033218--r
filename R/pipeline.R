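## internal: run manifest capturing inputs and configuration for exact re-runs
.manifest <- function(call_name, params) {
  list(command = call_name, params = params,
       package_version = as.character(utils::packageVersion("S3score")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}

#' Score a cohort with the full correlation-based S3 score and validate
#'
#' Chains interprofile correlation, score aggregation, cut-off
#' classification and the survival validation statistics: per-group
#' Kaplan-Meier summaries, log-rank test, univariate Cox model of the risk
#' class, and Harrell's c-index of the continuous score (negated, so that
#' higher risk means earlier events).
#'
#' @param tumors an \linkS4class{ExpressionMatrix} of signature-gene
#'   expression.
#' @param refs a \linkS4class{ReferenceProfiles}.
#' @param clinical survival records (see \code{\link{survivalRecords}});
#'   matched to samples by \code{sample_id}.
#' @param cutoff fixed score cut-off; ignored when \code{learnCutoff}.
#' @param learnCutoff if \code{TRUE}, discover the cut-off with
#'   \code{\link{findCutoff}} (config via \code{cutoffArgs}).
#' @param cutoffArgs list of arguments passed on to
#'   \code{\link{findCutoff}}.
#' @param method,aggregation forwarded to \code{\link{computeS3Score}}.
#' @param outDir optional directory; when given, score table, report JSON
#'   and manifest are written there.
#' @return list with \code{scores} (\linkS4class{S3ScoreResult}),
#'   \code{classification}, \code{cutoff} (number or
#'   \linkS4class{CutoffModel}), \code{report} (km per group, logrank, cox,
#'   cindex, group sizes) and \code{manifest}.
#' @export
runScore97 <- function(tumors, refs, clinical, cutoff = NULL,
                       learnCutoff = is.null(cutoff), cutoffArgs = list(),
                       method = "spearman", aggregation = "origin",
                       outDir = NULL) {
  res <- computeS3Score(tumors, refs, method = method,
                        aggregation = aggregation)
  clinical <- clinical[match(sampleIds(res), clinical$sample_id), ]
  if (anyNA(clinical$sample_id))
    stop("survival stage: clinical records missing for some scored samples")
  if (nrow(clinical) < 2L)
    stop("survival stage: need at least 2 samples with outcomes")
  sc <- scoreValues(res)
  cut <- if (learnCutoff)
    do.call(findCutoff, c(list(scores = sc, records = clinical), cutoffArgs))
  else cutoff
  cls <- classifyRisk(sc, cut)
  grp <- factor(riskLabels(cls), levels = c("S3_high", "S3_low"))
  if (any(table(grp) == 0L))
    stop("survival stage: empty risk stratum at cutoff ",
         format(cutoffValue(cls)))
  km <- lapply(split(clinical, grp), kmEstimate)
  lr <- logrankTest(clinical, grp)
  cox <- fitCox(clinical,
                data.frame(S3_low = as.integer(grp == "S3_low")))
  ci <- harrellC(clinical, risk = -sc)
  report <- list(groups = as.list(table(grp)),
                 km = lapply(km, `[[`, "curve"), logrank = lr,
                 cox = cox@table, cindex = ci)
  manifest <- .manifest("runScore97",
                        list(n_samples = length(sc), method = method,
                             aggregation = aggregation,
                             cutoff = cutoffValue(cls),
                             learned = learnCutoff,
                             cutoffArgs = cutoffArgs))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeS3ScoreResult(res, file.path(outDir, "scores.tsv"))
    jsonlite::write_json(list(report = report[c("groups", "logrank",
                                                "cindex")],
                              cox = cox@table),
                         file.path(outDir, "validation_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(scores = res, classification = cls, cutoff = cut, report = report,
       manifest = manifest)
}

#' Refine the full signature to a sparse cross-platform linear score
#'
#' The platform-transfer workflow: (1) exclude qRT-PCR assays that failed at
#' least once; (2) keep genes comparable in mean and variability between
#' the development platform and normalized qRT-PCR; (3) select a sparse
#' linear model on the development cohort that reconstructs the
#' correlation-based score from the retained candidate genes; (4) report
#' concordance of the reduced score with the full score on a held-out
#' validation cohort when one is supplied.
#'
#' @param dev development-cohort \linkS4class{ExpressionMatrix} (log2
#'   platform) carrying the signature genes.
#' @param refs a \linkS4class{ReferenceProfiles}.
#' @param qpcr raw Ct \linkS4class{ExpressionMatrix} of the qRT-PCR
#'   cohort.
#' @param panel a \linkS4class{GenePanel}.
#' @param maxMeanShift,maxSdRatio comparability criteria (see
#'   \code{\link{comparabilityFilter}}).
#' @param method,maxTerms forwarded to \code{\link{selectLinearModel}}.
#' @param validation optional held-out \linkS4class{ExpressionMatrix} for
#'   concordance of reduced vs full score.
#' @param scoreMethod correlation method for the response score (default
#'   \code{"pearson"}: the variance-weighted interprofile correlation is the
#'   quantity a sparse linear model in gene expression can reconstruct;
#'   rank correlation weights all signature genes equally, so low-variance
#'   genes contribute irreducible rank jitter to it).
#' @return list with \code{model} (\linkS4class{LinearScoreModel},
#'   normalization genes recorded), \code{failedAssays} and
#'   \code{comparability} filter reports, \code{candidates} (gene ids used
#'   for selection), \code{counts} (signature / after failure filter /
#'   after comparability / selected), \code{concordance} (NULL without a
#'   validation cohort) and \code{manifest}.
#' @export
runRefine <- function(dev, refs, qpcr, panel, maxMeanShift = 0.5,
                      maxSdRatio = 2, method = "stepwise_aic",
                      maxTerms = NULL, validation = NULL,
                      scoreMethod = "pearson") {
  sig <- signatureGenes(panel)
  fa <- filterFailedAssays(qpcr)
  keep1 <- intersect(fa$retained, sig)
  if (!length(keep1)) stop("no signature assays survived the failure filter")
  qn <- normalizeQpcr(
    alignGenes(qpcr, union(keep1, normalizationGenes(panel))), panel)
  cf <- comparabilityFilter(alignGenes(dev, keep1), qn,
                            maxMeanShift = maxMeanShift,
                            maxSdRatio = maxSdRatio)
  candidates <- cf$retained
  if (!length(candidates)) stop("empty candidate set after filtering")
  dev_scores <- computeS3Score(alignGenes(dev, sig), refs,
                               method = scoreMethod)
  model <- selectLinearModel(alignGenes(dev, candidates),
                             scoreValues(dev_scores), method = method,
                             maxTerms = maxTerms)
  model@normalizationGenes <- normalizationGenes(panel)
  conc <- NULL
  if (!is.null(validation)) {
    full <- computeS3Score(alignGenes(validation, sig), refs,
                           method = scoreMethod)
    reduced <- applyLinearModel(model, validation)
    conc <- scoreConcordance(reduced, scoreValues(full))
  }
  list(model = model, failedAssays = fa$report, comparability = cf$report,
       candidates = candidates,
       counts = c(signature = length(sig), after_failure = length(keep1),
                  after_comparability = length(candidates),
                  selected = length(coef(model))),
       concordance = conc,
       manifest = .manifest("runRefine",
                            list(maxMeanShift = maxMeanShift,
                                 maxSdRatio = maxSdRatio, method = method,
                                 maxTerms = maxTerms, scoreMethod = scoreMethod,
                                 n_dev = ncol(dev), n_qpcr = ncol(qpcr))))
}

#' Does the molecular score improve an established predictor (and vice versa)?
#'
#' Fits Cox models for the established predictor alone, the molecular risk
#' class alone, and both together, and reports the analysis-of-deviance
#' (likelihood-ratio) chi-square for adding each predictor to the other.
#'
#' @param clinical survival records.
#' @param class molecular risk classification: a
#'   \linkS4class{RiskClassification} or a vector of labels per record.
#' @param established numeric established predictor per record (e.g. SSIGN
#'   scores).
#' @return list with the three \linkS4class{CoxFit}s and
#'   \code{addClass} / \code{addEstablished} likelihood-ratio results.
#' @export
runImprovementTest <- function(clinical, class, established) {
  clinical <- .check_records(clinical)
  if (is(class, "RiskClassification")) {
    lab <- riskLabels(class)[clinical$sample_id]
    if (anyNA(lab)) stop("classification missing for some records")
  } else lab <- class
  x_class <- as.integer(factor(lab)) - 1L
  cov_both <- data.frame(established = as.numeric(established),
                         class = x_class)
  fit_est <- fitCox(clinical, cov_both["established"])
  fit_class <- fitCox(clinical, cov_both["class"])
  fit_both <- fitCox(clinical, cov_both)
  list(established = fit_est, class = fit_class, both = fit_both,
       addClass = likelihoodRatioTest(fit_est, fit_both),
       addEstablished = likelihoodRatioTest(fit_class, fit_both))
}
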