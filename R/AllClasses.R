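#' @import methods
#' @importFrom stats cor median sd quantile rnorm runif rexp rbeta rgamma
#'   setNames lm AIC coef pchisq qnorm complete.cases var residuals
NULL

EXPR_PLATFORMS <- c("rnaseq_log", "microarray_log", "qpcr_ct", "qpcr_norm")

#' ExpressionMatrix: gene-by-sample expression values with a platform tag
#'
#' The universal carrier between pipeline stages. Rows are genes, columns are
#' samples; values are log2-scale expression, except for platform
#' \code{"qpcr_ct"} where they are raw qRT-PCR threshold cycles (Ct). Missing
#' values are permitted and explicitly marked as \code{NA}.
#'
#' @slot values numeric matrix (genes x samples) with unique dimnames.
#' @slot platform one of \code{"rnaseq_log"}, \code{"microarray_log"},
#'   \code{"qpcr_ct"}, \code{"qpcr_norm"}.
#'
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
  representation(values = "matrix", platform = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character(0)
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry gene (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate gene identifiers")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate sample identifiers")
  }
  if (length(object@platform) != 1L || !object@platform %in% EXPR_PLATFORMS)
    msgs <- c(msgs, sprintf("platform must be one of: %s",
                            paste(EXPR_PLATFORMS, collapse = ", ")))
  else if (object@platform == "qpcr_ct") {
    obs <- v[!is.na(v)]
    if (length(obs) && (min(obs) < 0 || max(obs) > 45))
      msgs <- c(msgs, "qpcr_ct values must lie in the plausible Ct range [0, 45]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   dimnames.
#' @param platform platform tag; see \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "rnaseq_log")
#' @export
ExpressionMatrix <- function(values, platform = "rnaseq_log") {
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, platform = platform)
}

#' GenePanel: signature and normalization gene lists
#'
#' @slot signatureGenes character vector of signature gene identifiers (the
#'   97-gene analogue).
#' @slot normalizationGenes character vector of reference ("housekeeping")
#'   genes used for delta-Ct normalization (the 5-gene analogue).
#' @exportClass GenePanel
setClass("GenePanel",
  representation(signatureGenes = "character", normalizationGenes = "character"))

setValidity("GenePanel", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@signatureGenes))
    msgs <- c(msgs, "duplicate signature genes")
  if (anyDuplicated(object@normalizationGenes))
    msgs <- c(msgs, "duplicate normalization genes")
  if (length(intersect(object@signatureGenes, object@normalizationGenes)))
    msgs <- c(msgs, "signature and normalization gene lists must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' @rdname GenePanel-class
#' @param signatureGenes,normalizationGenes character vectors of gene ids.
#' @export
GenePanel <- function(signatureGenes, normalizationGenes = character(0)) {
  new("GenePanel",
      signatureGenes = as.character(signatureGenes),
      normalizationGenes = as.character(normalizationGenes))
}

#' ReferenceProfiles: nephron-region reference expression profiles
#'
#' Gene-by-region matrix of log2-scale expression for the nephron regions,
#' with one region designated the tumor's proposed cell of origin (for clear
#' cell renal cell carcinoma, the S3 segment of the proximal tubule).
#'
#' @slot values numeric matrix, genes x regions, no missing values.
#' @slot originRegion one of the region (column) labels.
#' @exportClass ReferenceProfiles
setClass("ReferenceProfiles",
  representation(values = "matrix", originRegion = "character"))

setValidity("ReferenceProfiles", function(object) {
  v <- object@values
  msgs <- character(0)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry gene (row) and region (column) names")
  if (nrow(v) < 3L) msgs <- c(msgs, "at least 3 genes are required")
  if (anyNA(v)) msgs <- c(msgs, "reference profiles must not contain missing values")
  if (length(object@originRegion) != 1L ||
      !(object@originRegion %in% colnames(v)))
    msgs <- c(msgs, "originRegion must be exactly one of the region labels")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ReferenceProfiles-class
#' @param values gene x region numeric matrix with dimnames.
#' @param originRegion region label of the designated cell of origin.
#' @export
ReferenceProfiles <- function(values, originRegion) {
  storage.mode(values) <- "double"
  new("ReferenceProfiles", values = values, originRegion = originRegion)
}

#' S3ScoreResult: interprofile correlations and aggregated scores
#'
#' @slot correlations sample x region matrix of correlation coefficients.
#' @slot score named numeric vector, one score per sample.
#' @slot method correlation method ("spearman" or "pearson").
#' @slot aggregation aggregation tag ("origin" or "origin_margin").
#' @exportClass S3ScoreResult
setClass("S3ScoreResult",
  representation(correlations = "matrix", score = "numeric",
                 method = "character", aggregation = "character"))

setValidity("S3ScoreResult", function(object) {
  msgs <- character(0)
  r <- object@correlations
  obs <- r[!is.na(r)]
  if (length(obs) && (min(obs) < -1 - 1e-12 || max(obs) > 1 + 1e-12))
    msgs <- c(msgs, "correlations must lie in [-1, 1]")
  if (length(object@score) != nrow(r))
    msgs <- c(msgs, "one score per sample is required")
  if (length(msgs)) msgs else TRUE
})

#' RiskClassification: dichotomized score strata
#'
#' Labels are \code{"S3_high"} for scores strictly greater than the cut-off
#' and \code{"S3_low"} otherwise.
#'
#' @slot label named character vector of class labels per sample.
#' @slot cutoff the numeric cut-off used.
#' @exportClass RiskClassification
setClass("RiskClassification",
  representation(label = "character", cutoff = "numeric"))

setValidity("RiskClassification", function(object) {
  msgs <- character(0)
  if (!all(object@label %in% c("S3_high", "S3_low")))
    msgs <- c(msgs, "labels must be S3_high or S3_low")
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
    msgs <- c(msgs, "cutoff must be a single finite number")
  if (is.null(names(object@label)))
    msgs <- c(msgs, "labels must be named by sample")
  if (length(msgs)) msgs else TRUE
})

#' LinearScoreModel: sparse linear reconstruction of the correlation score
#'
#' The qRT-PCR-ready analogue of the full correlation-based score: an
#' intercept plus a small gene-to-weight map, selected on a development
#' cohort, applicable to any platform carrying the model genes.
#'
#' @slot intercept numeric intercept.
#' @slot coefficients named numeric vector, gene -> weight; non-empty.
#' @slot method training method tag ("stepwise_aic" or "lasso").
#' @slot r2 in-sample R-squared of the fit.
#' @slot normalizationGenes genes required for delta-Ct normalization when
#'   the model is applied to qRT-PCR data.
#' @exportClass LinearScoreModel
setClass("LinearScoreModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 method = "character", r2 = "numeric",
                 normalizationGenes = "character"))

setValidity("LinearScoreModel", function(object) {
  msgs <- character(0)
  if (length(object@coefficients) < 1L || is.null(names(object@coefficients)))
    msgs <- c(msgs, "coefficient map must be non-empty and named by gene")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a single finite number")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LinearScoreModel-class
#' @param intercept,coefficients,method,r2,normalizationGenes see slots.
#' @export
LinearScoreModel <- function(intercept, coefficients, method = "stepwise_aic",
                             r2 = NA_real_, normalizationGenes = character(0)) {
  new("LinearScoreModel", intercept = as.numeric(intercept),
      coefficients = coefficients, method = method, r2 = as.numeric(r2),
      normalizationGenes = as.character(normalizationGenes))
}

#' CutoffModel: survival-selected score threshold
#'
#' The result of maximally selected log-rank cut-point discovery (a depth-1
#' conditional-inference split): the threshold, the maximal standardized
#' two-group log-rank statistic attained there, and a permutation-adjusted
#' selection p-value.
#'
#' @slot threshold selected score threshold (midpoint between the adjacent
#'   observed scores defining the best split).
#' @slot statistic maximal absolute standardized log-rank statistic.
#' @slot pAdjusted permutation-adjusted p-value, add-one estimator.
#' @slot quantileRange candidate quantile range used, length 2.
#' @slot minGroupSize minimum admissible group size.
#' @slot permutations number of permutations B.
#' @slot seed RNG seed used for the permutations.
#' @exportClass CutoffModel
setClass("CutoffModel",
  representation(threshold = "numeric", statistic = "numeric",
                 pAdjusted = "numeric", quantileRange = "numeric",
                 minGroupSize = "integer", permutations = "integer",
                 seed = "integer"))

setValidity("CutoffModel", function(object) {
  msgs <- character(0)
  if (object@pAdjusted < 0 || object@pAdjusted > 1)
    msgs <- c(msgs, "adjusted p must lie in [0, 1]")
  if (length(object@quantileRange) != 2L)
    msgs <- c(msgs, "quantileRange must have length 2")
  if (length(msgs)) msgs else TRUE
})

#' CoxFit: a fitted Cox proportional hazards model
#'
#' Thin S4 wrapper around \code{survival::coxph} keeping the per-covariate
#' summary table (coefficient, SE, HR, 95\% CI, Wald p), log-likelihoods and
#' metadata needed for analysis-of-deviance comparisons.
#'
#' @slot table data.frame with columns term, coef, se, hr, lower, upper, p.
#' @slot loglik numeric(2): null and fitted partial log-likelihood.
#' @slot n number of records used; @slot nevent number of events.
#' @slot terms covariate names; @slot strata strata definition (may be empty).
#' @slot ties ties method ("efron" or "breslow").
#' @slot fit the underlying \code{coxph} object.
#' @exportClass CoxFit
setClass("CoxFit",
  representation(table = "data.frame", loglik = "numeric", n = "integer",
                 nevent = "integer", terms = "character", strata = "character",
                 ties = "character", fit = "ANY"))

setValidity("CoxFit", function(object) {
  msgs <- character(0)
  tb <- object@table
  need <- c("term", "coef", "se", "hr", "lower", "upper", "p")
  if (!all(need %in% names(tb)))
    msgs <- c(msgs, "summary table must carry term/coef/se/hr/lower/upper/p")
  else if (nrow(tb)) {
    ok <- abs(tb$hr - exp(tb$coef)) < 1e-8 * pmax(1, tb$hr)
    if (!all(ok | is.na(ok))) msgs <- c(msgs, "HR must equal exp(coef)")
    br <- tb$lower <= tb$hr & tb$hr <= tb$upper
    if (!all(br | is.na(br))) msgs <- c(msgs, "CI bounds must bracket the HR")
  }
  if (length(msgs)) msgs else TRUE
})
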