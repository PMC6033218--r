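#' Accessors for S3score containers
#'
#' @param x an object of one of the package's S4 classes.
#' @return \code{geneIds}/\code{sampleIds}/\code{regionLabels}: character
#'   vectors; \code{exprValues}: the underlying numeric matrix;
#'   \code{platform}, \code{originRegion}: character scalars;
#'   \code{scoreValues}: named numeric scores.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("originRegion", function(x) standardGeneric("originRegion"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setGeneric("normalizationGenes", function(x) standardGeneric("normalizationGenes"))
#' @rdname accessors
#' @export
setGeneric("riskLabels", function(x) standardGeneric("riskLabels"))
#' @rdname accessors
#' @export
setGeneric("cutoffValue", function(x) standardGeneric("cutoffValue"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("platform", "ExpressionMatrix", function(x) x@platform)
#' @rdname accessors
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("geneIds", "ReferenceProfiles", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "ReferenceProfiles", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("regionLabels", "ReferenceProfiles", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("originRegion", "ReferenceProfiles", function(x) x@originRegion)

#' @rdname accessors
#' @export
setMethod("signatureGenes", "GenePanel", function(x) x@signatureGenes)
#' @rdname accessors
#' @export
setMethod("normalizationGenes", "GenePanel", function(x) x@normalizationGenes)
#' @rdname accessors
#' @export
setMethod("normalizationGenes", "LinearScoreModel",
          function(x) x@normalizationGenes)

#' @rdname accessors
#' @export
setMethod("scoreValues", "S3ScoreResult", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("sampleIds", "S3ScoreResult", function(x) rownames(x@correlations))
#' @rdname accessors
#' @export
setMethod("regionLabels", "S3ScoreResult", function(x) colnames(x@correlations))

#' @rdname accessors
#' @param object an S3score S4 object (for \code{show}).
#' @export
setMethod("sampleIds", "RiskClassification", function(x) names(x@label))
#' @rdname accessors
#' @export
setMethod("riskLabels", "RiskClassification", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("cutoffValue", "RiskClassification", function(x) x@cutoff)
#' @rdname accessors
#' @export
setMethod("cutoffValue", "CutoffModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("coef", "LinearScoreModel", function(object) object@coefficients)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(object@values), ncol(object@values), object@platform))
  nmiss <- sum(is.na(object@values))
  if (nmiss) cat(sprintf("  %d missing values\n", nmiss))
})

setMethod("show", "ReferenceProfiles", function(object) {
  cat(sprintf("ReferenceProfiles: %d genes x %d regions (origin: %s)\n",
              nrow(object@values), ncol(object@values), object@originRegion))
})

setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel: %d signature genes, %d normalization genes\n",
              length(object@signatureGenes), length(object@normalizationGenes)))
})

setMethod("show", "S3ScoreResult", function(object) {
  cat(sprintf("S3ScoreResult: %d samples x %d regions (%s, aggregation: %s)\n",
              nrow(object@correlations), ncol(object@correlations),
              object@method, object@aggregation))
  cat(sprintf("  score range [%.3f, %.3f]\n",
              min(object@score), max(object@score)))
})

setMethod("show", "RiskClassification", function(object) {
  tab <- table(factor(object@label, levels = c("S3_high", "S3_low")))
  cat(sprintf("RiskClassification at cutoff %.4g: %d S3_high, %d S3_low\n",
              object@cutoff, tab[["S3_high"]], tab[["S3_low"]]))
})

setMethod("show", "LinearScoreModel", function(object) {
  cat(sprintf("LinearScoreModel (%s): intercept %.4g + %d genes, R2 = %.3f\n",
              object@method, object@intercept, length(object@coefficients),
              object@r2))
})

setMethod("show", "CutoffModel", function(object) {
  cat(sprintf(
    "CutoffModel: threshold %.4g (max |logrank z| = %.3f, adj. p = %.4g, B = %d)\n",
    object@threshold, object@statistic, object@pAdjusted, object@permutations))
})

setMethod("show", "CoxFit", function(object) {
  cat(sprintf("CoxFit (%s ties): n = %d, events = %d%s\n", object@ties,
              object@n, object@nevent,
              if (length(object@strata) && nzchar(object@strata[1]))
                sprintf(", strata: %s", paste(object@strata, collapse = ", "))
              else ""))
  print(object@table, digits = 4, row.names = FALSE)
})
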