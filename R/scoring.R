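#' Interprofile correlations against nephron-region references
#'
#' Correlates each tumor sample's expression profile with each nephron
#' region's reference profile over the genes shared between the two inputs.
#' Samples with sporadic missing values use pairwise-complete genes; fewer
#' than 3 usable genes for any sample-region pair, or a constant profile,
#' is an error (the correlation is undefined there).
#'
#' @param tumors an \linkS4class{ExpressionMatrix}.
#' @param refs a \linkS4class{ReferenceProfiles}.
#' @param method \code{"spearman"} (default; robust to cross-platform scale
#'   differences) or \code{"pearson"}.
#' @return sample x region numeric matrix of correlations in [-1, 1].
#' @export
interprofileCorrelations <- function(tumors, refs,
                                     method = c("spearman", "pearson")) {
  stopifnot(is(tumors, "ExpressionMatrix"), is(refs, "ReferenceProfiles"))
  method <- match.arg(method)
  shared <- intersect(geneIds(tumors), geneIds(refs))
  if (length(shared) < 3L)
    stop("fewer than 3 shared genes between tumors and reference profiles")
  tv <- exprValues(tumors)[shared, , drop = FALSE]
  rv <- exprValues(refs)[shared, , drop = FALSE]
  ok <- colSums(!is.na(tv)) >= 3L
  if (!all(ok))
    stop("samples with fewer than 3 non-missing shared genes: ",
         paste(colnames(tv)[!ok], collapse = ", "))
  cst <- apply(tv, 2L, function(x) {
    x <- x[!is.na(x)]; max(x) - min(x) == 0
  })
  if (any(cst))
    stop("constant expression profile (correlation undefined) for sample(s): ",
         paste(colnames(tv)[cst], collapse = ", "))
  cc <- suppressWarnings(
    cor(tv, rv, method = method, use = "pairwise.complete.obs"))
  if (anyNA(cc))
    stop("undefined correlations (degenerate pairwise-complete overlap)")
  cc
}

#' Aggregate interprofile correlations to the S3 score
#'
#' Default aggregation \code{"origin"}: the score is the correlation with the
#' designated cell-of-origin region. Alternative \code{"origin_margin"}: the
#' origin correlation minus the maximum correlation over all other regions.
#'
#' @param correlations sample x region matrix from
#'   \code{\link{interprofileCorrelations}}.
#' @param refs the \linkS4class{ReferenceProfiles} (supplies the origin).
#' @param aggregation \code{"origin"} or \code{"origin_margin"}.
#' @param method correlation method tag recorded on the result.
#' @return An \linkS4class{S3ScoreResult}.
#' @export
s3Score <- function(correlations, refs, aggregation = c("origin", "origin_margin"),
                    method = "spearman") {
  aggregation <- match.arg(aggregation)
  org <- originRegion(refs)
  if (!org %in% colnames(correlations))
    stop("origin region column '", org, "' absent from correlation matrix")
  score <- switch(aggregation,
    origin = correlations[, org],
    origin_margin = {
      others <- correlations[, setdiff(colnames(correlations), org),
                             drop = FALSE]
      correlations[, org] - apply(others, 1L, max)
    })
  names(score) <- rownames(correlations)
  new("S3ScoreResult", correlations = correlations, score = score,
      method = method, aggregation = aggregation)
}

#' Compute S3 scores from expression data in one call
#'
#' Convenience chain of \code{\link{interprofileCorrelations}} and
#' \code{\link{s3Score}}.
#'
#' @inheritParams interprofileCorrelations
#' @inheritParams s3Score
#' @return An \linkS4class{S3ScoreResult}.
#' @export
computeS3Score <- function(tumors, refs, method = c("spearman", "pearson"),
                           aggregation = c("origin", "origin_margin")) {
  method <- match.arg(method)
  cc <- interprofileCorrelations(tumors, refs, method = method)
  s3Score(cc, refs, aggregation = match.arg(aggregation), method = method)
}

#' Dichotomize scores into S3-high / S3-low strata
#'
#' Scores strictly greater than the cut-off are \code{"S3_high"} (favourable
#' prognosis: more similar to the cell of origin); scores less than or equal
#' to the cut-off are \code{"S3_low"}. Ties at the cut-off are measure-zero
#' on continuous scores; the convention is deterministic and documented.
#'
#' @param scores named numeric vector, or an \linkS4class{S3ScoreResult}.
#' @param cutoff finite numeric threshold (or a \linkS4class{CutoffModel}).
#' @return A \linkS4class{RiskClassification}.
#' @export
classifyRisk <- function(scores, cutoff) {
  if (is(scores, "S3ScoreResult")) scores <- scoreValues(scores)
  if (is(cutoff, "CutoffModel")) cutoff <- cutoffValue(cutoff)
  if (length(cutoff) != 1L || !is.finite(cutoff))
    stop("cutoff must be a single finite number")
  if (anyNA(scores))
    stop("missing score for sample(s): ",
         paste(names(scores)[is.na(scores)], collapse = ", "))
  if (is.null(names(scores))) names(scores) <- seq_along(scores)
  lab <- ifelse(scores > cutoff, "S3_high", "S3_low")
  new("RiskClassification", label = lab, cutoff = as.numeric(cutoff))
}
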