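#' Exclude assays that failed at least once
#'
#' For qRT-PCR panels intended for clinical use, any assay (gene) with one or
#' more missing Ct values across the cohort is excluded, to ensure minimal
#' failure rates in future applications.
#'
#' @param qpcr an \linkS4class{ExpressionMatrix} (platform \code{"qpcr_ct"}).
#' @return list with \code{retained} (gene ids with zero failures) and
#'   \code{report} (data.frame gene/failures/retained). An empty retained
#'   list is a valid, reportable outcome.
#' @export
filterFailedAssays <- function(qpcr) {
  stopifnot(is(qpcr, "ExpressionMatrix"))
  v <- exprValues(qpcr)
  failures <- rowSums(is.na(v))
  report <- data.frame(gene = geneIds(qpcr), failures = as.integer(failures),
                       retained = failures == 0L, row.names = NULL)
  list(retained = report$gene[report$retained], report = report)
}

#' Cross-platform comparability filter
#'
#' Retains genes whose per-gene mean and variability agree between a
#' development platform (e.g. RNA-seq log expression) and normalized
#' qRT-PCR values. Both matrices are first per-sample median-centered to
#' remove platform location offsets; then per gene,
#' mean and SD across samples are computed on each platform and a gene is
#' retained iff
#' \code{|mean_dev - mean_qpcr| <= max_mean_shift * pooled SD} and the SD
#' ratio (larger/smaller) is at most \code{max_sd_ratio}. Genes with zero SD
#' on both platforms are retained but flagged degenerate.
#'
#' @param dev development-platform \linkS4class{ExpressionMatrix}.
#' @param qpcr normalized qRT-PCR \linkS4class{ExpressionMatrix}.
#' @param maxMeanShift maximum absolute mean difference, in pooled-SD units
#'   (default 0.5).
#' @param maxSdRatio maximum SD ratio, larger over smaller (default 2).
#' @return list with \code{retained} (gene ids) and \code{report}
#'   (per-gene data.frame with both means, both SDs, decision and reason).
#' @export
comparabilityFilter <- function(dev, qpcr, maxMeanShift = 0.5, maxSdRatio = 2) {
  stopifnot(is(dev, "ExpressionMatrix"), is(qpcr, "ExpressionMatrix"),
            maxMeanShift > 0, maxSdRatio >= 1)
  if (ncol(dev) < 3L || ncol(qpcr) < 3L)
    stop("each platform needs at least 3 samples")
  shared <- intersect(geneIds(dev), geneIds(qpcr))
  if (!length(shared)) stop("no shared genes between the platforms")
  center <- function(m) sweep(m, 2L, apply(m, 2L, median, na.rm = TRUE))
  dv <- center(exprValues(dev))[shared, , drop = FALSE]
  qv <- center(exprValues(qpcr))[shared, , drop = FALSE]
  st <- function(m) list(mean = rowMeans(m, na.rm = TRUE),
                         sd = apply(m, 1L, sd, na.rm = TRUE))
  d <- st(dv); q <- st(qv)
  pooled <- sqrt((d$sd^2 + q$sd^2) / 2)
  degenerate <- d$sd == 0 & q$sd == 0
  shift_ok <- abs(d$mean - q$mean) <= maxMeanShift * pooled
  ratio <- pmax(d$sd, q$sd) / pmin(d$sd, q$sd)
  ratio_ok <- ratio <= maxSdRatio
  retained <- degenerate | (shift_ok & ratio_ok)
  reason <- rep("", length(shared))
  reason[!shift_ok & !degenerate] <- "mean_shift"
  reason[!ratio_ok & !degenerate] <- ifelse(
    nzchar(reason[!ratio_ok & !degenerate]), "mean_shift;sd_ratio", "sd_ratio")
  reason[degenerate] <- "degenerate"
  report <- data.frame(gene = shared,
                       mean_dev = d$mean, mean_qpcr = q$mean,
                       sd_dev = d$sd, sd_qpcr = q$sd,
                       retained = retained, reason = reason,
                       row.names = NULL)
  list(retained = shared[retained], report = report)
}

## internal: AIC on the stats::AIC scale for an OLS fit given RSS, n, k
## (k = number of slope terms; +2 for intercept and sigma)
.ols_aic <- function(rss, n, k) {
  n * (log(2 * pi) + log(rss / n) + 1) + 2 * (k + 2)
}

## internal: RSS of y regressed on design columns sel (with intercept)
.ols_rss <- function(Xc, y, sel) {
  if (!length(sel)) return(sum((y - mean(y))^2))
  f <- stats::lm.fit(cbind(1, Xc[, sel, drop = FALSE]), y)
  sum(f$residuals^2)
}

#' Sparse linear reconstruction of the correlation-based score
#'
#' Selects a small linear model that reconstructs the correlation-based S3
#' score from individual gene expression values, so the score can be ported
#' to a low-plex platform such as qRT-PCR.
#'
#' Default method \code{"stepwise_aic"}: bidirectional stepwise selection
#' minimizing AIC, starting from the empty (intercept-only) model; when
#' \code{maxTerms} is set, steps that would exceed it are not considered.
#' Selection stops early when the fit is numerically perfect
#' (RSS/n below 1e-12), where AIC comparisons are meaningless.
#' Alternative \code{"lasso"}: an L1-penalized path
#' (\code{glmnet}) with the penalty chosen as the smallest on the path whose
#' support does not exceed \code{maxTerms}, followed by an unpenalized refit
#' on the selected support.
#'
#' @param X an \linkS4class{ExpressionMatrix} restricted to candidate genes
#'   (or a genes x samples matrix with dimnames).
#' @param y numeric response, one correlation-based score per sample of
#'   \code{X} (order must match; names checked when present).
#' @param method \code{"stepwise_aic"} (default) or \code{"lasso"}.
#' @param maxTerms optional cap on the number of selected genes.
#' @return A \linkS4class{LinearScoreModel}; the attribute
#'   \code{"collinear"} on the result lists candidates found collinear with
#'   the selected support (degenerate design is reported, not silently
#'   dropped).
#' @export
selectLinearModel <- function(X, y, method = c("stepwise_aic", "lasso"),
                              maxTerms = NULL) {
  method <- match.arg(method)
  if (is(X, "ExpressionMatrix")) X <- exprValues(X)
  if (anyNA(X)) stop("candidate matrix must not contain missing values")
  Xc <- t(X)                                    # samples x genes
  if (nrow(Xc) != length(y)) stop("samples in X must match y")
  if (!is.null(names(y)) && !is.null(rownames(Xc)) &&
      !identical(names(y), rownames(Xc)))
    stop("sample names of y do not match X")
  genes <- colnames(Xc)
  n <- nrow(Xc)
  if (method == "stepwise_aic" && n <= ncol(Xc) && is.null(maxTerms))
    stop("stepwise selection needs n > candidate count (or set maxTerms)")

  if (method == "lasso") {
    if (is.null(maxTerms)) maxTerms <- ncol(Xc)
    fit <- glmnet::glmnet(Xc, y, alpha = 1)
    sizes <- fit$df
    ok <- which(sizes <= maxTerms & sizes >= 1L)
    if (!length(ok)) stop("no lasso path point with support <= maxTerms")
    i <- ok[length(ok)]                         # smallest admissible penalty
    b <- as.matrix(coef(fit, s = fit$lambda[i]))[-1L, 1L]
    support <- genes[b != 0]
  } else {
    support <- character(0)
    cur_rss <- .ols_rss(Xc, y, support)
    cur_aic <- .ols_aic(cur_rss, n, 0L)
    collinear <- character(0)
    repeat {
      if (cur_rss / n < 1e-12) break            # numerically perfect fit
      best <- list(aic = cur_aic, move = NULL)
      cand_add <- setdiff(genes, support)
      if (!is.null(maxTerms) && length(support) >= maxTerms)
        cand_add <- character(0)
      for (g in cand_add) {
        sel <- c(support, g)
        rss <- .ols_rss(Xc, y, sel)
        k <- qr(cbind(1, Xc[, sel, drop = FALSE]))$rank - 1L
        if (k < length(sel)) { collinear <- union(collinear, g); next }
        a <- .ols_aic(rss, n, length(sel))
        if (a < best$aic - 1e-8) best <- list(aic = a, move = c("add", g),
                                              rss = rss)
      }
      for (g in support) {
        sel <- setdiff(support, g)
        rss <- .ols_rss(Xc, y, sel)
        a <- .ols_aic(rss, n, length(sel))
        if (a < best$aic - 1e-8) best <- list(aic = a, move = c("drop", g),
                                              rss = rss)
      }
      if (is.null(best$move)) break
      support <- if (best$move[1] == "add") c(support, best$move[2])
                 else setdiff(support, best$move[2])
      cur_aic <- best$aic
      cur_rss <- best$rss
    }
    if (!length(support))
      stop("stepwise selection retained no genes (no candidate improves AIC)")
  }

  df <- data.frame(y = y, Xc[, support, drop = FALSE], check.names = FALSE)
  refit <- lm(y ~ ., data = df)
  cf <- coef(refit)
  if (anyNA(cf)) stop("degenerate design: collinear support ",
                      paste(support[is.na(cf[-1L])], collapse = ", "))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(refit)^2) / tss else NA_real_
  model <- LinearScoreModel(intercept = cf[[1L]],
                            coefficients = setNames(cf[-1L], support),
                            method = method, r2 = r2)
  if (method == "stepwise_aic") attr(model, "collinear") <- collinear
  model
}

#' Apply a linear score model to expression data
#'
#' \code{score(s) = intercept + sum_g coef(g) * expr(g, s)}. All model genes
#' must be present with no missing values.
#'
#' @param model a \linkS4class{LinearScoreModel}.
#' @param m an \linkS4class{ExpressionMatrix} carrying the model genes
#'   (for qRT-PCR input, normalize with \code{\link{normalizeQpcr}} first).
#' @return named numeric vector of scores per sample.
#' @export
applyLinearModel <- function(model, m) {
  stopifnot(is(model, "LinearScoreModel"), is(m, "ExpressionMatrix"))
  genes <- names(model@coefficients)
  absent <- setdiff(genes, geneIds(m))
  if (length(absent))
    stop("model genes absent from matrix: ", paste(absent, collapse = ", "))
  v <- exprValues(m)[genes, , drop = FALSE]
  if (anyNA(v)) {
    bad <- genes[rowSums(is.na(v)) > 0]
    stop("model genes with missing values: ", paste(bad, collapse = ", "))
  }
  drop(model@intercept + crossprod(v, model@coefficients)[, 1L])
}

#' Rank concordance between two score vectors
#'
#' Spearman rank correlation between two scorings of the same samples, the
#' statistic used to judge how well a reduced score tracks the full one.
#'
#' @param a,b numeric score vectors over the same samples (matched by name
#'   when both are named, by position otherwise); n >= 3.
#' @return list with \code{rho}, \code{n}, and a small \code{summary}
#'   data.frame (per-sample a, b, rank difference).
#' @export
scoreConcordance <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("mismatched sample sets")
    b <- b[names(a)]
  } else if (length(a) != length(b)) stop("mismatched sample sets")
  if (length(a) < 3L) stop("concordance needs n >= 3")
  rho <- cor(a, b, method = "spearman")
  list(rho = rho, n = length(a),
       summary = data.frame(sample = if (is.null(names(a)))
                              seq_along(a) else names(a),
                            a = as.numeric(a), b = as.numeric(b),
                            rank_diff = rank(a) - rank(b), row.names = NULL))
}
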