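#' @importFrom survival Surv survfit survdiff coxph strata concordance
NULL

#' Validate a set of survival records
#'
#' Survival records are a data.frame with columns \code{sample_id},
#' \code{time} (years, > 0), \code{event} (1 = event, 0 = censored) and
#' optionally \code{endpoint} (\code{"CSS"}, \code{"PFS"} or \code{"OS"}).
#'
#' @param sample_id,time,event,endpoint vectors of equal length.
#' @return validated data.frame.
#' @export
survivalRecords <- function(sample_id, time, event, endpoint = "CSS") {
  if (any(!is.finite(time)) || any(time <= 0)) stop("time must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  if (!all(endpoint %in% c("CSS", "PFS", "OS")))
    stop("endpoint must be CSS, PFS or OS")
  data.frame(sample_id = as.character(sample_id), time = as.numeric(time),
             event = as.integer(event),
             endpoint = rep_len(endpoint, length(time)), row.names = NULL)
}

.check_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (!nrow(records)) stop("empty survival records")
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records survival records (see \code{\link{survivalRecords}}).
#' @return list with a step-function data.frame \code{curve} (time, surv,
#'   n_risk, n_event) and the underlying \code{survfit} object as
#'   \code{fit}. The curve starts at 1 and is non-increasing, dropping only
#'   at event times.
#' @export
kmEstimate <- function(records) {
  records <- .check_records(records)
  fit <- survfit(Surv(time, event) ~ 1, data = records)
  list(curve = data.frame(time = fit$time, surv = fit$surv,
                          n_risk = fit$n.risk, n_event = fit$n.event),
       fit = fit)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km result of \code{\link{kmEstimate}}.
#' @param times numeric vector of evaluation times.
#' @return survival probabilities (right-continuous step function).
#' @export
kmSurvivalAt <- function(km, times) {
  s <- summary(km$fit, times = times, extend = TRUE)
  s$surv
}

#' Log-rank test between groups
#'
#' Standard (O - E)^2 / V chi-square form over the pooled event times, with
#' groups - 1 degrees of freedom.
#'
#' @param records survival records.
#' @param groups group label per record; >= 2 non-empty groups.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
logrankTest <- function(records, groups) {
  records <- .check_records(records)
  groups <- as.factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("log-rank test needs >= 2 non-empty groups")
  sd <- survdiff(Surv(time, event) ~ g,
                 data = cbind(records, g = groups))
  df <- nlevels(groups) - 1L
  list(statistic = sd$chisq, df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fit a Cox proportional hazards model
#'
#' Maximizes the partial likelihood (Efron tie handling by default) and
#' reports, per covariate, the coefficient, SE, hazard ratio with 95\%
#' Wald confidence interval (\code{exp(coef +/- 1.96 SE)}) and Wald p-value.
#' With \code{strataBy}, risk sets form within stratum.
#'
#' @param records survival records.
#' @param covariates data.frame of covariates (numeric or factor), one row
#'   per record.
#' @param strataBy optional factor (or name of a covariate column) defining
#'   strata.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return A \linkS4class{CoxFit}.
#' @export
fitCox <- function(records, covariates, strataBy = NULL,
                   ties = c("efron", "breslow")) {
  records <- .check_records(records)
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(records))
    stop("covariates must have one row per record")
  const <- vapply(covariates, function(x) length(unique(x)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const],
                                          collapse = ", "))
  dat <- cbind(records[, c("time", "event")], covariates)
  strata_name <- character(0)
  rhs <- paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  if (!is.null(strataBy)) {
    if (is.character(strataBy) && length(strataBy) == 1L) {
      strata_name <- strataBy
      if (!strataBy %in% names(covariates)) stop("unknown strata column")
      rhs <- paste(setdiff(sprintf("`%s`", names(covariates)),
                           sprintf("`%s`", strataBy)), collapse = " + ")
      rhs <- paste(rhs, sprintf("strata(`%s`)", strataBy), sep = " + ")
    } else {
      dat$.strata <- as.factor(strataBy)
      strata_name <- ".strata"
      rhs <- paste(rhs, "strata(.strata)", sep = " + ")
    }
    ev <- tapply(dat$event, if (strata_name == ".strata") dat$.strata
                 else dat[[strata_name]], sum)
    if (any(ev == 0L)) stop("stratum with zero events")
  }
  fml <- stats::as.formula(paste("Surv(time, event) ~", rhs))
  fit <- withCallingHandlers(
    coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge",
                conditionMessage(w)))
        warning("possible non-convergence or complete separation: ",
                conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  cf <- s$coefficients
  tb <- data.frame(term = rownames(cf), coef = cf[, "coef"],
                   se = cf[, "se(coef)"], hr = exp(cf[, "coef"]),
                   lower = exp(cf[, "coef"] - 1.96 * cf[, "se(coef)"]),
                   upper = exp(cf[, "coef"] + 1.96 * cf[, "se(coef)"]),
                   p = cf[, "Pr(>|z|)"], row.names = NULL)
  new("CoxFit", table = tb, loglik = fit$loglik, n = as.integer(s$n),
      nevent = as.integer(s$nevent), terms = names(covariates),
      strata = strata_name, ties = ties, fit = fit)
}

#' Harrell's concordance index
#'
#' Probability that, of a pair of subjects comparable under censoring, the
#' one with the higher risk score experiences the event first. Tied risk
#' scores count 0.5; pairs rendered incomparable by censoring are excluded.
#'
#' @param records survival records.
#' @param risk numeric risk scores (higher = higher risk of an earlier
#'   event). For S3-type scores, where higher scores mean better prognosis,
#'   pass the negated score.
#' @return c-index in [0, 1].
#' @export
harrellC <- function(records, risk) {
  records <- .check_records(records)
  if (length(risk) != nrow(records)) stop("one risk score per record required")
  cc <- concordance(Surv(time, event) ~ risk, data = cbind(records, risk = risk),
                    reverse = TRUE)
  counts <- cc$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs")
  as.numeric(cc$concordance)
}

#' Analysis of deviance for nested Cox models
#'
#' Likelihood-ratio comparison: \code{chi2 = 2 (ll_full - ll_reduced)} on
#' degrees of freedom equal to the difference in parameter count.
#'
#' @param reduced,full \linkS4class{CoxFit} objects fitted to the same
#'   records with the same strata; the reduced model's covariates must be a
#'   subset of the full model's.
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
likelihoodRatioTest <- function(reduced, full) {
  stopifnot(is(reduced, "CoxFit"), is(full, "CoxFit"))
  if (!all(reduced@terms %in% full@terms))
    stop("models are not nested (reduced terms not a subset of full terms)")
  if (reduced@n != full@n || reduced@nevent != full@nevent)
    stop("models were fitted on different records")
  if (!identical(reduced@strata, full@strata))
    stop("models use different strata")
  df <- nrow(full@table) - nrow(reduced@table)
  chisq <- max(0, 2 * (full@loglik[2L] - reduced@loglik[2L]))
  if (df == 0L)   # identical parameter sets: no improvement possible
    return(list(chisq = chisq, df = 0L, p = 1))
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE))
}

## internal: log-rank scores (martingale residuals at the null):
## a_i = event_i - Nelson-Aalen cumulative hazard at time_i
.logrank_scores <- function(time, event) {
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]
  n <- length(t_s)
  ut <- unique(t_s)                       # ascending (t_s is sorted)
  grp <- match(t_s, ut)
  dN <- as.numeric(rowsum(e_s, grp))      # events at each unique time
  Y <- n - match(ut, t_s) + 1             # at risk just before each time
  H <- cumsum(dN / Y)                     # Nelson-Aalen
  a <- numeric(n)
  a[o] <- e_s - H[grp]
  a
}

## internal: standardized linear log-rank statistics for all "low-side" sizes
## m = 1..n-1 given scores a ordered by the split variable
.max_split_stats <- function(a_ordered) {
  n <- length(a_ordered)
  abar <- mean(a_ordered)
  s2 <- sum((a_ordered - abar)^2)
  m <- seq_len(n - 1L)
  S <- cumsum(a_ordered)[m]
  V <- m * (n - m) / (n * (n - 1)) * s2
  abs(S - m * abar) / sqrt(V)
}

#' Survival-based cut-off discovery
#'
#' Maximally selected log-rank cut-point search — a depth-1
#' conditional-inference split. Candidate splits are at observed score
#' values within a quantile range, respecting a minimum group size; the
#' split maximizing the absolute standardized two-group log-rank statistic
#' (linear log-rank-scores form with permutation variance) is selected, and
#' the selection-adjusted p-value is the fraction of score permutations
#' whose own maximal statistic reaches the observed maximum (add-one
#' estimator \code{(r + 1) / (B + 1)}). The reported threshold is the
#' midpoint between the two adjacent observed scores defining the split.
#'
#' @param scores numeric, non-constant, one per record.
#' @param records survival records.
#' @param quantileRange candidate quantile range (default \code{c(0.10,
#'   0.90)}).
#' @param minGroupSize minimum samples on each side of a split (default 10).
#' @param B number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return A \linkS4class{CutoffModel}.
#' @export
findCutoff <- function(scores, records, quantileRange = c(0.10, 0.90),
                       minGroupSize = 10L, B = 1000L, seed = 1L) {
  records <- .check_records(records)
  n <- nrow(records)
  if (length(scores) != n) stop("one score per record required")
  if (anyNA(scores)) stop("missing scores")
  if (max(scores) == min(scores)) stop("scores are constant")
  if (n < 2L * minGroupSize) stop("need n >= 2 * minGroupSize")
  a <- .logrank_scores(records$time, records$event)
  o <- order(scores)
  s_sorted <- scores[o]
  q <- quantile(scores, quantileRange)
  m <- seq_len(n - 1L)
  ## admissible split after position m: group sizes ok, distinct scores,
  ## split value inside the quantile range
  admissible <- m >= minGroupSize & (n - m) >= minGroupSize &
    s_sorted[m] < s_sorted[pmin(m + 1L, n)] &
    s_sorted[m] >= q[1L] & s_sorted[m] <= q[2L]
  if (!any(admissible)) stop("no admissible candidate cutpoint")
  stats <- .max_split_stats(a[o])
  stats[!admissible] <- -Inf
  k <- which.max(stats)
  observed <- stats[k]
  threshold <- (s_sorted[k] + s_sorted[k + 1L]) / 2
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(B)) {
    ap <- a[sample.int(n)]
    sb <- .max_split_stats(ap)
    if (max(sb[admissible]) >= observed - 1e-12) exceed <- exceed + 1L
  }
  p_adj <- (exceed + 1) / (B + 1)
  new("CutoffModel", threshold = threshold, statistic = observed,
      pAdjusted = p_adj, quantileRange = as.numeric(quantileRange),
      minGroupSize = as.integer(minGroupSize), permutations = as.integer(B),
      seed = as.integer(seed))
}

#' Recode clinical covariates for multivariate Cox modelling
#'
#' Applies the grade and metastasis-status handling used for multivariate
#' models of this kind: grades \code{"2-3"} (also accepted as \code{"2–3"})
#' and \code{"4"} are merged into \code{"3"}; records with missing/"X" grade
#' or metastasis status \code{"X"} are excluded and listed. T, N, M and G
#' are expanded to reference-coded indicator columns with reference levels
#' T1 / N0 / M0 / G1.
#'
#' @param clinical data.frame with columns \code{sample_id}, \code{T},
#'   \code{N}, \code{M}, \code{G} (character/factor levels as in a TNM
#'   table: T 1-4, N 0/1/2/X, M 0/1/X, G 1/2/2-3/3/4/X or missing).
#' @return list with \code{data} (sample_id plus 0/1 indicator columns
#'   T2..T4, N1, N2, NX, M1, G2, G3) and \code{excluded} (sample_id,
#'   reason).
#' @export
recodeCovariates <- function(clinical) {
  stopifnot(all(c("sample_id", "T", "N", "M", "G") %in% names(clinical)))
  cl <- clinical
  for (col in c("T", "N", "M", "G")) cl[[col]] <- trimws(as.character(cl[[col]]))
  G <- cl$G
  G[G %in% c("2-3", "2–3", "G2-3", "G2–3")] <- "3"
  G[G %in% c("4", "G4")] <- "3"
  G <- sub("^G", "", G)
  bad_g <- is.na(G) | G %in% c("", "X", "NA")
  bad_m <- cl$M %in% c("X", "MX")
  excl <- bad_g | bad_m
  reason <- ifelse(bad_m & bad_g, "MX;missing_grade",
                   ifelse(bad_m, "MX", "missing_grade"))
  excluded <- data.frame(sample_id = cl$sample_id[excl],
                         reason = reason[excl], row.names = NULL)
  keep <- cl[!excl, , drop = FALSE]
  G <- G[!excl]
  ind <- function(x, lev) as.integer(x == lev)
  Tn <- sub("^T", "", keep$T); Nn <- sub("^N", "", keep$N)
  Mn <- sub("^M", "", keep$M)
  data <- data.frame(
    sample_id = keep$sample_id,
    T2 = ind(Tn, "2"), T3 = ind(Tn, "3"), T4 = ind(Tn, "4"),
    N1 = ind(Nn, "1"), N2 = ind(Nn, "2"), NX = ind(Nn, "X"),
    M1 = ind(Mn, "1"),
    G2 = ind(G, "2"), G3 = ind(G, "3"),
    row.names = NULL)
  list(data = data, excluded = excluded)
}
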