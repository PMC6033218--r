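## small in-code fixture builders shared across test files

em <- function(values, platform = "rnaseq_log",
               genes = sprintf("g%d", seq_len(nrow(values))),
               samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  ExpressionMatrix(values, platform)
}

## reference profiles with given origin column appended to random others
refs_from <- function(origin_profile, n_other = 3L, seed = 42L,
                      origin = "proximal_S3") {
  set.seed(seed)
  g <- length(origin_profile)
  v <- cbind(matrix(rnorm(g * n_other, 8, 1), g), origin_profile)
  dimnames(v) <- list(names(origin_profile),
                      c(paste0("region", seq_len(n_other)), origin))
  ReferenceProfiles(v, originRegion = origin)
}

recs <- function(time, event, id = sprintf("p%d", seq_along(time))) {
  survivalRecords(sample_id = id, time = time, event = event)
}

## Efron partial log-likelihood for a single binary/numeric covariate,
## independent of survival::coxph (used as grid-search oracle)
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    eta <- exp(beta * x)
    sR <- sum(eta[R]); sD <- sum(eta[D])
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sR - l / d * sD)
  }
  ll
}
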