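NEPHRON_REGIONS <- c("glomerulus", "proximal_S1", "proximal_S2",
                     "proximal_S3", "loop_of_Henle", "distal_tubule",
                     "connecting_tubule", "collecting_duct")

#' Configuration for the synthetic ccRCC cohort generator
#'
#' Every pipeline input can be generated from one seeded configuration:
#' nephron-region reference profiles, tumors whose expression is a noisy
#' convex mixture of the cell-of-origin profile and a background mixture of
#' the other regions, survival with hazard decreasing in the latent
#' similarity, a qRT-PCR re-measurement with affine Ct transformation and
#' sporadic assay failures, and matched metastases as small perturbations
#' of their primaries.
#'
#' @param n_genes total genes; @param n_signature signature genes (first
#'   \code{n_signature} gene ids).
#' @param n_regions number of nephron regions (default 8).
#' @param origin_region index of the cell-of-origin region (default 4,
#'   the proximal tubule S3 segment).
#' @param n_samples cohort size.
#' @param purity_shape1,purity_shape2 Beta parameters of the latent
#'   cell-of-origin similarity w (default Beta(5, 2): skewed high, tumors
#'   largely resembling their cell of origin).
#' @param noise_sd expression noise sd, log2 units (default 0.3).
#' @param base_mean,base_sd per-gene baseline expression distribution,
#'   log2 units (defaults 8, 1.2).
#' @param region_sd sd of gene-by-region effects, log2 units (default 1.2).
#' @param signature_informative optional count of signature genes carrying
#'   the region contrast; the remaining signature genes get their region
#'   effects shrunk by \code{noninformative_shrink}, concentrating the
#'   between-sample signature variance in the informative set.
#' @param informative_contrast multiplier on region effects of informative
#'   genes when \code{signature_informative} is set (default 8).
#' @param noninformative_shrink shrink factor for the rest (default 0.1).
#' @param h0 baseline hazard per year (default 0.2); @param beta hazard
#'   effect: rate = \code{h0 * exp(-beta * w)} (default 2, protective
#'   similarity); @param censor_horizon uniform censoring horizon in years
#'   (default 10).
#' @param qpcr_intercept,qpcr_slope affine map Ct = intercept - slope *
#'   expr (defaults 30, 1); @param ct_noise_sd Ct technical noise sd
#'   (default 0.15); @param failure_rate per-well sporadic assay failure
#'   probability (default 0.003).
#' @param n_norm_genes normalization genes added by \code{\link{toQpcr}}
#'   (default 5); @param norm_gene_sd their Ct sd (default 0.05).
#' @param met_sd metastasis per-gene perturbation sd (default 0.1).
#' @param bg_alpha Dirichlet concentration of the per-sample background
#'   mixture over non-origin regions (default 0.3: backgrounds dominated by
#'   one or two contaminating regions, as in real tumor stroma).
#' @param seed mandatory integer seed; every generator operation derives
#'   its stream deterministically from it.
#' @return a validated \code{GeneratorConfig} list.
#' @export
generatorConfig <- function(n_genes = 300L, n_signature = 97L,
                            n_regions = 8L, origin_region = 4L,
                            n_samples = 200L,
                            purity_shape1 = 5, purity_shape2 = 2,
                            noise_sd = 0.3, base_mean = 8, base_sd = 1.2,
                            region_sd = 1.2,
                            signature_informative = NULL,
                            informative_contrast = 8,
                            noninformative_shrink = 0.1,
                            h0 = 0.2, beta = 2, censor_horizon = 10,
                            qpcr_intercept = 30, qpcr_slope = 1,
                            ct_noise_sd = 0.15, failure_rate = 0.003,
                            n_norm_genes = 5L, norm_gene_sd = 0.05,
                            met_sd = 0.1, bg_alpha = 0.3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd >= 0, ct_noise_sd >= 0, norm_gene_sd >= 0, met_sd >= 0,
            failure_rate >= 0, failure_rate < 1,
            n_signature <= n_genes, origin_region <= n_regions)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$region_labels <- if (n_regions == 8L) NEPHRON_REGIONS
                       else paste0("region", seq_len(n_regions))
  cfg$gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  cfg$signature_genes <- cfg$gene_ids[seq_len(n_signature)]
  cfg$norm_gene_ids <- sprintf("NORM%02d", seq_len(n_norm_genes))
  class(cfg) <- "GeneratorConfig"
  cfg
}

## deterministic per-operation RNG streams derived from the master seed
.gen_seed <- function(cfg, offset) {
  set.seed((cfg$seed %% 1000000L) * 1000L + offset)
}

#' Generate nephron-region reference profiles
#'
#' Each gene gets a baseline expression plus independent region effects,
#' giving region-specific mean structure with pairwise inter-region
#' correlations below 0.8 over the signature genes. Deterministic given the
#' configuration seed.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @return A \linkS4class{ReferenceProfiles}.
#' @export
makeReferenceProfiles <- function(cfg) {
  .gen_seed(cfg, 1L)
  G <- cfg$n_genes; R <- cfg$n_regions
  base <- rnorm(G, cfg$base_mean, cfg$base_sd)
  delta <- matrix(rnorm(G * R, 0, cfg$region_sd), G, R)
  if (!is.null(cfg$signature_informative)) {
    k <- cfg$signature_informative
    stopifnot(k <= cfg$n_signature)
    scale <- rep(1, G)
    scale[seq_len(cfg$n_signature)] <- cfg$noninformative_shrink
    scale[seq_len(k)] <- cfg$informative_contrast
    delta <- delta * scale
  }
  v <- base + delta
  dimnames(v) <- list(cfg$gene_ids, cfg$region_labels)
  ReferenceProfiles(v, originRegion = cfg$region_labels[cfg$origin_region])
}

#' Simulate a tumor cohort with latent cell-of-origin similarity
#'
#' Per sample s with latent purity \code{w_s ~ Beta(a, b)}:
#' \deqn{expr(g, s) = w_s ref(g, origin) + (1 - w_s) bg(g, s) + e}
#' with \code{e ~ N(0, noise_sd)} and the background \code{bg} a random
#' convex (Dirichlet) mixture of the non-origin region profiles, so all
#' region correlations stay informative, as in real tumors. The latent
#' similarity \code{w} is returned as ground truth.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param refs profiles from \code{\link{makeReferenceProfiles}}.
#' @param n_samples optional override of \code{cfg$n_samples}.
#' @param stream integer sub-stream selector so several cohorts can be
#'   drawn from one configuration (default 0).
#' @return list with \code{expr} (\linkS4class{ExpressionMatrix},
#'   \code{rnaseq_log}) and \code{purity} (named numeric, ground truth w).
#' @export
simulateTumors <- function(cfg, refs, n_samples = cfg$n_samples, stream = 0L) {
  .gen_seed(cfg, 11L + 7L * as.integer(stream))
  v <- exprValues(refs)
  n <- n_samples
  org <- originRegion(refs)
  others <- setdiff(regionLabels(refs), org)
  w <- rbeta(n, cfg$purity_shape1, cfg$purity_shape2)
  mix <- matrix(rgamma(n * length(others), shape = cfg$bg_alpha), n)
  mix <- mix / rowSums(mix)
  bg <- v[, others, drop = FALSE] %*% t(mix)     # genes x samples
  expr <- outer(v[, org], w) + sweep(bg, 2L, 1 - w, "*") +
    matrix(rnorm(nrow(v) * n, 0, cfg$noise_sd), nrow(v))
  ids <- sprintf("S%s%03d", if (stream == 0L) "" else paste0(stream, "_"),
                 seq_len(n))
  dimnames(expr) <- list(rownames(v), ids)
  names(w) <- ids
  list(expr = ExpressionMatrix(expr, "rnaseq_log"), purity = w)
}

#' Simulate survival outcomes from latent similarity
#'
#' Event times are exponential with rate \code{h0 * exp(-beta * w)} (hazard
#' decreasing in the similarity w for beta > 0); censoring times are
#' uniform on (0, censor_horizon); the observed time is the minimum and the
#' event indicator marks whether the event came first.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param w named numeric latent similarities in [0, 1].
#' @param endpoint endpoint label (default \code{"CSS"}).
#' @param stream sub-stream selector (default 0).
#' @return survival records data.frame (see \code{\link{survivalRecords}}).
#' @export
simulateSurvival <- function(cfg, w, endpoint = "CSS", stream = 0L) {
  stopifnot(all(w >= 0 & w <= 1))
  .gen_seed(cfg, 101L + 7L * as.integer(stream))
  n <- length(w)
  tt <- rexp(n, rate = cfg$h0 * exp(-cfg$beta * w))
  cc <- runif(n, 0, cfg$censor_horizon)
  survivalRecords(sample_id = names(w), time = pmin(tt, cc),
                  event = as.integer(tt <= cc), endpoint = endpoint)
}

#' qRT-PCR re-measurement of an expression matrix
#'
#' Maps log2 expression to threshold cycles, \code{Ct = intercept - slope *
#' expr + noise}, clamps to the plausible [0, 45] Ct range, plants sporadic
#' assay failures (missing wells) at the configured rate, and appends
#' low-variance normalization ("housekeeping") genes.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param m an \linkS4class{ExpressionMatrix} on the log2 scale.
#' @param genes genes to measure (default: the configured signature genes).
#' @param stream sub-stream selector (default 0).
#' @return list with \code{ct} (\linkS4class{ExpressionMatrix},
#'   \code{qpcr_ct}) and \code{panel} (a \linkS4class{GenePanel} naming the
#'   measured signature and normalization genes).
#' @export
toQpcr <- function(cfg, m, genes = cfg$signature_genes, stream = 0L) {
  stopifnot(all(genes %in% geneIds(m)))
  .gen_seed(cfg, 201L + 7L * as.integer(stream))
  v <- exprValues(m)[genes, , drop = FALSE]
  n <- ncol(v)
  ct <- cfg$qpcr_intercept - cfg$qpcr_slope * v +
    matrix(rnorm(length(v), 0, cfg$ct_noise_sd), nrow(v))
  fail <- matrix(runif(length(ct)) < cfg$failure_rate, nrow(ct))
  ct[fail] <- NA_real_
  norm_base <- rnorm(cfg$n_norm_genes, cfg$qpcr_intercept - cfg$base_mean, 0.5)
  nv <- matrix(rep(norm_base, n), cfg$n_norm_genes) +
    matrix(rnorm(cfg$n_norm_genes * n, 0, cfg$norm_gene_sd),
           cfg$n_norm_genes)
  out <- rbind(ct, nv)
  out <- pmin(pmax(out, 0), 45)
  dimnames(out) <- list(c(genes, cfg$norm_gene_ids), colnames(v))
  list(ct = ExpressionMatrix(out, "qpcr_ct"),
       panel = GenePanel(signatureGenes = genes,
                         normalizationGenes = cfg$norm_gene_ids))
}

#' Generate matched metastasis profiles
#'
#' Each requested metastasis (or metastasis region) is its primary tumor's
#' profile plus independent per-gene Gaussian perturbations of sd
#' \code{met_sd}; multi-region metastases replicate a primary with
#' independent perturbations.
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param tumors an \linkS4class{ExpressionMatrix} of primary tumors.
#' @param patients sample ids of the primaries to metastasize.
#' @param regions integer vector (recycled over \code{patients}): number of
#'   metastasis samples per patient (default 1; use e.g. 4 for a
#'   multi-region metastasis).
#' @param stream sub-stream selector (default 0).
#' @return list with \code{expr} (metastasis \linkS4class{ExpressionMatrix},
#'   same platform as the primaries) and \code{roles} (data.frame:
#'   sample_id, patient_id, role).
#' @export
makeMetastases <- function(cfg, tumors, patients, regions = 1L, stream = 0L) {
  stopifnot(all(patients %in% sampleIds(tumors)))
  .gen_seed(cfg, 301L + 7L * as.integer(stream))
  regions <- rep_len(as.integer(regions), length(patients))
  v <- exprValues(tumors)
  cols <- list(); roles <- list()
  for (i in seq_along(patients)) {
    p <- patients[i]
    for (r in seq_len(regions[i])) {
      met <- v[, p] + rnorm(nrow(v), 0, cfg$met_sd)
      id <- if (regions[i] > 1L) sprintf("%s_met_r%d", p, r)
            else sprintf("%s_met", p)
      cols[[id]] <- met
      roles[[id]] <- data.frame(sample_id = id, patient_id = p,
                                role = if (regions[i] > 1L)
                                  "metastasis_region" else "metastasis")
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(v)
  list(expr = ExpressionMatrix(out, platform(tumors)),
       roles = do.call(rbind, c(roles, list(make.row.names = FALSE))))
}

#' Write a complete synthetic fixture set to a directory
#'
#' Generates reference profiles, a tumor cohort, survival records, a qRT-PCR
#' re-measurement and matched metastases, and writes them as plain-text
#' files (expression TSVs, clinical CSV, panel JSON, ground-truth JSON).
#'
#' @param cfg a \code{\link{generatorConfig}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulateCohort <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- makeReferenceProfiles(cfg)
  tum <- simulateTumors(cfg, refs)
  surv <- simulateSurvival(cfg, tum$purity)
  qp <- toQpcr(cfg, tum$expr)
  mets <- makeMetastases(cfg, tum$expr,
                         patients = sampleIds(tum$expr)[seq_len(min(5L,
                           ncol(tum$expr)))])
  writeReferenceProfiles(refs, file.path(dir, "reference_profiles.tsv"))
  writeExpressionTable(tum$expr, file.path(dir, "tumors_rnaseq.tsv"))
  writeExpressionTable(qp$ct, file.path(dir, "tumors_qpcr_ct.tsv"))
  writeExpressionTable(mets$expr, file.path(dir, "metastases_rnaseq.tsv"))
  writeGenePanel(qp$panel, file.path(dir, "gene_panel.json"))
  utils::write.csv(
    data.frame(sample_id = surv$sample_id, time_years = surv$time,
               event = surv$event, endpoint = surv$endpoint),
    file.path(dir, "clinical.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(purity = as.list(tum$purity), seed = cfg$seed,
                            beta = cfg$beta, h0 = cfg$h0,
                            met_sd = cfg$met_sd),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(refs = refs, tumors = tum, survival = surv, qpcr = qp,
                 metastases = mets))
}
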