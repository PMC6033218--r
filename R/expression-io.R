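MISSING_TOKENS <- c("", "NA", "NaN", "na", "nan", "Na", "NAN")

#' Read a gene-by-sample expression table
#'
#' Reads a delimited text table whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Unparseable cells and the
#' tokens \code{""}, \code{"NA"}, \code{"NaN"} (case-insensitive) become
#' explicit missing values.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param platform platform tag recorded on the result.
#' @param sep field separator; \code{"\t"} by default, \code{","} accepted.
#' @param transpose if \code{TRUE} the file is sample-by-gene and is
#'   transposed on read (internal orientation is always genes-in-rows).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionTable <- function(path, platform = "rnaseq_log", sep = "\t",
                                transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs a gene column plus >=1 sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[trimws(raw) %in% MISSING_TOKENS] <- NA_character_
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(ids, samples)))
  if (transpose) vals <- t(vals)
  ExpressionMatrix(vals, platform = platform)
}

#' Write an expression matrix as a delimited table
#'
#' Inverse of \code{\link{readExpressionTable}}: first column \code{gene_id},
#' header row sample identifiers, missing values written as \code{NA}.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(x, path, sep = "\t") {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(gene_id = geneIds(x), exprValues(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Delta-Ct normalization of qRT-PCR data
#'
#' Converts raw Ct values to log2-scale relative expression against the mean
#' of the panel's normalization ("housekeeping") genes:
#' \deqn{expr(g, s) = mean_{h}(Ct(h, s)) - Ct(g, s)}
#' so that higher values mean more expressed. The mean of Ct values equals
#' the log-scale geometric mean of the linear quantities — the standard
#' delta-Ct convention. Normalization genes are dropped from the output;
#' missing Ct values stay missing.
#'
#' @param ct an \linkS4class{ExpressionMatrix} with platform \code{"qpcr_ct"}.
#' @param panel a \linkS4class{GenePanel}; all normalization genes must be
#'   present in \code{ct} with no missing values.
#' @return An \linkS4class{ExpressionMatrix} with platform \code{"qpcr_norm"}.
#' @export
normalizeQpcr <- function(ct, panel) {
  stopifnot(is(ct, "ExpressionMatrix"), is(panel, "GenePanel"))
  if (platform(ct) != "qpcr_ct")
    stop("normalizeQpcr expects platform 'qpcr_ct', got '", platform(ct), "'")
  norm <- normalizationGenes(panel)
  if (!length(norm)) stop("panel has no normalization genes")
  absent <- setdiff(norm, geneIds(ct))
  if (length(absent))
    stop("normalization genes absent: ", paste(absent, collapse = ", "))
  v <- exprValues(ct)
  nv <- v[norm, , drop = FALSE]
  if (anyNA(nv)) {
    bad <- norm[rowSums(is.na(nv)) > 0]
    stop("normalization genes with missing Ct: ", paste(bad, collapse = ", "))
  }
  ref <- colMeans(nv)
  keep <- setdiff(geneIds(ct), norm)
  out <- sweep(-v[keep, , drop = FALSE], 2L, ref, FUN = "+")
  ExpressionMatrix(out, platform = "qpcr_norm")
}

#' Log2 transform of non-negative expression values
#'
#' @param raw an \linkS4class{ExpressionMatrix} of non-negative values
#'   (e.g. normalized RNA-seq counts).
#' @param pseudocount positive offset added before taking log2; default 1.
#' @return An \linkS4class{ExpressionMatrix} with platform
#'   \code{"rnaseq_log"}.
#' @export
logTransformCounts <- function(raw, pseudocount = 1) {
  stopifnot(is(raw, "ExpressionMatrix"), pseudocount > 0)
  v <- exprValues(raw)
  if (any(v < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  ExpressionMatrix(log2(v + pseudocount), platform = "rnaseq_log")
}

#' Subset and order a matrix to a gene list
#'
#' @param m an \linkS4class{ExpressionMatrix}.
#' @param genes identifier vector; the result's rows follow this order.
#' @return An \linkS4class{ExpressionMatrix} restricted to \code{genes}.
#' @export
alignGenes <- function(m, genes) {
  stopifnot(is(m, "ExpressionMatrix"))
  absent <- setdiff(genes, geneIds(m))
  if (length(absent))
    stop("genes absent from matrix: ", paste(absent, collapse = ", "))
  ExpressionMatrix(exprValues(m)[genes, , drop = FALSE], platform = platform(m))
}

#' Read / write a gene panel as JSON
#'
#' Format: \code{{"signature_genes": [...], "normalization_genes": [...]}}.
#'
#' @param path JSON file path.
#' @return \code{readGenePanel}: a \linkS4class{GenePanel}.
#' @export
readGenePanel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  GenePanel(signatureGenes = j$signature_genes,
            normalizationGenes = if (is.null(j$normalization_genes))
              character(0) else j$normalization_genes)
}

#' @rdname readGenePanel
#' @param panel a \linkS4class{GenePanel} to serialize.
#' @export
writeGenePanel <- function(panel, path) {
  jsonlite::write_json(list(signature_genes = signatureGenes(panel),
                            normalization_genes = normalizationGenes(panel)),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read / write nephron-region reference profiles
#'
#' The profile matrix is a gene-by-region TSV; a sidecar JSON
#' (\code{<path>.json}) names the designated cell-of-origin region.
#'
#' @param path TSV path; the sidecar is \code{paste0(path, ".json")}.
#' @return \code{readReferenceProfiles}: a \linkS4class{ReferenceProfiles}.
#' @export
readReferenceProfiles <- function(path) {
  m <- readExpressionTable(path, platform = "rnaseq_log")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ReferenceProfiles(exprValues(m), originRegion = side$origin_region)
}

#' @rdname readReferenceProfiles
#' @param refs a \linkS4class{ReferenceProfiles} to serialize.
#' @export
writeReferenceProfiles <- function(refs, path) {
  writeExpressionTable(ExpressionMatrix(exprValues(refs)), path)
  jsonlite::write_json(list(origin_region = originRegion(refs)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expected CSV columns: \code{sample_id, time_years, event, endpoint, T, N,
#' M, G, necrosis, size_cm}. Time must be positive and events coded 0/1.
#'
#' @param path CSV file path.
#' @return data.frame with one row per sample.
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$time_years <- as.numeric(df$time_years)
  df$event <- as.integer(df$event)
  if (any(!is.finite(df$time_years)) || any(df$time_years <= 0))
    stop("time_years must be positive")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if ("size_cm" %in% names(df))
    df$size_cm <- suppressWarnings(as.numeric(df$size_cm))
  df
}

#' Serialize / deserialize a LinearScoreModel as JSON
#'
#' Format: \code{{"intercept": x, "coefficients": {gene: w}, "method": tag,
#' "r2": x, "normalization_genes": [...]}}. Numbers round-trip exactly.
#'
#' @param path JSON file path.
#' @return \code{readLinearScoreModel}: a \linkS4class{LinearScoreModel}.
#' @export
readLinearScoreModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  LinearScoreModel(intercept = j$intercept,
                   coefficients = unlist(j$coefficients),
                   method = j$method, r2 = j$r2,
                   normalizationGenes = if (is.null(j$normalization_genes))
                     character(0) else j$normalization_genes)
}

#' @rdname readLinearScoreModel
#' @param model a \linkS4class{LinearScoreModel}.
#' @export
writeLinearScoreModel <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model@intercept,
         coefficients = as.list(model@coefficients),
         method = model@method, r2 = model@r2,
         normalization_genes = model@normalizationGenes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an S3ScoreResult as TSV plus JSON metadata
#'
#' @param x an \linkS4class{S3ScoreResult}.
#' @param path output TSV path (one row per sample: id, per-region
#'   correlations, score); metadata goes to \code{<path>.json}.
#' @export
writeS3ScoreResult <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x), x@correlations,
                   score = x@score, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = x@method, aggregation = x@aggregation),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
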