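#' Default SSIGN point table
#'
#' Stage, Size, Grade and Necrosis point assignments following the published
#' Mayo table as validated by Zigeuner and colleagues: pT1 = 0, pT2 = 1,
#' pT3-pT4 = 2; pN0 = 0, pN1-pN2 = 2; pM0 = 0, pM1 = 4; size < 5 cm = 0,
#' >= 5 cm = 2; grade 1-2 = 0, grade 3 = 1, grade 4 = 3; necrosis absent = 0,
#' present = 1. Risk bins default to 0-2 (low), 3-5 (intermediate), >= 6
#' (high). Shipped as editable JSON in
#' \code{system.file("extdata", "ssign_default.json", package = "S3score")};
#' this function reads it.
#'
#' @return SSIGN table as a nested list (see the JSON for the schema).
#' @export
defaultSsignTable <- function() {
  readSsignTable(system.file("extdata", "ssign_default.json",
                             package = "S3score"))
}

#' @rdname defaultSsignTable
#' @param path path to an SSIGN table JSON.
#' @export
readSsignTable <- function(path) {
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("T", "N", "M", "G", "necrosis"))
    if (any(unlist(tab[[f]]) < 0)) stop("SSIGN points must be >= 0")
  tab
}

#' SSIGN clinicopathological score
#'
#' Sums the point contributions of T category, N category, M category,
#' tumor size (threshold in cm), grade and necrosis, then assigns a risk
#' stratum by the table's score bins.
#'
#' @param clinical data.frame (or single-row list) with columns \code{T},
#'   \code{N}, \code{M}, \code{G}, \code{necrosis} (\code{"present"}/
#'   \code{"absent"}) and \code{size_cm}; all must be present and not
#'   \code{"X"}.
#' @param table SSIGN point table; default \code{\link{defaultSsignTable}}.
#' @return data.frame with \code{sample_id} (when present), \code{score}
#'   (integer) and \code{stratum}.
#' @export
ssignScore <- function(clinical, table = defaultSsignTable()) {
  cl <- as.data.frame(clinical, stringsAsFactors = FALSE)
  need <- c("T", "N", "M", "G", "necrosis", "size_cm")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("missing features: ", paste(miss, collapse = ", "))
  lookup <- function(map, x, what) {
    x <- trimws(as.character(x))
    x <- sub(sprintf("^%s", what), "", x)   # accept "T1" and "1" alike
    bad <- is.na(x) | x == "X" | x == "" | !(x %in% names(map))
    if (any(bad))
      stop("missing or unscoreable ", what, " for record(s) ",
           paste(which(bad), collapse = ", "))
    unlist(map)[x]
  }
  pts <- lookup(table$T, cl$T, "T") + lookup(table$N, cl$N, "N") +
    lookup(table$M, cl$M, "M") + lookup(table$G, cl$G, "G")
  nec <- trimws(as.character(cl$necrosis))
  if (any(!nec %in% names(table$necrosis)))
    stop("necrosis must be one of: ", paste(names(table$necrosis),
                                            collapse = ", "))
  pts <- pts + unlist(table$necrosis)[nec]
  if (any(is.na(cl$size_cm) | cl$size_cm < 0)) stop("size_cm missing or negative")
  pts <- pts + ifelse(cl$size_cm >= table$size$threshold_cm,
                      table$size$at_or_above, table$size$below)
  bins <- table$bins
  stratum <- vapply(pts, function(s) {
    for (nm in names(bins)) {
      b <- unlist(bins[[nm]])
      if (s >= b[1L] && s <= b[2L]) return(nm)
    }
    NA_character_
  }, character(1))
  out <- data.frame(score = as.integer(pts), stratum = stratum,
                    row.names = NULL)
  if ("sample_id" %in% names(cl)) out <- cbind(sample_id = cl$sample_id, out)
  out
}

#' Read a centroid model (ClearCode34-style classifier)
#'
#' JSON schema: \code{{"genes": [...], "centroids": {"ccA": {gene: value},
#' "ccB": {...}}, "method": "pearson", "provenance": "..."}}.
#'
#' @param path JSON path.
#' @return centroid model list with \code{genes}, \code{centroids}
#'   (gene x class matrix), \code{labels}, \code{method}.
#' @export
readCentroidModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- names(j$centroids)
  cm <- vapply(labels, function(l) unlist(j$centroids[[l]])[j$genes],
               numeric(length(j$genes)))
  rownames(cm) <- j$genes
  centroidModel(cm, method = if (is.null(j$method)) "pearson" else j$method)
}

#' @rdname readCentroidModel
#' @param centroids gene x class numeric matrix (two columns) with dimnames.
#' @param method correlation method used for assignment.
#' @export
centroidModel <- function(centroids, method = "pearson") {
  stopifnot(is.matrix(centroids), ncol(centroids) == 2L,
            !is.null(rownames(centroids)), !is.null(colnames(centroids)),
            !anyNA(centroids))
  list(genes = rownames(centroids), centroids = centroids,
       labels = colnames(centroids), method = method)
}

#' Nearest-centroid molecular subtype classification
#'
#' Per sample, computes the correlation to each class centroid over the
#' model genes and assigns the class with the larger correlation;
#' confidence is the correlation difference. An exact tie (to machine
#' precision) yields \code{"unclassified"}.
#'
#' @param m an \linkS4class{ExpressionMatrix} carrying all centroid genes.
#' @param model a centroid model (see \code{\link{centroidModel}}).
#' @return data.frame: sample_id, correlation per class, class, confidence.
#' @export
centroidClassify <- function(m, model) {
  stopifnot(is(m, "ExpressionMatrix"))
  absent <- setdiff(model$genes, geneIds(m))
  if (length(absent))
    stop("centroid genes absent: ", paste(absent, collapse = ", "))
  v <- exprValues(m)[model$genes, , drop = FALSE]
  cc <- cor(v, model$centroids, method = model$method,
            use = "pairwise.complete.obs")
  d <- cc[, 1L] - cc[, 2L]
  class <- ifelse(abs(d) <= .Machine$double.eps * 4, "unclassified",
                  ifelse(d > 0, model$labels[1L], model$labels[2L]))
  out <- data.frame(sample_id = sampleIds(m), cc, class = class,
                    confidence = abs(d), row.names = NULL,
                    check.names = FALSE)
  names(out)[2:3] <- model$labels
  out
}

#' Primary/metastasis score and class concordance
#'
#' Groups scored, classified samples by patient; a patient is concordant
#' iff all of their samples (primary, metastases, metastasis regions) share
#' one class. Patients contributing a single sample are skipped and
#' reported.
#'
#' @param samples data.frame with columns \code{patient_id},
#'   \code{sample_id}, \code{role} (e.g. \code{"primary"},
#'   \code{"metastasis"}, \code{"metastasis_region"}), \code{score},
#'   \code{class}.
#' @return list with \code{pairs} (per-patient data.frame: patient_id,
#'   n_samples, classes, concordant, score_range), \code{summary}
#'   (n_patients, n_concordant, concordance fraction) and \code{skipped}
#'   (single-sample patients).
#' @export
concordanceAnalysis <- function(samples) {
  need <- c("patient_id", "sample_id", "role", "score", "class")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sp <- split(samples, samples$patient_id)
  single <- vapply(sp, nrow, integer(1)) < 2L
  skipped <- data.frame(patient_id = names(sp)[single],
                        reason = rep("single sample", sum(single)),
                        row.names = NULL)
  sp <- sp[!single]
  pairs <- do.call(rbind, lapply(sp, function(d) {
    data.frame(patient_id = d$patient_id[1L], n_samples = nrow(d),
               classes = paste(sort(unique(d$class)), collapse = ";"),
               concordant = length(unique(d$class)) == 1L,
               score_range = max(d$score) - min(d$score), row.names = NULL)
  }))
  if (is.null(pairs))
    pairs <- data.frame(patient_id = character(0), n_samples = integer(0),
                        classes = character(0), concordant = logical(0),
                        score_range = numeric(0))
  list(pairs = pairs,
       summary = list(n_patients = nrow(pairs),
                      n_concordant = sum(pairs$concordant),
                      fraction = if (nrow(pairs)) mean(pairs$concordant)
                                 else NA_real_),
       skipped = skipped)
}
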