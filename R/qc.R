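#' Sample-level quality filtering
#'
#' Retains samples meeting all four standard CNV-analysis QC thresholds:
#' high SNP call rate, low standard deviation of normalised intensity, low
#' absolute genomic wave factor (GCWF) and a bounded number of CNV calls.
#' All thresholds are applied inclusively, matching their printed operators
#' (call rate >= 0.95, s.d. <= 0.3, |GCWF| <= 0.02, #CNVs <= 100).
#'
#' @param samples Sample data.frame (see [read_samples()]).
#' @param thresholds Numeric vector `c(call_rate, lrr_sd, gcwf, n_cnv)`;
#'   defaults `c(0.95, 0.3, 0.02, 100)`.
#' @return A list with `kept` (passing samples) and `excluded` (failing
#'   samples with a `reasons` column listing every violated criterion).
#' @examples
#' s <- data.frame(sample_id = c("a", "b"), cohort = "case",
#'                 call_rate = c(0.99, 0.90), lrr_sd = 0.1, gcwf = 0,
#'                 n_cnv = 5L, quality_score = 1)
#' filter_samples(s)$excluded$reasons
#' @export
filter_samples <- function(samples, thresholds = c(call_rate = 0.95,
                                                   lrr_sd = 0.3,
                                                   gcwf = 0.02,
                                                   n_cnv = 100)) {
  metrics <- c("call_rate", "lrr_sd", "gcwf", "n_cnv")
  check_columns(samples, c("sample_id", metrics), "sample table")
  check_that(length(thresholds) == 4L, "thresholds must have 4 elements")
  thresholds <- stats::setNames(as.numeric(thresholds), metrics)
  for (m in metrics) {
    bad <- which(is.na(samples[[m]]))
    if (length(bad)) {
      stop(sprintf("sample '%s' has missing QC metric '%s'",
                   samples$sample_id[bad[1L]], m), call. = FALSE)
    }
  }
  viol <- cbind(
    call_rate = samples$call_rate < thresholds["call_rate"],
    lrr_sd = samples$lrr_sd > thresholds["lrr_sd"],
    gcwf = abs(samples$gcwf) > thresholds["gcwf"],
    n_cnv = samples$n_cnv > thresholds["n_cnv"])
  fails <- rowSums(viol) > 0
  excluded <- samples[fails, , drop = FALSE]
  excluded$reasons <- apply(viol[fails, , drop = FALSE], 1L, function(v) {
    paste(metrics[v], collapse = ",")
  })
  rownames(excluded) <- NULL
  kept <- samples[!fails, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Remove duplicate samples by IBS single-linkage clustering
#'
#' Builds the graph on all sample pairs with identity-by-state at or above
#' `ibs_threshold` (inclusive), takes its connected components — single
#' linkage — and retains, from each component, the sample with the highest
#' `quality_score` (ties broken by lexicographically smallest `sample_id`).
#' Samples in no high-IBS pair are always retained. Pairs naming samples
#' absent from `samples` are ignored, which makes the operation idempotent.
#'
#' @param samples Sample data.frame with a `quality_score` column.
#' @param pairs IBS pair data.frame (`id_a, id_b, ibs`).
#' @param ibs_threshold Similarity at or above which two samples are
#'   considered duplicates; default 0.9.
#' @return A list with `kept` (unique samples) and `removed` (character
#'   vector of discarded sample ids).
#' @export
dedupe_samples <- function(samples, pairs, ibs_threshold = 0.9) {
  check_columns(samples, c("sample_id", "quality_score"), "sample table")
  check_columns(pairs, c("id_a", "id_b", "ibs"), "IBS pair table")
  hi <- pairs[pairs$ibs >= ibs_threshold &
                pairs$id_a %in% samples$sample_id &
                pairs$id_b %in% samples$sample_id, , drop = FALSE]
  if (nrow(hi) == 0L) {
    return(list(kept = samples, removed = character(0)))
  }
  g <- igraph::graph_from_data_frame(hi[, c("id_a", "id_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  q <- stats::setNames(samples$quality_score, samples$sample_id)
  removed <- unlist(lapply(seq_len(comp$no), function(k) {
    ids <- sort(names(membership)[membership == k])
    best <- ids[order(-q[ids], ids)][1L]
    setdiff(ids, best)
  }), use.names = FALSE)
  kept <- samples[!(samples$sample_id %in% removed), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Supervised nearest-centroid ancestry classification
#'
#' Assigns continental ancestry from the first D principal-component
#' eigenvectors, in the supervised k-means setting: with training labels
#' fixed, the class centroids are the per-label means of the training
#' samples, and each unlabelled sample is assigned the label of the nearest
#' centroid (Euclidean distance). With fixed training labels the assignment
#' step alone is deterministic; no iterative refinement is performed. Ties
#' in distance are broken by lexicographic label order.
#'
#' @param features Data.frame with `sample_id`, eigenvector columns
#'   `ev1..evD`, and `label` (NA for samples to classify).
#' @param k Expected number of classes; checked against the training labels
#'   when supplied (default 3).
#' @return Data.frame `sample_id, ancestry` for the unlabelled samples.
#' @export
classify_ancestry <- function(features, k = 3L) {
  check_columns(features, c("sample_id", "label"), "ancestry features")
  ev_cols <- grep("^ev[0-9]+$", names(features), value = TRUE)
  ev_cols <- ev_cols[order(as.integer(sub("ev", "", ev_cols)))]
  check_that(length(ev_cols) > 0L, "no eigenvector (ev*) columns found")
  X <- as.matrix(features[, ev_cols, drop = FALSE])
  check_that(!anyNA(X), "eigenvector columns contain missing values")
  train <- !is.na(features$label)
  check_that(any(train), "no training samples: every label is missing")
  labels <- sort(unique(features$label[train]))
  if (!is.null(k)) {
    check_that(length(labels) == k,
               "training set has %d labels but k = %d", length(labels), k)
  }
  centroids <- do.call(rbind, lapply(labels, function(l) {
    colMeans(X[train & features$label == l, , drop = FALSE])
  }))
  test <- which(!train)
  if (length(test) == 0L) {
    return(data.frame(sample_id = character(0), ancestry = character(0),
                      stringsAsFactors = FALSE))
  }
  # squared distances to each centroid; ties fall to the first (lexicographic)
  d2 <- outer(rowSums(X[test, , drop = FALSE]^2), rowSums(centroids^2), `+`) -
    2 * X[test, , drop = FALSE] %*% t(centroids)
  assigned <- labels[apply(d2, 1L, which.min)]
  data.frame(sample_id = features$sample_id[test], ancestry = assigned,
             stringsAsFactors = FALSE)
}
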