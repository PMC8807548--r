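#' @include AllClasses.R AllGenerics.R pairs.R classify.R
NULL

#' Stratified k-fold assignment
#'
#' @param labels 0/1 vector (both classes, each with at least `k` members)
#' @param k fold count, default 5
#' @param seed integer seed
#' @return integer fold id (1..k) per example; per-class fold sizes differ
#'   by at most 1
#' @export
kfoldSplit <- function(labels, k = 5L, seed = 1L) {
  y <- as.integer(labels)
  k <- assert_scalar_int(k, "k", min = 2)
  if (any(table(factor(y, levels = c(0, 1))) < k))
    stop(sprintf("need at least k = %d examples per class", k), call. = FALSE)
  fold <- integer(length(y))
  with_seed(stageSeed(seed, "kfold"), {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

## step-wise area under the precision-recall curve (ties processed as
## blocks; no interpolation)
aupr_step <- function(labels, scores) {
  P <- sum(labels == 1)
  ord <- order(-scores)
  y <- labels[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))          # block id per distinct score
  tp_b <- tapply(y == 1, grp, sum)
  n_b <- tapply(rep(1, length(y)), grp, sum)
  tp <- cumsum(tp_b); nn <- cumsum(n_b)
  prec <- tp / nn
  recall <- tp / P
  sum(diff(c(0, recall)) * prec)
}

#' The seven evaluation metrics from labels and scores
#'
#' Thresholded metrics (default threshold 0.5): accuracy, sensitivity,
#' specificity, precision and the Matthews correlation coefficient; plus
#' the rank-based AUC (probability a random positive outscores a random
#' negative, ties counted 1/2) and the step-wise area under the
#' precision-recall curve.
#'
#' Precision with an empty predicted-positive set is reported as 0 with a
#' warning flag; an MCC denominator of 0 likewise yields 0 with a flag.
#'
#' @param labels 0/1 vector containing both classes
#' @param scores numeric scores in `[0, 1]`
#' @param threshold classification threshold, default 0.5
#' @param seed informational seed recorded on the report
#' @return a [MetricsReport-class]
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5,
                           seed = NA_integer_) {
  y <- as.integer(labels)
  stopifnot(length(y) == length(scores), all(is.finite(scores)))
  if (length(unique(y)) < 2)
    stop("labels must contain both classes", call. = FALSE)
  flags <- character()
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  acc <- (tp + tn) / length(y)
  sen <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  if (tp + fp == 0) {
    prec <- 0
    flags <- c(flags, "precision undefined (no predicted positives); reported 0")
  } else prec <- tp / (tp + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (mcc_den == 0) {
    mcc <- 0
    flags <- c(flags, "MCC denominator 0; reported 0")
  } else mcc <- (tp * tn - fp * fn) / mcc_den
  ## rank-based AUC with half credit for ties
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  aupr <- aupr_step(y, scores)
  new("MetricsReport",
      summary = stats::setNames(c(acc, sen, spec, prec, mcc, auc, aupr),
                                METRIC_NAMES),
      perFold = matrix(numeric(0), 0, 7,
                       dimnames = list(NULL, METRIC_NAMES)),
      n = length(y), k = 0L, seed = as.integer(seed),
      threshold = threshold, flags = flags)
}

#' Stratified k-fold cross-validation of an embedding + classifier
#'
#' Retrains the classifier for every fold of the training partition and
#' averages the seven metrics. By default the embedding is the one passed
#' in, trained once on the full graph -- which contains all known
#' interaction edges, mirroring the replicated pipeline but leaking
#' fold-test edges into the graph. Set `maskTestEdges = TRUE` (and supply
#' `graph` and `embedBuilder`) to rebuild the embedding per fold on a
#' graph with the fold-test positive lncRNA-mRNA edges removed.
#'
#' @param emb an [EmbeddingMatrix-class] (ignored per fold when masking)
#' @param pairs a [PairDataset-class]; CV runs on its train partition
#' @param k folds, default 5
#' @param seed integer seed
#' @param algorithm,params classifier, as in [trainClassifier()]
#' @param combine pair feature combination
#' @param threshold classification threshold
#' @param maskTestEdges rebuild embeddings on a masked graph per fold
#' @param graph,embedBuilder the [HeteroGraph-class] and a
#'   `function(graph)` returning an [EmbeddingMatrix-class]; only used
#'   when `maskTestEdges = TRUE`
#' @return a [MetricsReport-class] with per-fold rows
#' @export
crossValidate <- function(emb, pairs, k = 5L, seed = 1L,
                          algorithm = "xgboost", params = list(),
                          combine = "concat", threshold = 0.5,
                          maskTestEdges = FALSE, graph = NULL,
                          embedBuilder = NULL) {
  stopifnot(is(pairs, "PairDataset"))
  tr <- pairTable(pairs, "train")
  fold <- kfoldSplit(tr$label, k = k, seed = seed)
  if (maskTestEdges && (is.null(graph) || is.null(embedBuilder)))
    stop("maskTestEdges = TRUE needs `graph` and `embedBuilder`", call. = FALSE)
  feats_full <- if (!maskTestEdges) pairFeatures(emb, tr, combine = combine)
  per <- matrix(NA_real_, k, 7, dimnames = list(NULL, METRIC_NAMES))
  for (f in seq_len(k)) {
    test_i <- which(fold == f); train_i <- which(fold != f)
    if (maskTestEdges) {
      drop_pairs <- tr[test_i[tr$label[test_i] == 1], c("lnc", "mrna")]
      gf <- maskPairEdges(graph, drop_pairs)
      ef <- embedBuilder(gf)
      feats <- pairFeatures(ef, tr, combine = combine)
    } else feats <- feats_full
    model <- trainClassifier(feats[train_i, , drop = FALSE],
                             tr$label[train_i], algorithm = algorithm,
                             params = params,
                             seed = stageSeed(seed, paste0("cv-fold", f)))
    sc <- predictScores(model, feats[test_i, , drop = FALSE])
    per[f, ] <- metricSummary(
      computeMetrics(tr$label[test_i], sc, threshold = threshold))
  }
  new("MetricsReport", summary = colMeans(per), perFold = per,
      n = nrow(tr), k = as.integer(k), seed = as.integer(seed),
      threshold = threshold, flags = character())
}

#' Remove given lncRNA-mRNA interaction edges from a graph
#'
#' Used by the `maskTestEdges` honest-evaluation mode: fold-test positive
#' pairs are removed from the `lnc-mrna` layer before re-embedding.
#'
#' @param g a [HeteroGraph-class]
#' @param dropPairs data.frame of pairs to remove (columns lnc, mrna)
#' @return the graph without those edges (nodes unchanged)
#' @export
maskPairEdges <- function(g, dropPairs) {
  stopifnot(is(g, "HeteroGraph"))
  if (is.null(dropPairs) || nrow(dropPairs) == 0) return(g)
  cp <- canonical_pairs(as.character(dropPairs[[1]]),
                        as.character(dropPairs[[2]]),
                        node_order = g@nodes$id)
  drop_key <- paste(cp$src, cp$dst, sep = "\r")
  ed <- g@edges
  keep <- !(ed$layer == "lnc-mrna" &
              paste(ed$src, ed$dst, sep = "\r") %in% drop_key)
  ed <- ed[keep, , drop = FALSE]
  rownames(ed) <- NULL
  new("HeteroGraph", nodes = g@nodes, edges = ed)
}

#' Evaluate a trained model on the untouched independent partition
#'
#' @param model a [TrainedModel-class] trained on the training partition
#' @param emb the [EmbeddingMatrix-class] used for pair features
#' @param pairs a [PairDataset-class] with both partitions
#' @param combine pair feature combination
#' @param threshold classification threshold
#' @return a [MetricsReport-class]
#' @export
evaluateIndependent <- function(model, emb, pairs, combine = "concat",
                                threshold = 0.5) {
  stopifnot(is(pairs, "PairDataset"))
  tr <- pairTable(pairs, "train")
  ind <- pairTable(pairs, "independent")
  key <- function(d) paste(d$lnc, d$mrna, sep = "\r")
  if (length(intersect(key(tr), key(ind))))
    stop("train and independent partitions overlap", call. = FALSE)
  if (!nrow(ind)) stop("independent partition is empty", call. = FALSE)
  sc <- predictScores(model, pairFeatures(emb, ind, combine = combine))
  computeMetrics(ind$label, sc, threshold = threshold)
}

#' Write a metrics report as JSON and/or a TSV row
#' @param report a [MetricsReport-class]
#' @param jsonFile,tsvFile output paths (NULL to skip either)
#' @return invisibly, the written paths
#' @export
writeMetricsReport <- function(report, jsonFile = NULL, tsvFile = NULL) {
  if (!is.null(jsonFile)) {
    payload <- list(summary = as.list(report@summary),
                    perFold = report@perFold, n = report@n, k = report@k,
                    seed = report@seed, threshold = report@threshold,
                    flags = report@flags)
    jsonlite::write_json(payload, jsonFile, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  if (!is.null(tsvFile)) {
    df <- as.data.frame(t(report@summary))
    utils::write.table(df, tsvFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(jsonFile, tsvFile))
}
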