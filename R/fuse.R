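#' @include AllClasses.R AllGenerics.R pairs.R
NULL

## align a list of embeddings to a common id order; error on mismatch
align_embeddings <- function(embeddings, require_same_dim = TRUE) {
  stopifnot(is.list(embeddings), length(embeddings) >= 1)
  nms <- names(embeddings) %||% vapply(embeddings, embeddingMethod, "")
  mats <- lapply(embeddings, embeddingVectors)
  ids <- rownames(mats[[1]])
  for (i in seq_along(mats)) {
    if (!setequal(rownames(mats[[i]]), ids))
      stop(sprintf("embedding '%s' covers a different node set", nms[i]),
           call. = FALSE)
    mats[[i]] <- mats[[i]][ids, , drop = FALSE]
  }
  if (require_same_dim) {
    dims <- vapply(mats, ncol, 1L)
    if (length(unique(dims)) != 1)
      stop(sprintf("dimension mismatch across methods: %s",
                   paste(sprintf("%s=%d", nms, dims), collapse = ", ")),
           call. = FALSE)
  }
  stats::setNames(mats, nms)
}

#' Per-method AUC weights from cross-validation on the training partition
#'
#' For each embedding method, trains the downstream classifier on that
#' method's pair features alone under `cvFolds`-fold stratified CV
#' restricted to the training partition, and records the mean AUC. These
#' AUCs are the fusion weights; the independent partition is never touched.
#'
#' @param embeddings named list of [EmbeddingMatrix-class] objects covering
#'   the pair endpoints
#' @param pairs a [PairDataset-class]; only its train partition is used
#' @param cvFolds fold count, default 5
#' @param seed integer seed (fold assignment and classifier)
#' @param algorithm,params classifier passed to [trainClassifier()]
#' @return a [FusionWeights-class]
#' @export
aucWeights <- function(embeddings, pairs, cvFolds = 5L, seed = 1L,
                       algorithm = "xgboost", params = list()) {
  stopifnot(is(pairs, "PairDataset"))
  tr <- pairTable(pairs, "train")
  nms <- names(embeddings) %||% vapply(embeddings, embeddingMethod, "")
  auc <- stats::setNames(numeric(length(embeddings)), nms)
  for (m in seq_along(embeddings)) {
    rep_m <- crossValidate(embeddings[[m]], pairs, k = cvFolds, seed = seed,
                           algorithm = algorithm, params = params)
    auc[m] <- metricSummary(rep_m)[["AUC"]]
  }
  new("FusionWeights", auc = auc,
      provenance = sprintf(
        "%d-fold CV on the training partition (n = %d), algorithm = %s, seed = %d",
        cvFolds, nrow(tr), algorithm, as.integer(seed)))
}

#' AUC-weighted average fusion of embeddings
#'
#' The fused vector of each node is
#' `V = sum_m V_m * AUC_m / sum_m AUC_m`:
#' the convex combination of the per-method vectors with the per-method CV
#' AUCs as weights. All embeddings must share dimension and node set.
#'
#' @param embeddings named list of [EmbeddingMatrix-class] (typically the
#'   four methods at a common fusion dimension)
#' @param weights a [FusionWeights-class] (or named numeric) with one
#'   positive weight per embedding
#' @return an [EmbeddingMatrix-class] with method `"fused"`
#' @export
weightedAverage <- function(embeddings, weights) {
  w <- if (is(weights, "FusionWeights")) weights@auc else weights
  mats <- align_embeddings(embeddings)
  if (!setequal(names(w), names(mats)))
    stop("weights must be named exactly by the fused methods", call. = FALSE)
  w <- w[names(mats)]
  if (any(w <= 0)) stop("all fusion weights must be > 0", call. = FALSE)
  acc <- matrix(0, nrow(mats[[1]]), ncol(mats[[1]]),
                dimnames = dimnames(mats[[1]]))
  for (m in names(mats)) acc <- acc + w[[m]] * mats[[m]]
  new_embedding("fused", acc / sum(w),
                params = list(weights = as.list(w),
                              methods = names(mats)))
}

#' Concatenate / average fusion baselines
#'
#' The two non-weighted fusion baselines: `"concatenate"` stacks the
#' method blocks (dimension = sum of input dimensions, blocks in input
#' order); `"average"` is the unweighted mean (requires a common
#' dimension) and equals [weightedAverage()] with equal weights.
#'
#' @param embeddings named list of [EmbeddingMatrix-class]
#' @param mode `"concatenate"` or `"average"`
#' @return an [EmbeddingMatrix-class]
#' @export
fuseBaseline <- function(embeddings, mode = c("concatenate", "average")) {
  mode <- match.arg(mode)
  mats <- align_embeddings(embeddings, require_same_dim = (mode == "average"))
  v <- if (mode == "concatenate") {
    do.call(cbind, unname(mats))
  } else {
    Reduce(`+`, mats) / length(mats)
  }
  rownames(v) <- rownames(mats[[1]])
  new_embedding(mode, v, params = list(methods = names(mats)))
}
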