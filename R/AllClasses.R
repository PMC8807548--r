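#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Biostrings DNAStringSet
#' @useDynLib lncTargetNet, .registration = TRUE
NULL

NODE_TYPES <- c("lncRNA", "mRNA", "miRNA")
EDGE_LAYERS <- c("lnc-sim", "mrna-sim", "lnc-mrna", "lnc-mirna", "mrna-mirna")

## expected endpoint types per layer (unordered)
LAYER_TYPES <- list(
  "lnc-sim"    = c("lncRNA", "lncRNA"),
  "mrna-sim"   = c("mRNA", "mRNA"),
  "lnc-mrna"   = c("lncRNA", "mRNA"),
  "lnc-mirna"  = c("lncRNA", "miRNA"),
  "mrna-mirna" = c("mRNA", "miRNA")
)

#' RnaSet: identified RNA sequences with a node type
#'
#' Holds sequences for one or more of the three node types of the
#' heterogeneous network (lncRNA, mRNA, miRNA). Sequences are stored over
#' the DNA alphabet; `U` is mapped to `T` and letters are upper-cased at
#' ingest. Any other character is an error, never silently skipped.
#'
#' @slot sequences a [Biostrings::DNAStringSet] named by stable ids
#' @slot nodeType character vector parallel to `sequences`, each one of
#'   `"lncRNA"`, `"mRNA"`, `"miRNA"`
#' @export
setClass("RnaSet",
  representation(sequences = "DNAStringSet", nodeType = "character"))

setValidity("RnaSet", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (length(object@nodeType) != n)
    msgs <- c(msgs, "nodeType length must equal number of sequences")
  if (!all(object@nodeType %in% NODE_TYPES))
    msgs <- c(msgs, sprintf("nodeType values must be in {%s}",
                            paste(NODE_TYPES, collapse = ", ")))
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msgs <- c(msgs, "all sequences must be named by non-empty ids")
  else {
    key <- paste(object@nodeType, ids, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "ids must be unique within each node type")
  }
  if (n > 0) {
    af <- Biostrings::alphabetFrequency(object@sequences)
    bad <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE]) != Biostrings::width(object@sequences)
    if (any(bad)) {
      letters_bad <- colnames(af)[colSums(af[bad, , drop = FALSE]) > 0]
      letters_bad <- setdiff(letters_bad, c("A", "C", "G", "T"))
      msgs <- c(msgs, sprintf(
        "sequences contain non-ACGT characters (%s) in: %s",
        paste(letters_bad, collapse = ","),
        paste(utils::head(ids[bad], 5), collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' HeteroGraph: the five-layer typed heterogeneous network
#'
#' An undirected, weighted graph over lncRNA, mRNA and miRNA nodes whose
#' edges carry a layer tag: two sequence-similarity layers (`lnc-sim`,
#' `mrna-sim`, weighted by linear-neighborhood similarity) and three
#' interaction layers (`lnc-mrna`, `lnc-mirna`, `mrna-mirna`, weight 1 by
#' default). Node order is fixed (lncRNAs sorted, then mRNAs, then miRNAs)
#' so matrix indices are reproducible.
#'
#' @slot nodes data.frame with columns `id`, `type`
#' @slot edges data.frame with columns `src`, `dst`, `weight`, `layer`;
#'   each undirected edge stored once with `src` before `dst` in node order
#' @export
setClass("HeteroGraph",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("HeteroGraph", function(object) {
  msgs <- character()
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "type") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns id, type")
  if (!all(c("src", "dst", "weight", "layer") %in% names(ed)))
    msgs <- c(msgs, "edges must have columns src, dst, weight, layer")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "node ids must be unique")
  if (!all(nd$type %in% NODE_TYPES)) msgs <- c(msgs, "invalid node type")
  if (nrow(ed)) {
    if (any(ed$src == ed$dst)) msgs <- c(msgs, "self-loops are not allowed")
    if (!all(c(ed$src, ed$dst) %in% nd$id))
      msgs <- c(msgs, "edge endpoint not present in node table")
    if (any(!is.finite(ed$weight)) || any(ed$weight <= 0))
      msgs <- c(msgs, "edge weights must be finite and > 0")
    if (!all(ed$layer %in% EDGE_LAYERS)) msgs <- c(msgs, "invalid edge layer tag")
    if (anyDuplicated(paste(pmin(ed$src, ed$dst), pmax(ed$src, ed$dst))))
      msgs <- c(msgs, "duplicate undirected edges")
    type_of <- stats::setNames(nd$type, nd$id)
    for (ly in unique(ed$layer)) {
      sel <- ed$layer == ly
      want <- sort(LAYER_TYPES[[ly]])
      got_ok <- mapply(function(a, b) identical(sort(c(a, b)), want),
                       type_of[ed$src[sel]], type_of[ed$dst[sel]])
      if (!all(got_ok))
        msgs <- c(msgs, sprintf("layer %s has edges with wrong endpoint types", ly))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' EmbeddingMatrix: per-node representation vectors
#'
#' One row per embedded node (rownames are node ids), one column per
#' dimension. `method` records which network-representation-learning
#' method produced it (`"LINE"`, `"GraRep"`, `"node2vec"`, `"TADW"`,
#' `"fused"`, `"concatenate"`, `"average"`).
#'
#' @slot method character scalar
#' @slot vectors numeric matrix, rownames = node ids
#' @slot seed integer seed used (NA for deterministic methods)
#' @slot params list of hyperparameters used
#' @export
setClass("EmbeddingMatrix",
  representation(method = "character", vectors = "matrix",
                 seed = "integer", params = "list"))

setValidity("EmbeddingMatrix", function(object) {
  msgs <- character()
  v <- object@vectors
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msgs <- c(msgs, "vectors must have unique rownames (node ids)")
  if (length(v) && !all(is.finite(v)))
    msgs <- c(msgs, "embedding entries must all be finite")
  if (length(object@method) != 1L)
    msgs <- c(msgs, "method must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' PairDataset: labeled lncRNA-mRNA pairs with a train/independent split
#'
#' @slot pairs data.frame with columns `lnc`, `mrna`, `label` (0/1) and
#'   `partition` (`"train"` or `"independent"`)
#' @slot seed integer seed used for negative sampling / splitting
#' @export
setClass("PairDataset",
  representation(pairs = "data.frame", seed = "integer"))

setValidity("PairDataset", function(object) {
  msgs <- character()
  pr <- object@pairs
  if (!all(c("lnc", "mrna", "label", "partition") %in% names(pr)))
    return("pairs must have columns lnc, mrna, label, partition")
  if (nrow(pr)) {
    if (!all(pr$label %in% c(0L, 1L))) msgs <- c(msgs, "labels must be 0/1")
    if (!all(pr$partition %in% c("train", "independent")))
      msgs <- c(msgs, "partition must be 'train' or 'independent'")
    if (anyDuplicated(paste(pr$lnc, pr$mrna, sep = "\r")))
      msgs <- c(msgs, "duplicated pairs")
  }
  if (length(msgs)) msgs else TRUE
})

#' MetricsReport: the seven-link prediction evaluation metrics
#'
#' Accuracy, sensitivity, specificity, precision, Matthews correlation
#' coefficient, area under the ROC curve and area under the
#' precision-recall curve, optionally with per-fold values from
#' cross-validation.
#'
#' @slot summary named numeric: ACC, SEN, SPEC, PREC, MCC, AUC, AUPR
#' @slot perFold numeric matrix (folds x 7), 0 rows when not from CV
#' @slot n number of evaluated pairs
#' @slot k fold count (0 when not from CV)
#' @slot seed integer seed
#' @slot threshold classification threshold for the five thresholded metrics
#' @slot flags character vector of warnings raised (e.g. undefined precision)
#' @export
setClass("MetricsReport",
  representation(summary = "numeric", perFold = "matrix", n = "integer",
                 k = "integer", seed = "integer", threshold = "numeric",
                 flags = "character"))

METRIC_NAMES <- c("ACC", "SEN", "SPEC", "PREC", "MCC", "AUC", "AUPR")

setValidity("MetricsReport", function(object) {
  msgs <- character()
  s <- object@summary
  if (!identical(names(s), METRIC_NAMES))
    msgs <- c(msgs, sprintf("summary must be named %s", paste(METRIC_NAMES, collapse = ",")))
  else {
    in01 <- s[c("ACC", "SEN", "SPEC", "PREC", "AUC", "AUPR")]
    if (any(in01 < -1e-9 | in01 > 1 + 1e-9, na.rm = TRUE))
      msgs <- c(msgs, "ACC/SEN/SPEC/PREC/AUC/AUPR must be in [0,1]")
    if (!is.na(s["MCC"]) && (s["MCC"] < -1 - 1e-9 || s["MCC"] > 1 + 1e-9))
      msgs <- c(msgs, "MCC must be in [-1,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' FusionWeights: per-method AUC weights for embedding fusion
#'
#' @slot auc named numeric, one AUC per fused method, each in (0, 1]
#' @slot provenance description of the evaluation that produced the AUCs
#' @export
setClass("FusionWeights",
  representation(auc = "numeric", provenance = "character"))

setValidity("FusionWeights", function(object) {
  msgs <- character()
  if (is.null(names(object@auc)) || anyDuplicated(names(object@auc)))
    msgs <- c(msgs, "auc must be uniquely named by method")
  if (any(object@auc <= 0 | object@auc > 1))
    msgs <- c(msgs, "all AUC weights must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' WalkCorpus: biased random walks over the heterogeneous graph
#'
#' @slot walks integer matrix, one walk per row, entries are 1-based node
#'   indices into `ids`, NA past a dead end
#' @slot ids node ids indexed by the walk entries
#' @slot n walks per start node
#' @slot l walk length
#' @slot p,q node2vec return / in-out parameters
#' @slot seed integer seed
#' @export
setClass("WalkCorpus",
  representation(walks = "matrix", ids = "character", n = "integer",
                 l = "integer", p = "numeric", q = "numeric", seed = "integer"))

#' TrainedModel: a fitted pair classifier
#'
#' @slot algorithm one of `"xgboost"`, `"gbdt"`, `"adaboost"`, `"rf"`,
#'   `"knn"`, `"svm"` (the boosted-tree learner is the primary choice)
#' @slot fit internal fitted object
#' @slot params hyperparameters used
#' @slot seed integer seed
#' @slot featureWidth expected feature-vector width
#' @export
setClass("TrainedModel",
  representation(algorithm = "character", fit = "list", params = "list",
                 seed = "integer", featureWidth = "integer"))
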