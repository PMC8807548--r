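#' @include AllClasses.R
NULL

#' Node ids of an object
#' @param x an object holding identified nodes or sequences
#' @return character vector of ids
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Node types of an object
#' @param x an object holding typed nodes
#' @return character vector, values in `lncRNA`, `mRNA`, `miRNA`
#' @export
setGeneric("nodeTypes", function(x) standardGeneric("nodeTypes"))

#' Edge table of a heterogeneous graph
#' @param x a [HeteroGraph-class]
#' @return data.frame with columns src, dst, weight, layer
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Weighted adjacency matrix S of a graph
#' @param x a [HeteroGraph-class]
#' @param sparse return a sparse `Matrix` (default) or a dense matrix
#' @return symmetric weighted adjacency matrix with node ids as dimnames
#' @export
setGeneric("adjacencyMatrix", function(x, sparse = TRUE) standardGeneric("adjacencyMatrix"))

#' Weighted node degrees d_i (row sums of the adjacency matrix)
#' @param x a [HeteroGraph-class]
#' @return named numeric vector
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' Total edge weight W (half the adjacency matrix sum)
#' @param x a [HeteroGraph-class]
#' @return numeric scalar
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' First-order transition probability matrix A = D^-1 S
#'
#' Rows of the returned matrix are probability distributions over one-step
#' neighbors. Isolated nodes must be removed first (see
#' [dropIsolatedNodes()]); reaching this function with a zero-degree node is
#' an error.
#' @param x a [HeteroGraph-class]
#' @return dense row-stochastic matrix with node ids as dimnames
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' Embedding method name
#' @param x an [EmbeddingMatrix-class]
#' @return character scalar
#' @export
setGeneric("embeddingMethod", function(x) standardGeneric("embeddingMethod"))

#' Embedding vectors as a plain matrix
#' @param x an [EmbeddingMatrix-class]
#' @return numeric matrix, rownames = node ids
#' @export
setGeneric("embeddingVectors", function(x) standardGeneric("embeddingVectors"))

#' Pair table of a pair dataset
#' @param x a [PairDataset-class]
#' @param partition optional: restrict to `"train"` or `"independent"`
#' @return data.frame with columns lnc, mrna, label, partition
#' @export
setGeneric("pairTable", function(x, partition = NULL) standardGeneric("pairTable"))

#' Metric summary of a report
#' @param x a [MetricsReport-class]
#' @return named numeric vector (ACC, SEN, SPEC, PREC, MCC, AUC, AUPR)
#' @export
setGeneric("metricSummary", function(x) standardGeneric("metricSummary"))

## ---- RnaSet ----

#' @describeIn RnaSet-class sequence ids
#' @param x object
#' @export
setMethod("nodeIds", "RnaSet", function(x) names(x@sequences))

#' @describeIn RnaSet-class node types
#' @export
setMethod("nodeTypes", "RnaSet", function(x) x@nodeType)

#' @describeIn RnaSet-class number of sequences
#' @export
setMethod("length", "RnaSet", function(x) length(x@sequences))

setMethod("show", "RnaSet", function(object) {
  cat(sprintf("RnaSet with %d sequences (%s)\n", length(object),
              paste(sprintf("%s: %d", names(table(object@nodeType)),
                            as.integer(table(object@nodeType))), collapse = ", ")))
})

#' Subset an RnaSet
#' @param x an [RnaSet-class]
#' @param i index vector (logical, integer or id names)
#' @param j,...,drop ignored
#' @export
setMethod("[", "RnaSet", function(x, i, j, ..., drop = FALSE) {
  new("RnaSet", sequences = x@sequences[i], nodeType = {
    idx <- if (is.character(i)) match(i, names(x@sequences)) else i
    x@nodeType[idx]
  })
})

#' Sequences of an RnaSet as character
#' @param x an [RnaSet-class]
#' @return named character vector
#' @export
rnaSequences <- function(x) {
  stopifnot(is(x, "RnaSet"))
  stats::setNames(as.character(x@sequences), names(x@sequences))
}

## ---- HeteroGraph ----

#' @describeIn HeteroGraph-class node ids in canonical order
#' @param x object
#' @export
setMethod("nodeIds", "HeteroGraph", function(x) x@nodes$id)

#' @describeIn HeteroGraph-class node types in canonical order
#' @export
setMethod("nodeTypes", "HeteroGraph", function(x)
  stats::setNames(x@nodes$type, x@nodes$id))

#' @describeIn HeteroGraph-class edge table
#' @export
setMethod("edgeTable", "HeteroGraph", function(x) x@edges)

#' @describeIn HeteroGraph-class weighted adjacency matrix
#' @param sparse logical
#' @export
setMethod("adjacencyMatrix", "HeteroGraph", function(x, sparse = TRUE) {
  n <- nrow(x@nodes)
  idx <- stats::setNames(seq_len(n), x@nodes$id)
  ed <- x@edges
  S <- Matrix::sparseMatrix(
    i = c(idx[ed$src], idx[ed$dst]),
    j = c(idx[ed$dst], idx[ed$src]),
    x = c(ed$weight, ed$weight),
    dims = c(n, n), dimnames = list(x@nodes$id, x@nodes$id))
  if (sparse) S else as.matrix(S)
})

#' @describeIn HeteroGraph-class weighted degrees
#' @export
setMethod("nodeDegrees", "HeteroGraph", function(x)
  stats::setNames(Matrix::rowSums(adjacencyMatrix(x)), x@nodes$id))

#' @describeIn HeteroGraph-class total edge weight
#' @export
setMethod("totalWeight", "HeteroGraph", function(x) sum(x@edges$weight))

setMethod("show", "HeteroGraph", function(object) {
  tt <- table(factor(object@nodes$type, levels = NODE_TYPES))
  lt <- table(factor(object@edges$layer, levels = EDGE_LAYERS))
  cat(sprintf("HeteroGraph: %d nodes (%s)\n", nrow(object@nodes),
              paste(sprintf("%s %d", names(tt), as.integer(tt)), collapse = ", ")))
  cat(sprintf("  %d undirected edges (%s)\n", nrow(object@edges),
              paste(sprintf("%s %d", names(lt), as.integer(lt)), collapse = ", ")))
})

## ---- EmbeddingMatrix ----

#' @describeIn EmbeddingMatrix-class method name
#' @param x object
#' @export
setMethod("embeddingMethod", "EmbeddingMatrix", function(x) x@method)

#' @describeIn EmbeddingMatrix-class plain matrix of vectors
#' @export
setMethod("embeddingVectors", "EmbeddingMatrix", function(x) x@vectors)

#' @describeIn EmbeddingMatrix-class embedded node ids
#' @export
setMethod("nodeIds", "EmbeddingMatrix", function(x) rownames(x@vectors))

#' @describeIn EmbeddingMatrix-class rows x dimension
#' @export
setMethod("dim", "EmbeddingMatrix", function(x) dim(x@vectors))

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix [%s]: %d nodes x %d dims\n",
              object@method, nrow(object@vectors), ncol(object@vectors)))
})

## ---- PairDataset ----

#' @describeIn PairDataset-class pair table, optionally one partition
#' @param x object
#' @param partition NULL, "train" or "independent"
#' @export
setMethod("pairTable", "PairDataset", function(x, partition = NULL) {
  pr <- x@pairs
  if (!is.null(partition)) {
    stopifnot(partition %in% c("train", "independent"))
    pr <- pr[pr$partition == partition, , drop = FALSE]
    rownames(pr) <- NULL
  }
  pr
})

setMethod("show", "PairDataset", function(object) {
  pr <- object@pairs
  cat(sprintf("PairDataset: %d pairs (%d+/%d-), %d train / %d independent\n",
              nrow(pr), sum(pr$label == 1), sum(pr$label == 0),
              sum(pr$partition == "train"), sum(pr$partition == "independent")))
})

## ---- MetricsReport ----

#' @describeIn MetricsReport-class named metric vector
#' @param x object
#' @export
setMethod("metricSummary", "MetricsReport", function(x) x@summary)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport (n = %d%s):\n", object@n,
              if (object@k > 0) sprintf(", %d-fold CV", object@k) else ""))
  print(round(object@summary, 4))
  if (length(object@flags)) cat("flags:", paste(object@flags, collapse = "; "), "\n")
})

## ---- others ----

setMethod("show", "FusionWeights", function(object) {
  cat("FusionWeights (AUC):\n")
  print(round(object@auc, 4))
})

setMethod("show", "WalkCorpus", function(object) {
  cat(sprintf("WalkCorpus: %d walks of length %d (n = %d per node, p = %g, q = %g)\n",
              nrow(object@walks), ncol(object@walks), object@n, object@p, object@q))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel [%s], feature width %d\n",
              object@algorithm, object@featureWidth))
})

#' Fusion AUC weights as a named vector
#' @param x a [FusionWeights-class]
#' @return named numeric
#' @export
fusionAuc <- function(x) {
  stopifnot(is(x, "FusionWeights"))
  x@auc
}

#' Walks of a corpus as a 1-based integer index matrix
#' @param x a [WalkCorpus-class]
#' @return integer matrix; `walkIds(x)` maps indices to node ids
#' @export
corpusWalks <- function(x) {
  stopifnot(is(x, "WalkCorpus"))
  x@walks
}

#' Node ids indexed by walk entries
#' @param x a [WalkCorpus-class]
#' @return character vector
#' @export
walkIds <- function(x) {
  stopifnot(is(x, "WalkCorpus"))
  x@ids
}
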