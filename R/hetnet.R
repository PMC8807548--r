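#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Filter an interaction edge list to allowed endpoints, deduplicated
#'
#' Mirrors the database-cleaning protocol for the interaction layers: drop
#' duplicate pairs, then keep only pairs whose first endpoint lies in
#' `allowedA` and second endpoint in `allowedB` (e.g. lncRNA-miRNA
#' interactions restricted to the lncRNAs present in the lncRNA-mRNA
#' layer). Passing `NULL` for an allowed set disables that restriction.
#'
#' @param rawEdges two-column data.frame (or matrix) of id pairs
#' @param allowedA character set for column 1, or NULL
#' @param allowedB character set for column 2, or NULL
#' @return deduplicated, restricted data.frame with columns `a`, `b`,
#'   sorted by (`a`, `b`) for order-normalized output
#' @export
filterInteractions <- function(rawEdges, allowedA = NULL, allowedB = NULL) {
  df <- as.data.frame(rawEdges, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2)
  df <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]))
  df <- unique(df)
  if (!is.null(allowedA)) df <- df[df$a %in% allowedA, , drop = FALSE]
  if (!is.null(allowedB)) df <- df[df$b %in% allowedB, , drop = FALSE]
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## similarity edge list (directed top-k) -> symmetrized undirected edges
sym_sim_edges <- function(simEdges, layer) {
  if (is.null(simEdges) || nrow(simEdges) == 0)
    return(data.frame(src = character(), dst = character(),
                      weight = numeric(), layer = character()))
  keep <- simEdges$source != simEdges$target
  se <- simEdges[keep, , drop = FALSE]
  cp <- canonical_pairs(se$source, se$target)
  key <- paste(cp$src, cp$dst, sep = "\r")
  ## union with max weight over the two directions
  w <- tapply(se$weight, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  data.frame(src = vapply(parts, `[`, "", 1), dst = vapply(parts, `[`, "", 2),
             weight = as.numeric(w), layer = layer)
}

#' Assemble the five-layer heterogeneous graph
#'
#' Merges the two sequence-similarity layers (edges carry their LNS
#' weights; the row-wise top-k graphs are symmetrized by edge union with
#' the maximum weight) and the three interaction layers (weight
#' `interactionWeight`, default 1) into one undirected typed graph. Node
#' order is lncRNAs (sorted), then mRNAs, then miRNAs. The three id spaces
#' must be disjoint.
#'
#' @param lncSim,mrnaSim similarity edge lists from [topkGraph()]
#'   (`source`, `target`, `weight`), or NULL/empty
#' @param lncMrna,lncMirna,mrnaMirna interaction pair data.frames
#'   (columns a, b as from [filterInteractions()]), or NULL/empty
#' @param interactionWeight weight given to interaction edges, default 1
#' @param binarizeSim if TRUE, similarity edges get weight 1 instead of the
#'   LNS weight
#' @return a [HeteroGraph-class]
#' @export
assembleHeteroGraph <- function(lncSim = NULL, mrnaSim = NULL,
                                lncMrna = NULL, lncMirna = NULL,
                                mrnaMirna = NULL, interactionWeight = 1,
                                binarizeSim = FALSE) {
  as_pairs <- function(x) {
    if (is.null(x) || nrow(x) == 0)
      return(data.frame(a = character(), b = character()))
    data.frame(a = as.character(x[[1]]), b = as.character(x[[2]]))
  }
  lm <- as_pairs(lncMrna); li <- as_pairs(lncMirna); mi <- as_pairs(mrnaMirna)
  sim_l <- sym_sim_edges(lncSim, "lnc-sim")
  sim_m <- sym_sim_edges(mrnaSim, "mrna-sim")

  lnc_ids <- sort(unique(c(sim_l$src, sim_l$dst, lm$a, li$a)))
  mrna_ids <- sort(unique(c(sim_m$src, sim_m$dst, lm$b, mi$a)))
  mirna_ids <- sort(unique(c(li$b, mi$b)))
  overlap <- c(intersect(lnc_ids, mrna_ids), intersect(lnc_ids, mirna_ids),
               intersect(mrna_ids, mirna_ids))
  if (length(overlap))
    stop("id spaces of the three node types must be disjoint; shared ids: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)

  nodes <- data.frame(
    id = c(lnc_ids, mrna_ids, mirna_ids),
    type = c(rep("lncRNA", length(lnc_ids)), rep("mRNA", length(mrna_ids)),
             rep("miRNA", length(mirna_ids))))

  if (binarizeSim) { sim_l$weight[] <- 1; sim_m$weight[] <- 1 }
  inter_edges <- function(p, layer)
    if (nrow(p)) data.frame(src = p$a, dst = p$b,
                            weight = interactionWeight, layer = layer)
    else data.frame(src = character(), dst = character(),
                    weight = numeric(), layer = character())
  ed <- rbind(sim_l, sim_m,
              inter_edges(unique(lm), "lnc-mrna"),
              inter_edges(unique(li), "lnc-mirna"),
              inter_edges(unique(mi), "mrna-mirna"))

  if (nrow(ed)) {
    cp <- canonical_pairs(ed$src, ed$dst, node_order = nodes$id)
    ed$src <- cp$src; ed$dst <- cp$dst
    ## duplicates (within a layer, or hypothetically across) -> max weight;
    ## ties broken by layer declaration order for determinism
    ed$layer <- factor(ed$layer, levels = EDGE_LAYERS)
    ed <- ed[order(ed$src, ed$dst, -ed$weight, ed$layer), , drop = FALSE]
    ed <- ed[!duplicated(paste(ed$src, ed$dst, sep = "\r")), , drop = FALSE]
    ed$layer <- as.character(ed$layer)
    ## fixed edge order: by node index then layer
    ed <- ed[order(match(ed$src, nodes$id), match(ed$dst, nodes$id)), , drop = FALSE]
    rownames(ed) <- NULL
  }
  new("HeteroGraph", nodes = nodes, edges = ed)
}

#' Drop isolated (degree-zero) nodes from a graph
#'
#' Embedding methods need every node to have at least one edge; synthetic
#' configurations can produce isolated nodes. Removal is logged with a
#' warning naming the count.
#'
#' @param g a [HeteroGraph-class]
#' @return the graph without isolated nodes
#' @export
dropIsolatedNodes <- function(g) {
  stopifnot(is(g, "HeteroGraph"))
  deg <- nodeDegrees(g)
  iso <- names(deg)[deg == 0]
  if (!length(iso)) return(g)
  warning(sprintf("dropping %d isolated node(s) before embedding: %s",
                  length(iso), paste(utils::head(iso, 5), collapse = ", ")))
  nodes <- g@nodes[!g@nodes$id %in% iso, , drop = FALSE]
  rownames(nodes) <- NULL
  new("HeteroGraph", nodes = nodes, edges = g@edges)
}

#' @describeIn transitionMatrix row-stochastic transition matrix of a
#'   heterogeneous graph
#' @export
setMethod("transitionMatrix", "HeteroGraph", function(x) {
  S <- adjacencyMatrix(x, sparse = FALSE)
  d <- rowSums(S)
  if (any(d == 0))
    stop("graph has zero-degree node(s); call dropIsolatedNodes() first",
         call. = FALSE)
  S / d
})

#' Write a heterogeneous graph as node + edge TSV tables
#' @param g a [HeteroGraph-class]
#' @param nodeFile,edgeFile output paths
#' @return invisibly, c(nodeFile, edgeFile)
#' @export
writeHeteroGraph <- function(g, nodeFile, edgeFile) {
  utils::write.table(g@nodes, nodeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g@edges, edgeFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodeFile, edgeFile))
}

#' Read a heterogeneous graph written by [writeHeteroGraph()]
#' @param nodeFile,edgeFile TSV paths
#' @return a [HeteroGraph-class]
#' @export
readHeteroGraph <- function(nodeFile, edgeFile) {
  nodes <- utils::read.delim(nodeFile, stringsAsFactors = FALSE)
  edges <- utils::read.delim(edgeFile, stringsAsFactors = FALSE)
  new("HeteroGraph", nodes = nodes, edges = edges)
}

#' Read a two-column interaction TSV
#' @param file TSV path; first two columns are the id pair
#' @return data.frame with columns a, b
#' @export
readInteractionTSV <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  filterInteractions(df)
}

#' Write a two-column interaction table as TSV
#' @param pairs data.frame with columns a, b
#' @param file output path
#' @return `file`, invisibly
#' @export
writeInteractionTSV <- function(pairs, file) {
  utils::write.table(pairs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
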