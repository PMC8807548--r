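#' @include AllClasses.R AllGenerics.R utils.R hetnet.R
NULL

## directed 0-based edge arrays (both directions of each undirected edge)
directed_edges <- function(g) {
  idx <- stats::setNames(seq_len(nrow(g@nodes)) - 1L, g@nodes$id)
  ed <- g@edges
  list(src = c(idx[ed$src], idx[ed$dst]),
       dst = c(idx[ed$dst], idx[ed$src]),
       weight = c(ed$weight, ed$weight),
       n = nrow(g@nodes))
}

## CSR arrays with sorted neighbor indices; for a symmetric matrix the CSC
## slots of a dgCMatrix double as CSR
graph_csr <- function(g) {
  S <- adjacencyMatrix(g, sparse = TRUE)
  S <- methods::as(S, "generalMatrix")
  S <- methods::as(S, "CsparseMatrix")
  list(indptr = S@p, indices = S@i, weights = S@x, n = nrow(S))
}

new_embedding <- function(method, vectors, seed = NA_integer_, params = list()) {
  new("EmbeddingMatrix", method = method, vectors = vectors,
      seed = as.integer(seed), params = params)
}

check_graph_nonempty <- function(g) {
  if (!is(g, "HeteroGraph") || nrow(g@nodes) == 0 || nrow(g@edges) == 0)
    stop("need a non-empty HeteroGraph with at least one edge", call. = FALSE)
  if (any(nodeDegrees(g) == 0))
    stop("graph has zero-degree node(s); call dropIsolatedNodes() first",
         call. = FALSE)
}

#' Embed a heterogeneous graph with one named method
#'
#' Thin dispatcher over [lineEmbed()], [grarepEmbed()], [node2vecEmbed()]
#' and [tadwEmbed()] so pipelines can sweep methods by name. Defaults per
#' method follow the tuned settings of the underlying study design
#' (GraRep d = 128, k = 4; LINE d = 64, order 3; TADW d = 256, lambda =
#' 0.1; node2vec d = 64, n = 20, l = 80); pass `d` to override, as fusion
#' requires a common dimension.
#'
#' @param g a [HeteroGraph-class]
#' @param method `"LINE"`, `"GraRep"`, `"node2vec"` or `"TADW"`
#' @param d embedding dimension; NULL uses the per-method default
#' @param seed integer seed
#' @param text feature matrix for TADW (rows = node ids), ignored otherwise
#' @param ... further method-specific arguments
#' @return an [EmbeddingMatrix-class]
#' @export
embedGraph <- function(g, method, d = NULL, seed = 1L, text = NULL, ...) {
  method <- match.arg(method, c("LINE", "GraRep", "node2vec", "TADW"))
  switch(method,
    LINE = lineEmbed(g, d = d %||% 64L, seed = seed, ...),
    GraRep = grarepEmbed(g, d = d %||% 128L, ...),
    node2vec = node2vecEmbed(g, d = d %||% 64L, seed = seed, ...),
    TADW = {
      if (is.null(text)) stop("TADW needs a text feature matrix", call. = FALSE)
      tadwEmbed(g, text, d = d %||% 256L, seed = seed, ...)
    })
}

#' Write an embedding as TSV plus a JSON metadata sidecar
#' @param emb an [EmbeddingMatrix-class]
#' @param file TSV path; the sidecar is written to `<file>.json`
#' @return `file`, invisibly
#' @export
writeEmbedding <- function(emb, file) {
  v <- embeddingVectors(emb)
  df <- data.frame(id = rownames(v), v, check.names = FALSE, row.names = NULL)
  colnames(df) <- c("id", paste0("d", seq_len(ncol(v)) - 1))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(method = embeddingMethod(emb), d = ncol(v),
               seed = emb@seed,
               params = emb@params[!vapply(emb@params, is.numeric, TRUE) |
                                     lengths(emb@params) <= 16])
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(file)
}

#' Read an embedding written by [writeEmbedding()]
#' @param file TSV path (sidecar `<file>.json` read if present)
#' @return an [EmbeddingMatrix-class]
#' @export
readEmbedding <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$id
  meta_file <- paste0(file, ".json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file) else list()
  sd <- meta$seed
  if (!is.numeric(sd)) sd <- NA_integer_
  new_embedding(meta$method %||% "unknown", v, seed = sd)
}
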