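#' @include embed-common.R
NULL

#' Biased second-order random walks (node2vec)
#'
#' Generates `n` walks of length `l` from every node. After the first step,
#' the unnormalized probability of moving from the current node to
#' candidate `x` given previous node `t` is the edge weight times `1/p` if
#' `x = t`, times 1 if `x` is a neighbor of `t`, and times `1/q` otherwise
#' (BFS-like for small `q`, DFS-like for large `q` reversed). Fixed seed
#' gives an identical corpus.
#'
#' @param g a [HeteroGraph-class] without isolated nodes
#' @param n walks per start node, default 20
#' @param l walk length, default 80
#' @param p return parameter (> 0), default 1
#' @param q in-out parameter (> 0), default 1
#' @param seed integer seed
#' @return a [WalkCorpus-class]
#' @export
node2vecWalks <- function(g, n = 20L, l = 80L, p = 1, q = 1, seed = 1L) {
  check_graph_nonempty(g)
  n <- assert_scalar_int(n, "n")
  l <- assert_scalar_int(l, "l", min = 2)
  stopifnot(is.numeric(p), p > 0, is.numeric(q), q > 0)
  seed <- assert_scalar_int(seed, "seed", min = 0)
  csr <- graph_csr(g)
  walks <- cpp_node2vec_walks(csr$indptr, csr$indices, csr$weights, csr$n,
                              n, l, p, q, stageSeed(seed, "node2vec-walks"))
  walks <- walks + 1L
  walks[walks == 0L] <- NA_integer_
  new("WalkCorpus", walks = walks, ids = g@nodes$id,
      n = n, l = l, p = as.numeric(p), q = as.numeric(q),
      seed = as.integer(seed))
}

#' Skip-gram with negative sampling over a walk corpus
#'
#' Maximizes the windowed co-occurrence likelihood of walk contexts around
#' each center node (negative-sampling surrogate, noise distribution
#' proportional to corpus frequency^0.75). Fixed seed gives identical
#' vectors.
#'
#' @param corpus a [WalkCorpus-class]
#' @param d embedding dimension, default 64
#' @param window one-sided context window size (>= 1), default 5
#' @param negativeSamples negatives per positive, default 5
#' @param epochs passes over the corpus, default 5
#' @param learningRate initial SGD rate (linear decay), default 0.025
#' @param seed integer seed
#' @return an [EmbeddingMatrix-class] with method `"node2vec"`
#' @export
skipgramEmbed <- function(corpus, d = 64L, window = 5L, negativeSamples = 5L,
                          epochs = 5L, learningRate = 0.025, seed = 1L) {
  stopifnot(is(corpus, "WalkCorpus"))
  if (nrow(corpus@walks) == 0) stop("empty walk corpus", call. = FALSE)
  d <- assert_scalar_int(d, "d")
  window <- assert_scalar_int(window, "window", min = 1)
  seed <- assert_scalar_int(seed, "seed", min = 0)
  w0 <- corpus@walks - 1L
  w0[is.na(w0)] <- -1L
  v <- cpp_skipgram_train(w0, length(corpus@ids), d, window,
                          as.integer(negativeSamples), as.integer(epochs),
                          learningRate, stageSeed(seed, "skipgram"))
  rownames(v) <- corpus@ids
  new_embedding("node2vec", v, seed = seed,
                params = list(d = d, window = window,
                              negativeSamples = negativeSamples,
                              epochs = epochs, learningRate = learningRate,
                              n = corpus@n, l = corpus@l,
                              p = corpus@p, q = corpus@q))
}

#' node2vec embedding: biased walks + skip-gram
#'
#' Convenience wrapper chaining [node2vecWalks()] and [skipgramEmbed()].
#' With `p = q = 1` this reduces to DeepWalk (unbiased walks).
#'
#' @inheritParams node2vecWalks
#' @inheritParams skipgramEmbed
#' @return an [EmbeddingMatrix-class] with method `"node2vec"`
#' @export
node2vecEmbed <- function(g, d = 64L, n = 20L, l = 80L, p = 1, q = 1,
                          window = 5L, negativeSamples = 5L, epochs = 5L,
                          learningRate = 0.025, seed = 1L) {
  corpus <- node2vecWalks(g, n = n, l = l, p = p, q = q, seed = seed)
  skipgramEmbed(corpus, d = d, window = window,
                negativeSamples = negativeSamples, epochs = epochs,
                learningRate = learningRate, seed = seed)
}
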