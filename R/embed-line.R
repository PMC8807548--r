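#' @include embed-common.R
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LINE embedding of a heterogeneous graph
#'
#' Stochastic-gradient training of first- and/or second-order proximity.
#' Order 1 models the joint edge probability `p1(i,j) = sigmoid(u_i . u_j)`
#' against the empirical distribution `w_ij / W`; order 2 models the
#' context-generation probability with separate vertex and context vectors
#' against `w_ij / d_i`, optimized with the negative-sampling surrogate.
#' Order 3 is the concatenation of an order-1 and an order-2 half, each of
#' dimension `d/2`. Edges are sampled with the alias method proportional to
#' weight; negatives from the weighted-degree^0.75 noise distribution.
#' Fixed seed gives bit-identical results.
#'
#' @param g a [HeteroGraph-class] without isolated nodes
#' @param d embedding dimension (even when `order = 3`), default 64
#' @param order 1, 2 or 3 (default 3)
#' @param negativeSamples negatives per positive sample, default 5
#' @param epochs passes over the edge multiset, default 5
#' @param learningRate initial SGD rate (linear decay), default 0.025
#' @param seed integer seed
#' @return an [EmbeddingMatrix-class] with method `"LINE"`
#' @export
lineEmbed <- function(g, d = 64L, order = 3L, negativeSamples = 5L,
                      epochs = 5L, learningRate = 0.025, seed = 1L) {
  check_graph_nonempty(g)
  d <- assert_scalar_int(d, "d")
  order <- assert_scalar_int(order, "order")
  stopifnot(order %in% 1:3)
  if (order == 3L && d %% 2 != 0)
    stop("order 3 needs an even dimension d (concatenated d/2 halves)",
         call. = FALSE)
  seed <- assert_scalar_int(seed, "seed", min = 0)
  de <- directed_edges(g)

  train1 <- function(dd, ord, sd) {
    fit <- cpp_line_train(as.integer(de$src), as.integer(de$dst),
                          as.numeric(de$weight), de$n, dd, ord,
                          as.integer(negativeSamples), as.integer(epochs),
                          learningRate, sd)
    fit$u
  }
  v <- if (order == 3L) {
    cbind(train1(d %/% 2, 1L, stageSeed(seed, "line-o1")),
          train1(d %/% 2, 2L, stageSeed(seed, "line-o2")))
  } else {
    train1(d, order, stageSeed(seed, paste0("line-o", order)))
  }
  rownames(v) <- g@nodes$id
  new_embedding("LINE", v, seed = seed,
                params = list(d = d, order = order,
                              negativeSamples = negativeSamples,
                              epochs = epochs, learningRate = learningRate))
}

## noise distribution used by LINE / skip-gram negatives
line_noise_dist <- function(g) {
  deg <- nodeDegrees(g)^0.75
  deg / sum(deg)
}

#' LINE objectives (reference implementation for small graphs)
#'
#' Computes the first-order objective
#' `O1 = -sum_E w_ij log sigmoid(u_i . u_j)` (undirected edges counted
#' once) or the second-order negative-sampling surrogate
#' `O2 = -sum_dirE w_ij [log sigmoid(u'_j . u_i) +
#'   K * sum_n P(n) log sigmoid(-u'_n . u_i)]`
#' with noise distribution `P(n) ~ degree^0.75` and `K = negativeSamples`,
#' the expectation form of the quantity the SGD trainer optimizes. Dense in
#' the node count; intended for analytic-gradient verification and for
#' monitoring convergence on small graphs.
#'
#' @param g a [HeteroGraph-class]
#' @param u vertex vector matrix (nodes x d, rows in graph node order)
#' @param order 1 or 2
#' @param uctx context vector matrix (required for order 2)
#' @param negativeSamples K in the surrogate, default 5
#' @return numeric scalar
#' @export
lineObjective <- function(g, u, order = 1L, uctx = NULL, negativeSamples = 5L) {
  de <- directed_edges(g)
  if (order == 1L) {
    keep <- de$src < de$dst # each undirected edge once
    i <- de$src[keep] + 1L; j <- de$dst[keep] + 1L
    dots <- rowSums(u[i, , drop = FALSE] * u[j, , drop = FALSE])
    -sum(de$weight[keep] * log(sigmoid(dots)))
  } else {
    stopifnot(!is.null(uctx))
    P <- line_noise_dist(g)
    i <- de$src + 1L; j <- de$dst + 1L
    pos <- log(sigmoid(rowSums(u[i, , drop = FALSE] * uctx[j, , drop = FALSE])))
    ## neg[i] = sum_n P(n) log sigmoid(-uctx_n . u_i), shared per source node
    dots_all <- u %*% t(uctx)           # n x n
    neg_per_node <- as.numeric(log(sigmoid(-dots_all)) %*% P)
    -sum(de$weight * (pos + negativeSamples * neg_per_node[i]))
  }
}

#' Analytic gradients of the LINE objectives
#'
#' Gradient of [lineObjective()] with respect to the vertex matrix `u` and
#' (order 2) the context matrix `uctx`.
#'
#' @inheritParams lineObjective
#' @return list with elements `u` and (order 2) `uctx`
#' @export
lineGradient <- function(g, u, order = 1L, uctx = NULL, negativeSamples = 5L) {
  de <- directed_edges(g)
  n <- de$n
  gu <- matrix(0, n, ncol(u))
  if (order == 1L) {
    keep <- de$src < de$dst
    i <- de$src[keep] + 1L; j <- de$dst[keep] + 1L; w <- de$weight[keep]
    s <- sigmoid(rowSums(u[i, , drop = FALSE] * u[j, , drop = FALSE]))
    coef <- -w * (1 - s)
    for (e in seq_along(i)) {
      gu[i[e], ] <- gu[i[e], ] + coef[e] * u[j[e], ]
      gu[j[e], ] <- gu[j[e], ] + coef[e] * u[i[e], ]
    }
    return(list(u = gu))
  }
  stopifnot(!is.null(uctx))
  P <- line_noise_dist(g)
  gc_ <- matrix(0, n, ncol(u))
  i <- de$src + 1L; j <- de$dst + 1L; w <- de$weight
  s_pos <- sigmoid(rowSums(u[i, , drop = FALSE] * uctx[j, , drop = FALSE]))
  s_all <- sigmoid(u %*% t(uctx))       # n x n: sigma(uctx_n . u_i) at [i, n]
  ## total positive-edge weight leaving each node
  w_out <- as.numeric(tapply(w, factor(i, levels = seq_len(n)), sum))
  w_out[is.na(w_out)] <- 0
  for (e in seq_along(i)) {
    gu[i[e], ] <- gu[i[e], ] - w[e] * (1 - s_pos[e]) * uctx[j[e], ]
    gc_[j[e], ] <- gc_[j[e], ] - w[e] * (1 - s_pos[e]) * u[i[e], ]
  }
  ## noise terms: per source i, K * w_out_i * sum_n P(n) sigma_in uctx_n
  gu <- gu + negativeSamples * (w_out * s_all) %*% (P * uctx)
  ## per context m: K * P(m) * sum_i w_out_i sigma_im u_i
  gc_ <- gc_ + negativeSamples * P * t(s_all) %*% (w_out * u)
  list(u = gu, uctx = gc_)
}
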