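#' @include AllClasses.R AllGenerics.R utils.R
NULL

## Euclidean projection of v onto the probability simplex (Duchi et al. style
## sort-and-threshold rule).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

## Minimize ||x - t(Xn) %*% w||^2 + reg * ||w||^2 over the simplex by
## accelerated projected gradient. Convex QP; k is small (<= ~10) so exact
## convergence is cheap. Returns the weight vector over the k neighbors.
solve_lns_weights <- function(Xn, x, reg, max_iter = 2000, tol = 1e-12) {
  k <- nrow(Xn)
  G <- Xn %*% t(Xn) + diag(reg, k)
  cvec <- as.numeric(Xn %*% x)
  L <- 2 * max(colSums(abs(G)))            # bound on the gradient Lipschitz constant
  w <- rep(1 / k, k)
  z <- w
  tprev <- 1
  for (it in seq_len(max_iter)) {
    grad <- 2 * (G %*% z - cvec)
    w_new <- project_simplex(as.numeric(z - grad / L))
    tcur <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    z <- w_new + ((tprev - 1) / tcur) * (w_new - w)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
    tprev <- tcur
  }
  w
}

#' Linear-neighborhood similarity (LNS) matrix from feature vectors
#'
#' For each node i, finds its `neighborhoodSize` nearest nodes in feature
#' space (Euclidean distance) and computes non-negative reconstruction
#' weights summing to 1 that minimize
#' `||x_i - sum_j w_ij x_j||^2 + regularizer * ||w_i||^2`.
#' Weights outside the neighborhood are 0. The regularizer keeps the local
#' Gram matrix well-posed even with duplicated feature rows.
#'
#' @param features numeric matrix, one row per node, rownames = ids
#' @param neighborhoodSize number of nearest neighbors reconstructed from
#'   (default 10, matching the top-10 linking rule)
#' @param regularizer non-negative ridge term, default 1e-6
#' @return n x n similarity matrix with zero diagonal; row i holds node i's
#'   reconstruction weights and sums to 1
#' @export
lnsSimilarity <- function(features, neighborhoodSize = 10, regularizer = 1e-6) {
  stopifnot(is.matrix(features), all(is.finite(features)))
  k <- assert_scalar_int(neighborhoodSize, "neighborhoodSize", min = 1)
  stopifnot(is.numeric(regularizer), regularizer >= 0)
  n <- nrow(features)
  if (n < k + 1)
    stop(sprintf("need at least neighborhoodSize + 1 = %d nodes, got %d",
                 k + 1, n), call. = FALSE)
  ids <- rownames(features) %||% as.character(seq_len(n))

  ## squared Euclidean distances via the Gram expansion
  sq <- rowSums(features^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(features)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- D2[i, ]
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]             # stable: ties broken by index
    w <- solve_lns_weights(features[nb, , drop = FALSE], features[i, ], regularizer)
    W[i, nb] <- w
  }
  W
}

#' Sparsify a similarity matrix to each node's top-k positive neighbors
#'
#' Per source node, keeps the `k` largest strictly positive weights (fewer
#' if fewer are positive). Ties at the k-th weight are broken by
#' lexicographic target id for determinism.
#'
#' @param sim square similarity matrix with id dimnames (rows = sources)
#' @param k maximum retained neighbors per source, default 10
#' @return data.frame with columns `source`, `target`, `weight`
#' @export
topkGraph <- function(sim, k = 10) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  k <- assert_scalar_int(k, "k", min = 1)
  ids <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
  out <- vector("list", nrow(sim))
  for (i in seq_len(nrow(sim))) {
    w <- sim[i, ]
    pos <- which(w > 0)
    if (!length(pos)) next
    ord <- pos[order(-w[pos], ids[pos])]
    keep <- ord[seq_len(min(k, length(ord)))]
    out[[i]] <- data.frame(source = ids[i], target = ids[keep],
                           weight = unname(w[keep]))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(source = character(), target = character(),
                      weight = numeric())
  rownames(res) <- NULL
  res
}

#' Write a similarity edge list as 3-column TSV
#' @param edges data.frame from [topkGraph()]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeSimEdges <- function(edges, file) {
  utils::write.table(edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a similarity edge list written by [writeSimEdges()]
#' @param file TSV path with columns source, target, weight
#' @return data.frame
#' @export
readSimEdges <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "weight") %in% names(df)))
  df
}
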