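#' @include embed-common.R
NULL

#' GraRep embedding: k-step transition factorization
#'
#' For each step `s = 1..kMax`, forms the s-step transition matrix `A^s`
#' (`A = D^-1 S`), the log-shifted matrix
#' `Y_s[i,j] = log(A^s[i,j] / sum_t A^s[t,j]) - log(beta)` with
#' `beta = negativeSamples / N` (N = number of undirected edges), clips
#' negative entries to 0, and factorizes `Y_s` by truncated SVD into
#' `d/kMax` dimensions scaled by the square roots of the singular values.
#' The `kMax` blocks are concatenated. Deterministic (no seed).
#'
#' @param g a [HeteroGraph-class] without isolated nodes
#' @param d total embedding dimension, divisible by `kMax` (default 128)
#' @param kMax maximum transition order (default 4)
#' @param negativeSamples the lambda of the NCE shift (default 5)
#' @return an [EmbeddingMatrix-class] with method `"GraRep"`
#' @export
grarepEmbed <- function(g, d = 128L, kMax = 4L, negativeSamples = 5L) {
  check_graph_nonempty(g)
  d <- assert_scalar_int(d, "d")
  kMax <- assert_scalar_int(kMax, "kMax")
  if (d %% kMax != 0)
    stop(sprintf("d = %d is not divisible by kMax = %d", d, kMax), call. = FALSE)
  m <- d %/% kMax
  A <- transitionMatrix(g)
  n <- nrow(A)
  if (m > n)
    stop(sprintf("per-order dimension d/kMax = %d exceeds node count %d", m, n),
         call. = FALSE)
  beta <- negativeSamples / nrow(g@edges)

  blocks <- vector("list", kMax)
  Ak <- diag(n)
  for (s in seq_len(kMax)) {
    Ak <- Ak %*% A
    colsum <- colSums(Ak)
    Y <- log(sweep(Ak, 2, colsum, "/")) - log(beta)
    Y[!is.finite(Y)] <- 0      # log(0) cells: treated as maximally shifted-out
    Y[Y < 0] <- 0              # clip negatives before factorization
    sv <- svd(Y, nu = m, nv = 0)
    blocks[[s]] <- sv$u %*% diag(sqrt(sv$d[seq_len(m)]), m)
  }
  v <- do.call(cbind, blocks)
  rownames(v) <- g@nodes$id
  new_embedding("GraRep", v,
                params = list(d = d, kMax = kMax,
                              negativeSamples = negativeSamples, beta = beta))
}
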