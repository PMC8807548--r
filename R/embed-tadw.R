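#' @include embed-common.R
NULL

## loss of the text-associated factorization:
## ||M - t(W) H T||_F^2 + (lambda/2) (||W||_F^2 + ||H||_F^2)
tadw_loss <- function(M, W, H, Tm, lambda) {
  R <- M - t(W) %*% H %*% Tm
  sum(R^2) + (lambda / 2) * (sum(W^2) + sum(H^2))
}

#' TADW embedding: text-associated matrix factorization
#'
#' Factorizes `M = (A + A^2) / 2` (A the transition matrix) as
#' `M ~ t(W) H T` where `T` is a reduced text-feature matrix, by exact
#' alternating ridge least squares on the loss
#' `||M - t(W) H T||_F^2 + (lambda/2)(||W||_F^2 + ||H||_F^2)`,
#' so the loss is non-increasing across updates. The per-node output is
#' the concatenation of the node's `W` column and its `H T` column, giving
#' dimension `d = 2k` with factor rank `k = d/2`.
#'
#' Text features are the 94-dimensional union vectors of the sequence
#' module; columns are unit-normalized and SVD-reduced to `fT` rows.
#' miRNA nodes have no collected sequence: `mirnaText` selects whether they
#' receive the mean text vector (default), zeros, or are excluded from the
#' TADW embedding altogether.
#'
#' @param g a [HeteroGraph-class] without isolated nodes
#' @param text numeric matrix of node text features (rows named by id; must
#'   cover every lncRNA and mRNA node)
#' @param d embedding dimension (even), default 256
#' @param lambda regularization weight, default 0.1
#' @param iterations alternating update sweeps, default 20
#' @param fT reduced text dimension, default 64
#' @param mirnaText `"mean"`, `"zeros"` or `"exclude"`
#' @param seed integer seed (random factor initialization)
#' @return an [EmbeddingMatrix-class] with method `"TADW"`; the recorded
#'   loss trajectory is in `@params$loss`
#' @export
tadwEmbed <- function(g, text, d = 256L, lambda = 0.1, iterations = 20L,
                      fT = 64L, mirnaText = c("mean", "zeros", "exclude"),
                      seed = 1L) {
  check_graph_nonempty(g)
  d <- assert_scalar_int(d, "d")
  if (d %% 2 != 0) stop("TADW dimension d must be even (output = [W; HT])",
                        call. = FALSE)
  k <- d %/% 2
  mirnaText <- match.arg(mirnaText)
  seed <- assert_scalar_int(seed, "seed", min = 0)
  iterations <- assert_scalar_int(iterations, "iterations")
  stopifnot(is.matrix(text), !is.null(rownames(text)))

  types <- nodeTypes(g)
  ids <- nodeIds(g)
  need <- ids[types != "miRNA"]
  missing_ids <- setdiff(need, rownames(text))
  if (length(missing_ids))
    stop("text features missing for typed node(s): ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)

  embed_ids <- if (mirnaText == "exclude") need else ids
  ## full text matrix over embedded nodes
  Tfull <- matrix(0, length(embed_ids), ncol(text),
                  dimnames = list(embed_ids, colnames(text)))
  have <- intersect(embed_ids, rownames(text))
  Tfull[have, ] <- text[have, , drop = FALSE]
  if (mirnaText == "mean") {
    ## only miRNA nodes without supplied text receive the imputed mean
    mir <- setdiff(embed_ids[types[embed_ids] == "miRNA"], rownames(text))
    if (length(mir))
      Tfull[mir, ] <- matrix(colMeans(text[need, , drop = FALSE]),
                             length(mir), ncol(text), byrow = TRUE)
  }

  A <- transitionMatrix(g)
  M <- (A + A %*% A) / 2
  sel <- match(embed_ids, ids)
  M <- M[sel, sel, drop = FALSE]
  nV <- length(embed_ids)

  ## column-normalized text (features x nodes), SVD-reduced to fT rows
  Tt <- t(Tfull)
  cn <- sqrt(colSums(Tt^2)); cn[cn == 0] <- 1
  Tt <- sweep(Tt, 2, cn, "/")
  fT <- min(fT, nrow(Tt), ncol(Tt))
  sv <- svd(Tt, nu = fT, nv = 0)
  Tm <- t(sv$u) %*% Tt                   # fT x |V|

  kk <- min(k, nV)
  if (kk < k)
    stop(sprintf("factor rank d/2 = %d exceeds node count %d", k, nV),
         call. = FALSE)
  W <- with_seed(stageSeed(seed, "tadw-W"),
                 matrix(stats::runif(k * nV, -0.5, 0.5) / k, k, nV))
  H <- with_seed(stageSeed(seed, "tadw-H"),
                 matrix(stats::runif(k * fT, -0.5, 0.5) / k, k, fT))

  ## tiny Tikhonov floor keeps the alternating solves well-posed when
  ## lambda = 0 and the factor rank exceeds rank(M)
  ridge <- lambda / 2 + 1e-10
  loss <- numeric(2 * iterations)
  for (it in seq_len(iterations)) {
    ## W-step: ridge LS, columns of M' regressed on Z = H T
    Z <- H %*% Tm
    W <- solve(Z %*% t(Z) + diag(ridge, k), Z %*% t(M))
    loss[2 * it - 1] <- tadw_loss(M, W, H, Tm, lambda)
    ## H-step: Sylvester system (W W') H (T T') + (lambda/2) H = W M T'
    e1 <- eigen(W %*% t(W), symmetric = TRUE)
    e2 <- eigen(Tm %*% t(Tm), symmetric = TRUE)
    B <- t(e1$vectors) %*% (W %*% M %*% t(Tm)) %*% e2$vectors
    denom <- outer(pmax(e1$values, 0), pmax(e2$values, 0)) + ridge
    H <- e1$vectors %*% (B / denom) %*% t(e2$vectors)
    loss[2 * it] <- tadw_loss(M, W, H, Tm, lambda)
  }

  v <- cbind(t(W), t(H %*% Tm))
  rownames(v) <- embed_ids
  new_embedding("TADW", v, seed = seed,
                params = list(d = d, lambda = lambda, iterations = iterations,
                              fT = fT, mirnaText = mirnaText, loss = loss))
}
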