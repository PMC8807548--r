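mk_emb <- function(ids, d, seed, method = "m") {
  set.seed(seed)
  v <- matrix(rnorm(length(ids) * d), length(ids), d,
              dimnames = list(ids, NULL))
  new("EmbeddingMatrix", method = method, vectors = v,
      seed = NA_integer_, params = list())
}

test_that("weighted average reduces to the mean under equal weights", {
  ids <- sprintf("n%02d", 1:20)
  embs <- list(a = mk_emb(ids, 16, 1), b = mk_emb(ids, 16, 2),
               c = mk_emb(ids, 16, 3), d = mk_emb(ids, 16, 4))
  w_eq <- c(a = 0.8, b = 0.8, c = 0.8, d = 0.8)
  fused <- weightedAverage(embs, w_eq)
  manual <- Reduce(`+`, lapply(embs, embeddingVectors)) / 4
  expect_equal(embeddingVectors(fused), manual, tolerance = 1e-12)
  # idempotence: identical inputs return themselves for any weights
  same <- list(a = embs$a, b = embs$a, c = embs$a, d = embs$a)
  fused2 <- weightedAverage(same, c(a = 0.9, b = 0.6, c = 0.7, d = 0.95))
  expect_equal(embeddingVectors(fused2), embeddingVectors(embs$a),
               tolerance = 1e-12)
})

test_that("weighted average matches direct elementwise evaluation", {
  ids <- sprintf("n%02d", 1:20)
  for (seed in 1:5) {
    set.seed(100 + seed)
    embs <- lapply(1:4, function(i) mk_emb(ids, 16, seed * 10 + i))
    names(embs) <- paste0("m", 1:4)
    w <- setNames(runif(4, 0.5, 1), names(embs))
    fused <- weightedAverage(embs, w)
    direct <- (w[1] * embeddingVectors(embs[[1]]) +
               w[2] * embeddingVectors(embs[[2]]) +
               w[3] * embeddingVectors(embs[[3]]) +
               w[4] * embeddingVectors(embs[[4]])) / sum(w)
    expect_equal(embeddingVectors(fused), direct, tolerance = 1e-12)
    # invariance to a common positive rescaling of the weights
    fused_scaled <- weightedAverage(embs, w * 0.37)
    expect_equal(embeddingVectors(fused_scaled), embeddingVectors(fused),
                 tolerance = 1e-12)
    # coordinatewise convex-hull containment
    stack <- simplify2array(lapply(embs, embeddingVectors))
    expect_true(all(embeddingVectors(fused) >= apply(stack, 1:2, min) - 1e-12))
    expect_true(all(embeddingVectors(fused) <= apply(stack, 1:2, max) + 1e-12))
  }
})

test_that("dimension mismatches are rejected with the offending methods", {
  ids <- letters[1:5]
  embs <- list(x = mk_emb(ids, 8, 1), y = mk_emb(ids, 12, 2))
  expect_error(weightedAverage(embs, c(x = 0.9, y = 0.9)), "x=8")
  expect_error(fuseBaseline(embs, "average"), "mismatch")
  # concatenate tolerates different dims
  cc <- fuseBaseline(embs, "concatenate")
  expect_equal(dim(cc), c(5, 20))
})

test_that("concatenate stacks blocks in input order; average = equal weights", {
  ids <- sprintf("n%02d", 1:12)
  embs <- list(p = mk_emb(ids, 8, 5), q = mk_emb(ids, 8, 6))
  cc <- fuseBaseline(embs, "concatenate")
  expect_equal(embeddingVectors(cc)[, 1:8], embeddingVectors(embs$p))
  expect_equal(embeddingVectors(cc)[, 9:16], embeddingVectors(embs$q))
  av <- fuseBaseline(embs, "average")
  wa <- weightedAverage(embs, c(p = 0.5, q = 0.5))
  expect_equal(embeddingVectors(av), embeddingVectors(wa), tolerance = 1e-12)
  # averaging identical embeddings is the identity
  av2 <- fuseBaseline(list(a = embs$p, b = embs$p), "average")
  expect_equal(embeddingVectors(av2), embeddingVectors(embs$p))
})

test_that("AUC weights: perfect method ~ 1, shuffled method ~ 0.5", {
  # build a pair dataset and two synthetic 'embeddings': one encodes the
  # label in its vectors (perfectly informative), one is pure noise
  set.seed(42)
  n_l <- 24; n_m <- 24
  lnc <- sprintf("L%02d", 1:n_l); mrna <- sprintf("M%02d", 1:n_m)
  blk <- function(i) i %% 2
  # positives are exactly the same-block pairs
  grid <- expand.grid(lnc = lnc, mrna = mrna, stringsAsFactors = FALSE)
  pos <- grid[blk(match(grid$lnc, lnc)) == blk(match(grid$mrna, mrna)), ]
  ds <- buildPairDataset(pos, lnc, mrna, seed = 3)
  d <- 6
  # informative: coordinate 1 carries the node's block
  v <- matrix(rnorm((n_l + n_m) * d, sd = 0.05), n_l + n_m, d,
              dimnames = list(c(lnc, mrna), NULL))
  v[, 1] <- blk(c(seq_len(n_l), seq_len(n_m))) + rnorm(n_l + n_m, sd = 0.05)
  perfect <- new("EmbeddingMatrix", method = "good", vectors = v,
                 seed = NA_integer_, params = list())
  noise <- mk_emb(c(lnc, mrna), d, 7, method = "noise")
  w <- aucWeights(list(good = perfect, noise = noise), ds, cvFolds = 3,
                  seed = 5, params = list(nrounds = 60, maxDepth = 3))
  expect_gt(fusionAuc(w)[["good"]], 0.9)
  expect_lt(abs(fusionAuc(w)[["noise"]] - 0.5), 0.18)
  # identical inputs + identical seeds give identical weights
  w2 <- aucWeights(list(good = perfect, noise = noise), ds, cvFolds = 3,
                   seed = 5, params = list(nrounds = 60, maxDepth = 3))
  expect_identical(fusionAuc(w), fusionAuc(w2))
})

test_that("AUC weights never touch the independent partition", {
  set.seed(9)
  lnc <- sprintf("L%02d", 1:20); mrna <- sprintf("M%02d", 1:20)
  pos <- data.frame(lnc = rep(lnc, 2), mrna = c(mrna, rev(mrna)))
  ds <- buildPairDataset(pos, lnc, mrna, seed = 11)
  emb <- mk_emb(c(lnc, mrna), 6, 13)
  w1 <- aucWeights(list(m = emb), ds, cvFolds = 3, seed = 15,
                   params = list(nrounds = 30, maxDepth = 2))
  # corrupt the independent partition's labels: weights must not change
  pr <- pairTable(ds)
  pr$label[pr$partition == "independent"] <-
    1L - pr$label[pr$partition == "independent"]
  ds2 <- new("PairDataset", pairs = pr, seed = 11L)
  w2 <- aucWeights(list(m = emb), ds2, cvFolds = 3, seed = 15,
                   params = list(nrounds = 30, maxDepth = 2))
  expect_identical(fusionAuc(w1), fusionAuc(w2))
})
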