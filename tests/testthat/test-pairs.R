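test_that("negative sampling returns the forced complement when exhausted", {
  pos <- data.frame(lnc = c("L1", "L2"), mrna = c("M1", "M2"))
  for (seed in 1:5) {
    neg <- sampleNegatives(pos, c("L1", "L2"), c("M1", "M2"), seed = seed)
    expect_setequal(paste(neg$lnc, neg$mrna), c("L1 M2", "L2 M1"))
  }
})

test_that("negative sampling is seed-reproducible and avoids positives", {
  set.seed(1)
  lnc <- sprintf("L%02d", 1:10); mrna <- sprintf("M%02d", 1:10)
  pos <- data.frame(lnc = sample(lnc, 20, TRUE), mrna = sample(mrna, 20, TRUE))
  pos <- unique(pos)
  n1 <- sampleNegatives(pos, lnc, mrna, seed = 5)
  n2 <- sampleNegatives(pos, lnc, mrna, seed = 5)
  expect_identical(n1, n2)
  n3 <- sampleNegatives(pos, lnc, mrna, seed = 6)
  expect_false(identical(n1, n3))
  for (nn in list(n1, n3)) {
    expect_equal(nrow(nn), nrow(pos))
    expect_length(intersect(paste(nn$lnc, nn$mrna),
                            paste(pos$lnc, pos$mrna)), 0)
    expect_false(anyDuplicated(paste(nn$lnc, nn$mrna)) > 0)
  }
})

test_that("negative sampling is uniform over the complement", {
  # 10x10 grid, 20 positives: every unknown pair should appear with
  # frequency 20/80 across resamples (3 binomial SEs; scaled-down count)
  lnc <- sprintf("L%02d", 1:10); mrna <- sprintf("M%02d", 1:10)
  set.seed(2)
  grid <- expand.grid(lnc = lnc, mrna = mrna, stringsAsFactors = FALSE)
  pos <- grid[sample(100, 20), ]
  B <- 600
  counts <- integer(0)
  for (b in 1:B) {
    neg <- sampleNegatives(pos, lnc, mrna, seed = 1000 + b)
    counts <- c(counts, paste(neg$lnc, neg$mrna))
  }
  tab <- table(factor(counts,
                      levels = setdiff(paste(grid$lnc, grid$mrna),
                                       paste(pos$lnc, pos$mrna))))
  p <- 20 / 80
  se <- sqrt(p * (1 - p) / B)
  expect_true(all(abs(as.numeric(tab) / B - p) < 4 * se))
})

test_that("insufficient complement raises an informative error", {
  pos <- expand.grid(lnc = c("L1", "L2"), mrna = c("M1", "M2"),
                     stringsAsFactors = FALSE)
  pos <- pos[1:3, ]
  expect_error(sampleNegatives(pos, c("L1", "L2"), c("M1", "M2"), seed = 1),
               "complement too small")
})

test_that("5/6 split of 12 balanced pairs gives exactly 10 + 2, stratified", {
  labeled <- data.frame(lnc = sprintf("L%d", 1:12),
                        mrna = sprintf("M%d", 1:12),
                        label = rep(c(0L, 1L), 6))
  ds <- splitTrainIndependent(labeled, 5 / 6, seed = 1)
  pr <- pairTable(ds)
  expect_equal(sum(pr$partition == "train"), 10)
  expect_equal(sum(pr$partition == "independent"), 2)
  expect_equal(sum(pr$partition == "train" & pr$label == 1), 5)
  expect_equal(sum(pr$partition == "independent" & pr$label == 1), 1)
  expect_error(splitTrainIndependent(labeled, 1), "trainFraction")
})

test_that("split partitions are disjoint and exhaustive (600 random pairs)", {
  set.seed(3)
  labeled <- unique(data.frame(lnc = sample(sprintf("L%03d", 1:40), 900, TRUE),
                               mrna = sample(sprintf("M%03d", 1:40), 900, TRUE)))
  labeled <- labeled[1:600, ]
  labeled$label <- rep(c(0L, 1L), 300)
  ds <- splitTrainIndependent(labeled, 5 / 6, seed = 4)
  pr <- pairTable(ds)
  key <- paste(pr$lnc, pr$mrna)
  tr <- key[pr$partition == "train"]; ind <- key[pr$partition == "independent"]
  expect_length(intersect(tr, ind), 0)
  expect_setequal(c(tr, ind), paste(labeled$lnc, labeled$mrna))
  expect_equal(length(tr), 500)
})

test_that("pair features are the lncRNA block followed by the mRNA block", {
  v <- rbind(L1 = c(1, 2), M1 = c(3, 4), M2 = c(5, 6))
  emb <- new("EmbeddingMatrix", method = "t", vectors = v,
             seed = NA_integer_, params = list())
  f <- pairFeatures(emb, data.frame(lnc = "L1", mrna = "M1"))
  expect_equal(unname(f[1, ]), c(1, 2, 3, 4))
  # order sensitivity is intentional
  f_swap <- pairFeatures(emb, data.frame(lnc = "M1", mrna = "L1"))
  expect_false(identical(unname(f[1, ]), unname(f_swap[1, ])))
  expect_error(pairFeatures(emb, data.frame(lnc = "L1", mrna = "MX")), "MX")
})

test_that("slicing the feature block recovers the lncRNA matrix rows", {
  set.seed(5)
  ids <- c(sprintf("L%02d", 1:8), sprintf("M%02d", 1:8))
  v <- matrix(rnorm(16 * 5), 16, 5, dimnames = list(ids, NULL))
  emb <- new("EmbeddingMatrix", method = "t", vectors = v,
             seed = NA_integer_, params = list())
  pr <- data.frame(lnc = sample(ids[1:8], 20, TRUE),
                   mrna = sample(ids[9:16], 20, TRUE))
  f <- pairFeatures(emb, pr)
  expect_equal(dim(f), c(20, 10))
  expect_equal(unname(f[, 1:5]), unname(v[pr$lnc, ]))
  expect_equal(unname(f[, 6:10]), unname(v[pr$mrna, ]))
  # width 2d holds for the alternative combinations' documented widths
  expect_equal(ncol(pairFeatures(emb, pr, combine = "hadamard")), 5)
  expect_equal(ncol(pairFeatures(emb, pr, combine = "mean")), 5)
})
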