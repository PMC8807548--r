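test_that("kfoldSplit stratifies exactly and covers the input", {
  y <- rep(c(1L, 0L), 5)
  f <- kfoldSplit(y, k = 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == 1), 1)
    expect_equal(sum(f == k & y == 0), 1)
  }
  expect_error(kfoldSplit(c(1L, 1L, 0L), k = 5), "per class")
})

test_that("kfold per-class counts match a counting oracle on 1,000 pairs", {
  set.seed(2)
  y <- sample(rep(c(0L, 1L), c(520, 480)))
  f <- kfoldSplit(y, k = 5, seed = 3)
  expect_setequal(unique(f), 1:5)
  for (cl in 0:1) {
    per <- table(f[y == cl])
    expect_lte(max(per) - min(per), 1)
    expect_equal(sum(per), sum(y == cl))
  }
  # deterministic given the seed
  expect_identical(f, kfoldSplit(y, k = 5, seed = 3))
})

test_that("a perfect classifier scores 1.0 on all seven metrics", {
  y <- rep(c(0L, 1L), 10)
  rep_ <- computeMetrics(y, as.numeric(y))
  expect_equal(unname(metricSummary(rep_)), rep(1, 7))
})

test_that("a perfectly inverted classifier gives AUC 0 and MCC -1", {
  rep_ <- computeMetrics(c(1L, 0L), c(0.4, 0.6))
  s <- metricSummary(rep_)
  expect_equal(s[["AUC"]], 0)
  expect_equal(s[["MCC"]], -1)
  expect_error(computeMetrics(c(1, 1), c(0.2, 0.8)), "both classes")
})

test_that("rank-based AUC equals the all-pairs oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    y <- sample(rep(c(0L, 1L), c(25, 35)))
    # include ties by rounding half the scores
    sc <- round(runif(n), sample(1:2, 1))
    got <- metricSummary(computeMetrics(y, sc))[["AUC"]]
    expect_equal(got, oracle_auc(y, sc), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to joint permutation of labels and scores", {
  set.seed(4)
  y <- sample(rep(c(0L, 1L), 30))
  sc <- runif(60)
  perm <- sample(60)
  expect_equal(metricSummary(computeMetrics(y, sc)),
               metricSummary(computeMetrics(y[perm], sc[perm])))
})

test_that("degenerate thresholding is reported with flags, not errors", {
  y <- c(0L, 1L, 0L, 1L)
  rep_ <- computeMetrics(y, c(0.1, 0.2, 0.3, 0.4), threshold = 0.9)
  expect_equal(metricSummary(rep_)[["PREC"]], 0)
  expect_true(any(grepl("precision", rep_@flags)))
})

test_that("AUPR of a perfect ranking is 1 and respects prevalence bounds", {
  y <- rep(c(1L, 0L), c(10, 30))
  sc <- c(runif(10, 0.8, 1), runif(30, 0, 0.5))
  expect_equal(metricSummary(computeMetrics(y, sc))[["AUPR"]], 1)
  # random scores: AUPR stays above ~prevalence for large n
  set.seed(5)
  y2 <- sample(rep(c(0L, 1L), c(150, 50)))
  s2 <- runif(200)
  expect_gt(metricSummary(computeMetrics(y2, s2))[["AUPR"]], 0.15)
})

test_that("crossValidate reports per-fold metrics and is reproducible", {
  set.seed(6)
  lnc <- sprintf("L%02d", 1:15); mrna <- sprintf("M%02d", 1:15)
  pos <- expand.grid(lnc = lnc[1:8], mrna = mrna[1:8],
                     stringsAsFactors = FALSE)[sample(64, 40), ]
  ds <- buildPairDataset(pos, lnc, mrna, seed = 7)
  v <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(c(lnc, mrna), NULL))
  v[c(lnc[1:8], mrna[1:8]), 1] <- v[c(lnc[1:8], mrna[1:8]), 1] + 3
  emb <- new("EmbeddingMatrix", method = "t", vectors = v,
             seed = NA_integer_, params = list())
  r1 <- crossValidate(emb, ds, k = 3, seed = 8,
                      params = list(nrounds = 25, maxDepth = 2))
  r2 <- crossValidate(emb, ds, k = 3, seed = 8,
                      params = list(nrounds = 25, maxDepth = 2))
  expect_identical(metricSummary(r1), metricSummary(r2))
  expect_equal(dim(r1@perFold), c(3, 7))
  expect_equal(unname(metricSummary(r1)), unname(colMeans(r1@perFold)))
  expect_gt(metricSummary(r1)[["AUC"]], 0.6)  # block signal is learnable
})

test_that("independent evaluation rejects overlapping partitions", {
  set.seed(9)
  lnc <- sprintf("L%02d", 1:12); mrna <- sprintf("M%02d", 1:12)
  pos <- data.frame(lnc = lnc, mrna = mrna)
  ds <- buildPairDataset(pos, lnc, mrna, seed = 10)
  v <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(c(lnc, mrna), NULL))
  emb <- new("EmbeddingMatrix", method = "t", vectors = v,
             seed = NA_integer_, params = list())
  tr <- pairTable(ds, "train")
  m <- trainClassifier(pairFeatures(emb, tr), tr$label, seed = 11,
                       params = list(nrounds = 10))
  rep_ <- evaluateIndependent(m, emb, ds)
  expect_equal(rep_@n, nrow(pairTable(ds, "independent")))
  # an overlapping pair cannot even be constructed: class validity blocks it
  pr <- pairTable(ds)
  bad <- rbind(pr, transform(pr[pr$partition == "train", ][1, ],
                             partition = "independent"))
  expect_error(new("PairDataset", pairs = bad, seed = 1L), "duplicated")
})

test_that("masking removes exactly the requested lnc-mrna edges", {
  g <- tiny_graph()
  g2 <- maskPairEdges(g, data.frame(lnc = "L1", mrna = "M1"))
  ed <- edgeTable(g2)
  expect_equal(nrow(ed), nrow(edgeTable(g)) - 1)
  expect_false(any(ed$src == "L1" & ed$dst == "M1" & ed$layer == "lnc-mrna"))
  # other layers untouched
  expect_equal(sum(ed$layer == "lnc-sim"), 1)
})
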