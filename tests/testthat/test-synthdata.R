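test_that("config validation enforces the stated world's constraints", {
  expect_error(synthConfig(nLnc = 2, nBlocks = 4), ">= nBlocks")
  expect_error(synthConfig(blockBias = matrix(0, 4, 4)), "degenerate")
  cfg <- synthConfig()
  expect_equal(cfg$nLnc, 120L)
  expect_equal(cfg$nMrna, 150L)
  expect_equal(cfg$nMirna, 40L)
  expect_equal(cfg$nBlocks, 4L)
  expect_equal(unname(cfg$withinProb), rep(0.25, 3))
  expect_equal(unname(cfg$crossProb), rep(0.02, 3))
  expect_equal(cfg$seqLenRange, c(200L, 400L))
})

test_that("a degenerate all-A composition yields all-A sequences", {
  cfg <- synthConfig(nLnc = 4, nMrna = 4, nMirna = 4, nBlocks = 1,
                     seqLenRange = c(20L, 30L),
                     blockBias = matrix(c(1, 0, 0, 0), 1), seed = 1)
  seqs <- rnaSequences(genSequences(cfg))
  expect_true(all(grepl("^A+$", seqs)))
})

test_that("sequence generation is seed-reproducible and block-balanced", {
  cfg <- synthConfig(nLnc = 12, nMrna = 12, nMirna = 4,
                     seqLenRange = c(50L, 80L), seed = 5)
  s1 <- genSequences(cfg); s2 <- genSequences(cfg)
  expect_identical(rnaSequences(s1), rnaSequences(s2))
  blocks <- attr(s1, "blocks")
  expect_equal(nrow(blocks), 28)
  expect_equal(unname(table(blocks$block[blocks$type == "lncRNA"])),
               rep(3L, 4), ignore_attr = TRUE)
})

test_that("empirical composition tracks the block bias (multinomial oracle)", {
  bias <- c(0.4, 0.1, 0.4, 0.1)
  cfg <- synthConfig(nLnc = 60, nMrna = 4, nMirna = 4, nBlocks = 1,
                     seqLenRange = c(300L, 300L),
                     blockBias = matrix(bias, 1), seed = 7)
  seqs <- genSequences(cfg)
  types <- nodeTypes(seqs)
  letters_all <- strsplit(paste(rnaSequences(seqs[types == "lncRNA"]),
                                collapse = ""), "")[[1]]
  n <- length(letters_all)
  for (i in 1:4) {
    p_hat <- mean(letters_all == c("A", "C", "G", "T")[i])
    se <- sqrt(bias[i] * (1 - bias[i]) / n)
    expect_lt(abs(p_hat - bias[i]), 4 * se)
  }
})

test_that("cross-block probability 0 plants strictly within-block edges", {
  cfg <- synthConfig(nLnc = 20, nMrna = 20, nMirna = 8,
                     seqLenRange = c(50L, 60L), withinProb = 0.5,
                     crossProb = 0, seed = 9)
  bl <- attr(genSequences(cfg), "blocks")
  inter <- genInteractions(cfg, bl)
  blk <- setNames(bl$block, bl$id)
  for (layer in inter) {
    if (nrow(layer))
      expect_true(all(blk[layer$a] == blk[layer$b]))
  }
  # saturation: probabilities (1, 1) give the complete bipartite layers
  cfg2 <- synthConfig(nLnc = 5, nMrna = 6, nMirna = 4,
                      seqLenRange = c(50L, 60L), withinProb = 1,
                      crossProb = 1, seed = 10)
  bl2 <- attr(genSequences(cfg2), "blocks")
  inter2 <- genInteractions(cfg2, bl2)
  expect_equal(nrow(inter2$lnc_mrna), 5 * 6)
  expect_equal(nrow(inter2$lnc_mirna), 5 * 4)
  expect_equal(nrow(inter2$mrna_mirna), 6 * 4)
})

test_that("edge inclusion frequency matches the planted Bernoulli rates", {
  # scaled-down replicate count; fixed pair tracked across reseeded draws
  base <- synthConfig(nLnc = 12, nMrna = 12, nMirna = 4,
                      seqLenRange = c(50L, 60L), withinProb = 0.2,
                      crossProb = 0.02, seed = 1)
  bl <- attr(genSequences(base), "blocks")
  same_pair <- c("LNC001", "MRNA001")   # same block (both block 1)
  diff_pair <- c("LNC001", "MRNA002")   # different blocks
  B <- 400
  hits_same <- 0; hits_diff <- 0
  for (b in 1:B) {
    cfg <- synthConfig(nLnc = 12, nMrna = 12, nMirna = 4,
                       seqLenRange = c(50L, 60L), withinProb = 0.2,
                       crossProb = 0.02, seed = 2000 + b)
    ii <- genInteractions(cfg, bl)$lnc_mrna
    key <- paste(ii$a, ii$b)
    hits_same <- hits_same + (paste(same_pair, collapse = " ") %in% key)
    hits_diff <- hits_diff + (paste(diff_pair, collapse = " ") %in% key)
  }
  se_w <- sqrt(0.2 * 0.8 / B); se_c <- sqrt(0.02 * 0.98 / B)
  expect_lt(abs(hits_same / B - 0.2), 3 * se_w)
  expect_lt(abs(hits_diff / B - 0.02), 3 * se_c)
})

test_that("realized lnc-mrna edge count sits near its expectation", {
  cfg <- synthConfig(seed = 11)
  bl <- attr(genSequences(cfg), "blocks")
  inter <- genInteractions(cfg, bl)
  A <- bl[bl$type == "lncRNA", ]; B <- bl[bl$type == "mRNA", ]
  same <- outer(A$block, B$block, "==")
  probs <- ifelse(same, cfg$withinProb[["lnc-mrna"]],
                  cfg$crossProb[["lnc-mrna"]])
  mu <- sum(probs); sdv <- sqrt(sum(probs * (1 - probs)))
  expect_lt(abs(nrow(inter$lnc_mrna) - mu), 4 * sdv)
})

test_that("the benchmark bundle round-trips through every reader", {
  tmp <- withr::local_tempdir()
  cfg <- synthConfig(nLnc = 10, nMrna = 12, nMirna = 5,
                     seqLenRange = c(60L, 90L), seed = 13)
  bench <- genBenchmark(cfg, tmp)
  expect_true(all(file.exists(unlist(bench$paths))))
  lnc <- readRnaFasta(bench$paths$lnc_fasta, "lncRNA")
  expect_equal(length(lnc), 10)
  lm <- readInteractionTSV(bench$paths$lnc_mrna)
  expect_equal(names(lm), c("a", "b"))
  truth <- read.delim(bench$paths$truth)
  expect_equal(nrow(truth), 10 + 12 + 5)
  # within-block sequences are more LNS-similar than cross-block ones:
  # with 10 nodes in 4 blocks a node has ~1.6 same-block partners among 9,
  # so the chance level of a top-3 edge landing within-block is ~0.18
  feats <- unionFeatures(lnc)
  sim <- lnsSimilarity(feats, neighborhoodSize = 5)
  ek <- topkGraph(sim, 3)
  blk <- setNames(truth$block, truth$id)
  frac_within <- mean(blk[ek$source] == blk[ek$target])
  expect_gt(frac_within, 0.35)   # ~2x chance
})
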