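test_that("a walk on a single edge alternates between the endpoints", {
  g <- assembleHeteroGraph(lncMrna = data.frame(a = "L1", b = "M1"))
  wc <- node2vecWalks(g, n = 2, l = 10, seed = 1)
  w <- corpusWalks(wc)
  for (r in seq_len(nrow(w))) {
    ids <- walkIds(wc)[w[r, ]]
    expect_true(all(ids == rep_len(c(ids[1], setdiff(c("L1", "M1"), ids[1])), 10)))
  }
})

test_that("consecutive walk nodes are always graph neighbors", {
  g <- small_benchmark()$graph
  wc <- node2vecWalks(g, n = 1, l = 15, p = 0.5, q = 2, seed = 3)
  S <- adjacencyMatrix(g, sparse = FALSE)
  w <- corpusWalks(wc)
  for (r in sample(nrow(w), 20)) {
    steps <- w[r, ]
    for (t in 1:(length(steps) - 1))
      expect_gt(S[steps[t], steps[t + 1]], 0)
  }
})

test_that("p = q = 1 on an unweighted graph walks uniformly over neighbors", {
  # star-free 4-cycle L1-M1-L2-M2: every node has exactly 2 neighbors
  g <- assembleHeteroGraph(
    lncMrna = data.frame(a = c("L1", "L2", "L1", "L2"),
                         b = c("M1", "M1", "M2", "M2")))
  wc <- node2vecWalks(g, n = 220, l = 60, seed = 5)
  w <- corpusWalks(wc)
  ids <- walkIds(wc)
  # for every current node, the next node must be ~uniform over its 2 neighbors
  cur <- as.vector(w[, 1:59]); nxt <- as.vector(w[, 2:60])
  expect_gt(length(cur), 50000)
  for (v in ids) {
    sel <- cur == match(v, ids)
    tab <- table(factor(ids[nxt[sel]]))
    freqs <- as.numeric(tab) / sum(tab)
    expect_equal(length(freqs), 2)
    expect_true(all(abs(freqs - 0.5) < 0.02))
  }
})

test_that("empirical biases match the closed form on triangle-plus-pendant", {
  # triangle L1-M1-R1 (all connected) with pendant M2 attached to M1...
  # types: lnc-mrna L1-M1, lnc-mirna L1-R1, mrna-mirna M1-R1, mrna-sim M1-M2
  g <- assembleHeteroGraph(
    mrnaSim = data.frame(source = "M1", target = "M2", weight = 1),
    lncMrna = data.frame(a = "L1", b = "M1"),
    lncMirna = data.frame(a = "L1", b = "R1"),
    mrnaMirna = data.frame(a = "M1", b = "R1"))
  p <- 0.25; q <- 4
  wc <- node2vecWalks(g, n = 60, l = 60, p = p, q = q, seed = 7)
  w <- corpusWalks(wc)
  ids <- walkIds(wc)
  # closed-form next-step distribution from cur = M1 given prev = L1:
  # candidates L1 (back, 1/p), R1 (neighbor of prev, 1), M2 (non-neighbor, 1/q)
  biases <- c(L1 = 1 / p, R1 = 1, M2 = 1 / q)
  probs <- biases / sum(biases)
  # harvest empirical transitions (prev = L1, cur = M1)
  nxt <- character()
  for (r in seq_len(nrow(w))) {
    s <- ids[w[r, ]]
    # positions t where s[t] == M1 and s[t-1] == L1, next is s[t+1]
    hit <- which(s == "M1")
    hit <- hit[hit > 1 & hit < length(s)]
    hit <- hit[s[hit - 1] == "L1"]
    nxt <- c(nxt, s[hit + 1])
  }
  expect_gt(length(nxt), 500)
  emp <- table(factor(nxt, levels = names(probs))) / length(nxt)
  for (v in names(probs)) {
    se <- sqrt(probs[[v]] * (1 - probs[[v]]) / length(nxt))
    expect_lt(abs(emp[[v]] - probs[[v]]), 3 * se + 1e-6)
  }
})

test_that("walk corpus and skip-gram are seed-reproducible", {
  g <- small_benchmark()$graph
  wc1 <- node2vecWalks(g, n = 2, l = 20, seed = 9)
  wc2 <- node2vecWalks(g, n = 2, l = 20, seed = 9)
  expect_identical(corpusWalks(wc1), corpusWalks(wc2))
  e1 <- skipgramEmbed(wc1, d = 8, epochs = 1, seed = 4)
  e2 <- skipgramEmbed(wc2, d = 8, epochs = 1, seed = 4)
  expect_identical(embeddingVectors(e1), embeddingVectors(e2))
  expect_error(skipgramEmbed(wc1, d = 8, window = 0), "window")
})

test_that("skip-gram separates two disconnected cliques", {
  # two 5-cliques realized as dense bipartite blocks (disconnected halves)
  lnc <- sprintf("L%d", 1:6); mrna <- sprintf("M%d", 1:6)
  cl1 <- expand.grid(a = lnc[1:3], b = mrna[1:3], stringsAsFactors = FALSE)
  cl2 <- expand.grid(a = lnc[4:6], b = mrna[4:6], stringsAsFactors = FALSE)
  g <- assembleHeteroGraph(lncMrna = rbind(cl1, cl2))
  e <- node2vecEmbed(g, d = 8, n = 20, l = 30, epochs = 5, seed = 11)
  v <- embeddingVectors(e)
  v <- v / sqrt(rowSums(v^2))
  cs <- tcrossprod(v)
  block <- ifelse(rownames(v) %in% c(lnc[1:3], mrna[1:3]), 1, 2)
  same <- outer(block, block, "==") & upper.tri(cs)
  diff_ <- outer(block, block, "!=") & upper.tri(cs)
  expect_gt(mean(cs[same]), mean(cs[diff_]))
})

test_that("an alternating walk makes its two nodes nearest neighbors", {
  # two disjoint edges: walks alternate within each pair, so co-occurring
  # nodes must end up as each other's highest-cosine neighbor
  g <- assembleHeteroGraph(lncMrna = data.frame(a = c("L1", "L2"),
                                                b = c("M1", "M2")))
  wc <- node2vecWalks(g, n = 50, l = 40, seed = 13)
  e <- skipgramEmbed(wc, d = 6, epochs = 5, seed = 13)
  v <- embeddingVectors(e)
  v <- v / sqrt(rowSums(v^2))
  cs <- tcrossprod(v)
  for (pair in list(c("L1", "M1"), c("L2", "M2"))) {
    others <- setdiff(rownames(v), pair[1])
    expect_equal(others[which.max(cs[pair[1], others])], pair[2])
  }
})
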