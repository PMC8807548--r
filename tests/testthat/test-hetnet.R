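test_that("filterInteractions dedups and restricts to allowed sets", {
  raw <- data.frame(a = c("L1", "L1", "L2"), b = c("M1", "M1", "M2"))
  out <- filterInteractions(raw, allowedA = "L1", allowedB = c("M1", "M2"))
  expect_equal(out, data.frame(a = "L1", b = "M1"))
  # universal allowed sets -> deduplicated input
  out2 <- filterInteractions(raw)
  expect_equal(nrow(out2), 2)
})

test_that("filterInteractions equals a set-comprehension oracle", {
  set.seed(1)
  raw <- data.frame(a = sample(sprintf("A%02d", 1:20), 1000, TRUE),
                    b = sample(sprintf("B%02d", 1:20), 1000, TRUE))
  for (seed in 1:3) {
    set.seed(seed)
    aa <- sample(sprintf("A%02d", 1:20), 8)
    bb <- sample(sprintf("B%02d", 1:20), 12)
    got <- filterInteractions(raw, aa, bb)
    want <- unique(raw[raw$a %in% aa & raw$b %in% bb, ])
    want <- want[order(want$a, want$b), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("assemble builds the hand-checkable micrograph correctly", {
  g <- tiny_graph()
  expect_equal(nrow(edgeTable(g)), 6)
  expect_setequal(nodeIds(g), c("L1", "L2", "M1", "M2", "R1"))
  S <- adjacencyMatrix(g, sparse = FALSE)
  expect_true(isSymmetric(S))
  # hand-counted weighted degrees
  expect_equal(nodeDegrees(g)[["L1"]], 0.6 + 1 + 1)  # L2-sim + M1 + R1
  expect_equal(nodeDegrees(g)[["R1"]], 2)            # L1 + M2
  expect_equal(totalWeight(g), 0.6 + 0.8 + 4)
  expect_equal(sum(nodeDegrees(g)), 2 * totalWeight(g))
})

test_that("empty similarity layers leave the interaction union", {
  g <- assembleHeteroGraph(NULL, NULL,
                           lncMrna = data.frame(a = "L1", b = "M1"),
                           lncMirna = data.frame(a = "L1", b = "R1"),
                           mrnaMirna = data.frame(a = "M1", b = "R1"))
  expect_equal(nrow(edgeTable(g)), 3)
  expect_setequal(edgeTable(g)$layer, c("lnc-mrna", "lnc-mirna", "mrna-mirna"))
})

test_that("degrees and total weight match brute-force recomputation", {
  g <- random_graph(seed = 3, weighted = TRUE)
  ed <- edgeTable(g)
  deg_brute <- setNames(numeric(length(nodeIds(g))), nodeIds(g))
  for (r in seq_len(nrow(ed))) {
    deg_brute[ed$src[r]] <- deg_brute[ed$src[r]] + ed$weight[r]
    deg_brute[ed$dst[r]] <- deg_brute[ed$dst[r]] + ed$weight[r]
  }
  expect_equal(nodeDegrees(g), deg_brute)
  expect_equal(totalWeight(g), sum(ed$weight))
})

test_that("assemble rejects type conflicts and shared id spaces", {
  expect_error(assembleHeteroGraph(
    lncMrna = data.frame(a = "X1", b = "M1"),
    lncMirna = data.frame(a = "M1", b = "R1")), "disjoint")
})

test_that("assemble is invariant to edge-list row order", {
  mk <- function(perm) {
    lm <- data.frame(a = c("L1", "L2", "L1"), b = c("M1", "M2", "M2"))[perm, ]
    assembleHeteroGraph(lncMrna = lm,
                        lncMirna = data.frame(a = "L1", b = "R1"),
                        mrnaMirna = data.frame(a = "M2", b = "R1"))
  }
  g1 <- mk(1:3); g2 <- mk(3:1)
  expect_equal(edgeTable(g1), edgeTable(g2))
  expect_equal(nodeIds(g1), nodeIds(g2))
})

test_that("the lnc-mrna layer is bipartite between its two types", {
  g <- random_graph(seed = 5)
  ed <- edgeTable(g)
  ty <- nodeTypes(g)
  sel <- ed$layer == "lnc-mrna"
  expect_true(all(ty[ed$src[sel]] == "lncRNA"))
  expect_true(all(ty[ed$dst[sel]] == "mRNA"))
})

test_that("transition matrix rows are one-step probabilities", {
  # path graph 1-2-3 realized as L1-M1-L2 with unit weights
  g <- assembleHeteroGraph(lncMrna = data.frame(a = c("L1", "L2"),
                                                b = c("M1", "M1")))
  A <- transitionMatrix(g)
  expect_equal(A["M1", c("L1", "L2")], c(L1 = 0.5, L2 = 0.5))
  expect_equal(unname(rowSums(A)), rep(1, 3), tolerance = 1e-12)
})

test_that("A and its powers match path-probability enumeration", {
  g <- random_graph(n_lnc = 10, n_mrna = 14, n_mirna = 6, seed = 7,
                    weighted = TRUE)
  A <- transitionMatrix(g)
  expect_equal(unname(rowSums(A)), rep(1, nrow(A)), tolerance = 1e-12)
  # independent oracle: adjacency lists + recursive path enumeration
  ed <- edgeTable(g)
  ids <- nodeIds(g)
  nbr <- lapply(ids, function(v) {
    sel <- ed$src == v | ed$dst == v
    data.frame(to = ifelse(ed$src[sel] == v, ed$dst[sel], ed$src[sel]),
               w = ed$weight[sel])
  })
  names(nbr) <- ids
  step_prob <- function(v, s) {
    # probability vector over end nodes of s-step walks from v
    out <- setNames(numeric(length(ids)), ids)
    d <- sum(nbr[[v]]$w)
    for (r in seq_len(nrow(nbr[[v]]))) {
      p <- nbr[[v]]$w[r] / d
      if (s == 1) out[nbr[[v]]$to[r]] <- out[nbr[[v]]$to[r]] + p
      else out <- out + p * step_prob(nbr[[v]]$to[r], s - 1)
    }
    out
  }
  As <- A
  for (s in 1:3) {
    if (s > 1) As <- As %*% A
    for (v in ids[c(1, 8, 20)])
      expect_equal(As[v, ], step_prob(v, s), tolerance = 1e-10)
  }
})

test_that("isolated nodes are dropped with a warning before transition", {
  g <- new("HeteroGraph",
           nodes = data.frame(id = c("L1", "L2", "M1"),
                              type = c("lncRNA", "lncRNA", "mRNA")),
           edges = data.frame(src = "L1", dst = "M1", weight = 1,
                              layer = "lnc-mrna"))
  expect_error(transitionMatrix(g), "zero-degree")
  expect_warning(g2 <- dropIsolatedNodes(g), "isolated")
  expect_setequal(nodeIds(g2), c("L1", "M1"))
  expect_silent(transitionMatrix(g2))
  # a graph with no isolated nodes passes through untouched
  expect_silent(dropIsolatedNodes(g2))
})

test_that("graph TSV round trip preserves the graph", {
  tmp <- withr::local_tempdir()
  g <- random_graph(seed = 11, weighted = TRUE)
  writeHeteroGraph(g, file.path(tmp, "n.tsv"), file.path(tmp, "e.tsv"))
  g2 <- readHeteroGraph(file.path(tmp, "n.tsv"), file.path(tmp, "e.tsv"))
  expect_equal(nodeIds(g2), nodeIds(g))
  expect_equal(edgeTable(g2)$weight, edgeTable(g)$weight, tolerance = 1e-12)
  expect_equal(edgeTable(g2)[c("src", "dst", "layer")],
               edgeTable(g)[c("src", "dst", "layer")])
})
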