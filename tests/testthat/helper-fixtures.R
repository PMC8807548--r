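# shared fixtures and independent oracles; everything is generated in code

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force sliding-window k-mer counter, independent of the implementation
oracle_kmer <- function(seq, k = 3) {
  kmers <- sort(apply(expand.grid(rep(list(c("A","C","G","T")), k))[, k:1, drop = FALSE],
                      1, paste, collapse = ""))
  counts <- setNames(numeric(length(kmers)), kmers)
  n <- nchar(seq)
  for (i in 1:(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / (n - k + 1)
}

# brute-force position-scanning CTD oracle
oracle_ctd <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  nuc <- c("A", "C", "G", "T")
  comp <- sapply(nuc, function(x) sum(ch == x) / n)
  pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
  trans <- setNames(numeric(6), pairs)
  for (i in 1:(n - 1)) {
    two <- sort(c(ch[i], ch[i + 1]))
    if (two[1] != two[2])
      trans[paste0(two[1], two[2])] <- trans[paste0(two[1], two[2])] + 1
  }
  trans <- trans / (n - 1)
  dist <- numeric(0)
  for (x in nuc) {
    pos <- which(ch == x)
    if (!length(pos)) { dist <- c(dist, rep(0, 5)); next }
    cnt <- length(pos)
    picks <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(q) {
      idx <- ceiling(q * cnt)
      if (idx < 1) idx <- 1
      pos[idx] / n
    })
    dist <- c(dist, picks)
  }
  unname(c(comp, trans, dist))
}

# O(n^2) all-pairs AUC oracle with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# tiny hand-assembled heterogeneous graph used across modules:
# L1-L2 (lnc-sim 0.6), M1-M2 (mrna-sim 0.8), L1-M1, L2-M2, L1-R1, M2-R1
tiny_graph <- function() {
  assembleHeteroGraph(
    lncSim = data.frame(source = "L1", target = "L2", weight = 0.6),
    mrnaSim = data.frame(source = "M1", target = "M2", weight = 0.8),
    lncMrna = data.frame(a = c("L1", "L2"), b = c("M1", "M2")),
    lncMirna = data.frame(a = "L1", b = "R1"),
    mrnaMirna = data.frame(a = "M2", b = "R1"))
}

# connected random typed graph for property tests
random_graph <- function(n_lnc = 6, n_mrna = 7, n_mirna = 3, p = 0.5,
                         seed = 1, weighted = FALSE) {
  set.seed(seed)
  lnc <- sprintf("L%02d", 1:n_lnc)
  mrna <- sprintf("M%02d", 1:n_mrna)
  mir <- sprintf("R%02d", 1:n_mirna)
  rnd_pairs <- function(a, b) {
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g[runif(nrow(g)) < p, ]
  }
  lm <- rnd_pairs(lnc, mrna)
  # force connectivity: chain every node through the lnc-mrna layer
  lm <- unique(rbind(lm, data.frame(a = rep_len(lnc, max(n_lnc, n_mrna)),
                                    b = rep_len(mrna, max(n_lnc, n_mrna)))))
  li <- unique(rbind(rnd_pairs(lnc, mir),
                     data.frame(a = rep_len(lnc, n_mirna), b = mir)))
  mi <- rnd_pairs(mrna, mir)
  wts <- function(df) if (weighted) cbind(df, weight = runif(nrow(df), 0.2, 1)) else df
  sim_l <- wts(data.frame(source = lnc[-1], target = lnc[1]))
  if (!weighted) sim_l$weight <- 0.5
  assembleHeteroGraph(lncSim = sim_l, mrnaSim = NULL, lncMrna = lm,
                      lncMirna = li, mrnaMirna = mi)
}

# small synthetic benchmark shared by the slower tests (built once)
.bench_cache <- new.env(parent = emptyenv())
small_benchmark <- function() {
  if (!is.null(.bench_cache$b)) return(.bench_cache$b)
  cfg <- synthConfig(nLnc = 30L, nMrna = 36L, nMirna = 12L,
                     seqLenRange = c(120L, 200L), seed = 42L)
  seqs <- genSequences(cfg)
  blocks <- attr(seqs, "blocks")
  inter <- genInteractions(cfg, blocks)
  types <- nodeTypes(seqs)
  fl <- unionFeatures(seqs[types == "lncRNA"])
  fm <- unionFeatures(seqs[types == "mRNA"])
  g <- assembleHeteroGraph(
    topkGraph(lnsSimilarity(fl), 10), topkGraph(lnsSimilarity(fm), 10),
    inter$lnc_mrna, inter$lnc_mirna, inter$mrna_mirna)
  g <- suppressWarnings(dropIsolatedNodes(g))
  .bench_cache$b <- list(cfg = cfg, seqs = seqs, blocks = blocks,
                         inter = inter, text = rbind(fl, fm), graph = g)
  .bench_cache$b
}
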