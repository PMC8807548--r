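#' @include AllClasses.R AllGenerics.R seqfeat.R hetnet.R utils.R
NULL

## default per-block nucleotide compositions: each block biased toward a
## different pair of nucleotides so sequence composition carries block
## identity without being degenerate
default_block_bias <- function(nBlocks) {
  base <- rbind(c(0.40, 0.20, 0.25, 0.15),
                c(0.15, 0.40, 0.20, 0.25),
                c(0.25, 0.15, 0.40, 0.20),
                c(0.20, 0.25, 0.15, 0.40))
  m <- base[((seq_len(nBlocks) - 1) %% 4) + 1, , drop = FALSE]
  ## extra blocks beyond 4 get progressively flattened copies
  extra <- (seq_len(nBlocks) - 1) %/% 4
  m <- (m + extra * 0.25) / (1 + extra)
  colnames(m) <- NUC
  m
}

#' Configuration of the planted-block synthetic benchmark
#'
#' Describes a three-type network whose block structure couples sequence
#' composition and interaction probability: nodes in the same block are
#' compositionally similar AND preferentially interacting, so both the
#' similarity layers and the interaction layers carry recoverable signal.
#' Defaults are the benchmark's stated world: 120 lncRNAs, 150 mRNAs, 40
#' miRNAs, 4 blocks, within/cross edge probabilities 0.25/0.02, sequence
#' lengths 200-400 nt (miRNAs fixed at 22 nt).
#'
#' @param nLnc,nMrna,nMirna node counts per type (each >= `nBlocks`)
#' @param nBlocks number of planted blocks
#' @param seqLenRange length-2 range of lncRNA/mRNA sequence lengths
#' @param withinProb,crossProb edge probability for same-block /
#'   different-block cross-type pairs; scalars or length-3 vectors ordered
#'   (lnc-mrna, lnc-mirna, mrna-mirna)
#' @param blockBias `nBlocks x 4` matrix of per-block ACGT weights
#'   (rows need not be normalized), or NULL for the built-in biases
#' @param mirnaLen miRNA sequence length, default 22
#' @param seed master seed of the benchmark
#' @return a validated `synthConfig` list
#' @export
synthConfig <- function(nLnc = 120L, nMrna = 150L, nMirna = 40L,
                        nBlocks = 4L, seqLenRange = c(200L, 400L),
                        withinProb = 0.25, crossProb = 0.02,
                        blockBias = NULL, mirnaLen = 22L, seed = 1L) {
  nLnc <- assert_scalar_int(nLnc, "nLnc"); nMrna <- assert_scalar_int(nMrna, "nMrna")
  nMirna <- assert_scalar_int(nMirna, "nMirna")
  nBlocks <- assert_scalar_int(nBlocks, "nBlocks")
  if (min(nLnc, nMrna, nMirna) < nBlocks)
    stop("every node-type count must be >= nBlocks", call. = FALSE)
  stopifnot(length(seqLenRange) == 2, seqLenRange[1] >= 3,
            seqLenRange[2] >= seqLenRange[1])
  rec3 <- function(x, nm) {
    stopifnot(length(x) %in% c(1, 3), all(x >= 0), all(x <= 1))
    stats::setNames(rep_len(as.numeric(x), 3),
                    c("lnc-mrna", "lnc-mirna", "mrna-mirna"))
  }
  withinProb <- rec3(withinProb); crossProb <- rec3(crossProb)
  if (is.null(blockBias)) blockBias <- default_block_bias(nBlocks)
  blockBias <- as.matrix(blockBias)
  stopifnot(nrow(blockBias) == nBlocks, ncol(blockBias) == 4)
  if (any(rowSums(blockBias) <= 0))
    stop("degenerate block composition: zero-sum weight row", call. = FALSE)
  structure(list(nLnc = nLnc, nMrna = nMrna, nMirna = nMirna,
                 nBlocks = nBlocks, seqLenRange = as.integer(seqLenRange),
                 withinProb = withinProb, crossProb = crossProb,
                 blockBias = blockBias / rowSums(blockBias),
                 mirnaLen = assert_scalar_int(mirnaLen, "mirnaLen", min = 3),
                 seed = assert_scalar_int(seed, "seed", min = 0)),
            class = "synthConfig")
}

## balanced deterministic block assignment: node i -> block (i-1) %% B + 1
synth_blocks <- function(cfg) {
  mk <- function(prefix, n, type) data.frame(
    id = sprintf("%s%03d", prefix, seq_len(n)), type = type,
    block = ((seq_len(n) - 1) %% cfg$nBlocks) + 1L)
  rbind(mk("LNC", cfg$nLnc, "lncRNA"),
        mk("MRNA", cfg$nMrna, "mRNA"),
        mk("MIR", cfg$nMirna, "miRNA"))
}

#' Generate block-biased synthetic RNA sequences
#'
#' Every node is assigned a block (balanced round-robin within its type);
#' its sequence is drawn i.i.d. from the block's nucleotide composition,
#' with length uniform in `seqLenRange` (miRNAs at the fixed `mirnaLen`).
#' Seed-reproducible.
#'
#' @param cfg a [synthConfig()]
#' @return an [RnaSet-class]; the block truth table is in
#'   `attr(, "blocks")` (columns id, type, block)
#' @export
genSequences <- function(cfg) {
  stopifnot(inherits(cfg, "synthConfig"))
  blocks <- synth_blocks(cfg)
  seqs <- with_seed(stageSeed(cfg$seed, "sequences"), {
    vapply(seq_len(nrow(blocks)), function(i) {
      len <- if (blocks$type[i] == "miRNA") cfg$mirnaLen
             else cfg$seqLenRange[1] +
               sample.int(cfg$seqLenRange[2] - cfg$seqLenRange[1] + 1L, 1L) - 1L
      paste(sample(NUC, len, replace = TRUE,
                   prob = cfg$blockBias[blocks$block[i], ]), collapse = "")
    }, character(1))
  })
  out <- rnaSet(blocks$id, blocks$type, seqs)
  attr(out, "blocks") <- blocks
  out
}

#' Generate the three planted-block interaction layers
#'
#' Each cross-type pair is included independently with the within-block
#' probability if the two nodes share a block, else the cross-block
#' probability. Seed-reproducible.
#'
#' @param cfg a [synthConfig()]
#' @param blocks block truth table (id, type, block), e.g. from
#'   `attr(genSequences(cfg), "blocks")`
#' @return named list of data.frames (`lnc_mrna`, `lnc_mirna`,
#'   `mrna_mirna`), each with columns a, b
#' @export
genInteractions <- function(cfg, blocks) {
  stopifnot(inherits(cfg, "synthConfig"))
  one_layer <- function(typeA, typeB, layer) {
    A <- blocks[blocks$type == typeA, ]
    B <- blocks[blocks$type == typeB, ]
    grid <- expand.grid(ia = seq_len(nrow(A)), ib = seq_len(nrow(B)))
    same <- A$block[grid$ia] == B$block[grid$ib]
    pp <- ifelse(same, cfg$withinProb[[layer]], cfg$crossProb[[layer]])
    keep <- with_seed(stageSeed(cfg$seed, paste0("layer-", layer)),
                      stats::runif(nrow(grid)) < pp)
    filterInteractions(data.frame(a = A$id[grid$ia][keep],
                                  b = B$id[grid$ib][keep]))
  }
  list(lnc_mrna = one_layer("lncRNA", "mRNA", "lnc-mrna"),
       lnc_mirna = one_layer("lncRNA", "miRNA", "lnc-mirna"),
       mrna_mirna = one_layer("mRNA", "miRNA", "mrna-mirna"))
}

#' Generate and write a complete synthetic benchmark bundle
#'
#' Writes every pipeline input: one FASTA per node type, three 2-column
#' interaction TSVs, the block truth table and the configuration (JSON).
#'
#' @param cfg a [synthConfig()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the in-memory objects (`sequences`,
#'   `interactions`, `blocks`) and the written `paths`
#' @export
genBenchmark <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- genSequences(cfg)
  blocks <- attr(seqs, "blocks")
  inter <- genInteractions(cfg, blocks)
  paths <- list(
    lnc_fasta = file.path(dir, "lncrna.fasta"),
    mrna_fasta = file.path(dir, "mrna.fasta"),
    mirna_fasta = file.path(dir, "mirna.fasta"),
    lnc_mrna = file.path(dir, "lnc_mrna.tsv"),
    lnc_mirna = file.path(dir, "lnc_mirna.tsv"),
    mrna_mirna = file.path(dir, "mrna_mirna.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json"))
  types <- nodeTypes(seqs)
  writeRnaFasta(seqs[types == "lncRNA"], paths$lnc_fasta)
  writeRnaFasta(seqs[types == "mRNA"], paths$mrna_fasta)
  writeRnaFasta(seqs[types == "miRNA"], paths$mirna_fasta)
  writeInteractionTSV(inter$lnc_mrna, paths$lnc_mrna)
  writeInteractionTSV(inter$lnc_mirna, paths$lnc_mirna)
  writeInteractionTSV(inter$mrna_mirna, paths$mrna_mirna)
  utils::write.table(blocks, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_json <- cfg
  cfg_json$blockBias <- apply(cfg$blockBias, 1, as.list)
  jsonlite::write_json(unclass(cfg_json), paths$config, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(sequences = seqs, interactions = inter, blocks = blocks,
                 paths = paths))
}
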