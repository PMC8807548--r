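#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Sample negative lncRNA-mRNA pairs uniformly from the unknown pairs
#'
#' Draws `|positives|` pairs without replacement, uniformly from the
#' complement of the known positives in `lncIds x mrnaIds` (the standard
#' 1:1 negative-sampling protocol; unknown pairs may of course contain
#' undiscovered positives, and no filter is applied).
#'
#' @param positives data.frame of known pairs (columns lnc, mrna, or first
#'   two columns)
#' @param lncIds,mrnaIds candidate id sets
#' @param seed integer seed; same seed, same sample
#' @return data.frame with columns `lnc`, `mrna`
#' @export
sampleNegatives <- function(positives, lncIds, mrnaIds, seed = 1L) {
  pos <- data.frame(lnc = as.character(positives[[1]]),
                    mrna = as.character(positives[[2]]))
  lncIds <- sort(unique(as.character(lncIds)))
  mrnaIds <- sort(unique(as.character(mrnaIds)))
  nl <- length(lncIds); nm <- length(mrnaIds)
  li <- match(pos$lnc, lncIds); mi <- match(pos$mrna, mrnaIds)
  if (anyNA(li) || anyNA(mi))
    stop("positives contain ids outside lncIds/mrnaIds", call. = FALSE)
  pos_idx <- unique((li - 1) * nm + mi)   # 1-based linear index
  total <- nl * nm
  n_needed <- nrow(pos)
  n_free <- total - length(pos_idx)
  if (n_free < n_needed)
    stop(sprintf(
      "complement too small: %d unknown pairs available, %d needed",
      n_free, n_needed), call. = FALSE)
  neg_idx <- with_seed(stageSeed(seed, "negatives"), {
    complement <- setdiff(seq_len(total), pos_idx)
    sample(complement, n_needed)
  })
  data.frame(lnc = lncIds[(neg_idx - 1) %/% nm + 1],
             mrna = mrnaIds[(neg_idx - 1) %% nm + 1])
}

#' Stratified train/independent split of labeled pairs
#'
#' Randomly assigns `trainFraction` of the pairs (default 5/6), stratified
#' by label, to the training partition; the remainder is the independent
#' set touched only by final evaluation.
#'
#' @param labeled data.frame with columns lnc, mrna, label (0/1)
#' @param trainFraction in (0, 1), default 5/6
#' @param seed integer seed
#' @return a [PairDataset-class]
#' @export
splitTrainIndependent <- function(labeled, trainFraction = 5 / 6, seed = 1L) {
  stopifnot(is.numeric(trainFraction), trainFraction > 0, trainFraction < 1)
  df <- data.frame(lnc = as.character(labeled$lnc),
                   mrna = as.character(labeled$mrna),
                   label = as.integer(labeled$label))
  partition <- rep(NA_character_, nrow(df))
  with_seed(stageSeed(seed, "split"), {
    for (cl in c(0L, 1L)) {
      idx <- which(df$label == cl)
      n_tr <- round(trainFraction * length(idx))
      if (n_tr < 1 || n_tr >= length(idx))
        stop(sprintf(
          "class %d has %d pairs: too few to stratify at fraction %.3f",
          cl, length(idx), trainFraction), call. = FALSE)
      tr <- sample(idx, n_tr)
      partition[tr] <- "train"
      partition[setdiff(idx, tr)] <- "independent"
    }
  })
  df$partition <- partition
  new("PairDataset", pairs = df, seed = as.integer(seed))
}

#' Build the labeled pair dataset: positives + 1:1 negatives + split
#'
#' @param positives data.frame of known lncRNA-mRNA pairs
#' @param lncIds,mrnaIds id universes for negative sampling
#' @param trainFraction train share, default 5/6
#' @param seed integer seed (drives sampling and splitting)
#' @return a [PairDataset-class]
#' @export
buildPairDataset <- function(positives, lncIds, mrnaIds,
                             trainFraction = 5 / 6, seed = 1L) {
  pos <- unique(data.frame(lnc = as.character(positives[[1]]),
                           mrna = as.character(positives[[2]])))
  neg <- sampleNegatives(pos, lncIds, mrnaIds, seed = seed)
  labeled <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
  splitTrainIndependent(labeled, trainFraction, seed = seed)
}

#' Pair feature vectors from an embedding
#'
#' The feature of pair (l, m) is the concatenation `vector(l) ++ vector(m)`
#' (width `2d`; the lncRNA block comes first and the asymmetry is
#' intentional). Element-wise alternatives are available for ablation.
#'
#' @param emb an [EmbeddingMatrix-class] covering every pair endpoint
#' @param pairs a [PairDataset-class] or a data.frame with columns lnc, mrna
#' @param combine `"concat"` (default), `"hadamard"` or `"mean"`
#' @return numeric matrix, one row per pair (input row order preserved)
#' @export
pairFeatures <- function(emb, pairs, combine = c("concat", "hadamard", "mean")) {
  combine <- match.arg(combine)
  pr <- if (is(pairs, "PairDataset")) pairTable(pairs) else as.data.frame(pairs)
  v <- embeddingVectors(emb)
  miss <- setdiff(unique(c(pr$lnc, pr$mrna)), rownames(v))
  if (length(miss))
    stop("no embedding vector for id(s): ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  L <- v[pr$lnc, , drop = FALSE]
  M <- v[pr$mrna, , drop = FALSE]
  out <- switch(combine,
    concat = cbind(L, M),
    hadamard = L * M,
    mean = (L + M) / 2)
  rownames(out) <- NULL
  out
}

#' Write a pair dataset as TSV
#' @param ds a [PairDataset-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writePairDataset <- function(ds, file) {
  utils::write.table(pairTable(ds), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a pair dataset written by [writePairDataset()]
#' @param file TSV path
#' @param seed seed to record on the object (informational)
#' @return a [PairDataset-class]
#' @export
readPairDataset <- function(file, seed = NA_integer_) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  df$lnc <- as.character(df$lnc); df$mrna <- as.character(df$mrna)
  new("PairDataset", pairs = df, seed = as.integer(seed))
}
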