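#' @include AllClasses.R AllGenerics.R utils.R
NULL

## canonical orders used throughout the feature blocks
KMER_K <- 3L
NUC <- c("A", "C", "G", "T")
NUC_PAIRS <- c("AC", "AG", "AT", "CG", "CT", "GT")
DIST_Q <- c(0, 0.25, 0.5, 0.75, 1)

## uppercase, map U -> T, and reject anything outside ACGT
clean_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, !is.na(seq))
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- unique(strsplit(s, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, NUC)
  if (length(bad))
    stop(sprintf("sequence contains non-ACGT character(s) after U->T mapping: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  s
}

#' k-mer relative frequencies of an RNA sequence
#'
#' Counts every length-`k` contiguous subsequence over the sequence's
#' sliding windows and divides by the window count, so the `4^k` entries
#' (fixed lexicographic A < C < G < T order) sum to 1. `U` is mapped to `T`
#' and case is folded before counting; any other character is an error.
#'
#' @param seq a single sequence string (length >= `k`)
#' @param k k-mer length, default 3
#' @return named numeric vector of length `4^k`
#' @examples
#' kmerFreq("ACGT")        # 0.5 at "ACG", 0.5 at "CGT"
#' @export
kmerFreq <- function(seq, k = KMER_K) {
  k <- assert_scalar_int(k, "k", min = 1)
  s <- clean_sequence(seq)
  if (nchar(s) < k)
    stop(sprintf("sequence length %d is shorter than k = %d", nchar(s), k),
         call. = FALSE)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), width = k)
  counts / (nchar(s) - k + 1)
}

#' Composition/transition/distribution (CTD) features of an RNA sequence
#'
#' The conventional 30-dimensional nucleotide CTD descriptor:
#' \itemize{
#'   \item composition (4): per-nucleotide frequency;
#'   \item transition (6): for each unordered pair \{x, y\}, the number of
#'     adjacent positions carrying the pair in either order, divided by
#'     `len - 1`;
#'   \item distribution (20): for each nucleotide, the 1-based sequence
#'     positions (divided by `len`) of its 1st, `ceil(25\% n)`-th,
#'     `ceil(50\% n)`-th, `ceil(75\% n)`-th and last occurrence among its
#'     `n` occurrences; all five slots are 0 when the nucleotide is absent.
#' }
#'
#' @param seq a single sequence string (length >= 2)
#' @return named numeric vector of length 30
#' @examples
#' ctdFeatures("ACAC")     # transition {A,C} = 1
#' @export
ctdFeatures <- function(seq) {
  s <- clean_sequence(seq)
  n <- nchar(s)
  if (n < 2)
    stop("CTD features need a sequence of length >= 2", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]

  comp <- vapply(NUC, function(x) sum(chars == x), numeric(1)) / n

  a <- chars[-n]; b <- chars[-1]
  key <- ifelse(a < b, paste0(a, b), paste0(b, a))
  trans <- vapply(NUC_PAIRS, function(pp) sum(key == pp & a != b), numeric(1)) / (n - 1)

  dist <- numeric(0)
  for (x in NUC) {
    pos <- which(chars == x)
    cnt <- length(pos)
    if (cnt == 0) {
      d <- rep(0, 5)
    } else {
      idx <- pmax(1L, ceiling(DIST_Q * cnt))
      d <- pos[idx] / n
    }
    names(d) <- paste0("dist_", x, "_", c("first", "q25", "q50", "q75", "last"))
    dist <- c(dist, d)
  }
  c(stats::setNames(comp, paste0("comp_", NUC)),
    stats::setNames(trans, paste0("trans_", NUC_PAIRS)),
    dist)
}

#' Union feature vectors: 3-mer frequencies ++ CTD
#'
#' Concatenates the 64 3-mer relative frequencies and the 30 CTD features
#' into the 94-dimensional union descriptor used for similarity computation
#' and as text features for the text-associated embedding.
#'
#' @param x a single sequence string, or an [RnaSet-class]
#' @return for a string, a named numeric vector of length 94; for an
#'   `RnaSet`, a numeric matrix (one row per sequence, rownames = ids)
#' @export
setGeneric("unionFeatures", function(x) standardGeneric("unionFeatures"))

#' @rdname unionFeatures
#' @export
setMethod("unionFeatures", "character", function(x) {
  stopifnot(length(x) == 1)
  c(kmerFreq(x), ctdFeatures(x))
})

#' @rdname unionFeatures
#' @export
setMethod("unionFeatures", "RnaSet", function(x) {
  seqs <- rnaSequences(x)
  out <- t(vapply(seqs, function(s) c(kmerFreq(s), ctdFeatures(s)), numeric(94)))
  rownames(out) <- names(seqs)
  out
})

#' Construct an RnaSet from character sequences
#'
#' Uppercases, maps `U` to `T` and validates the alphabet at ingest; any
#' other character is an error, never silently dropped.
#'
#' @param ids character ids, unique within each node type
#' @param nodeType character, each `"lncRNA"`, `"mRNA"` or `"miRNA"`
#'   (recycled if scalar)
#' @param sequences character vector of sequences
#' @return an [RnaSet-class]
#' @export
rnaSet <- function(ids, nodeType, sequences) {
  stopifnot(length(ids) == length(sequences))
  if (length(nodeType) == 1) nodeType <- rep(nodeType, length(ids))
  cleaned <- vapply(sequences, clean_sequence, character(1), USE.NAMES = FALSE)
  new("RnaSet",
      sequences = Biostrings::DNAStringSet(stats::setNames(cleaned, ids)),
      nodeType = nodeType)
}

#' Read RNA sequences from a FASTA file
#'
#' @param file path to a (possibly line-wrapped) multi-record FASTA file
#' @param nodeType node type assigned to every record
#' @return an [RnaSet-class]
#' @export
readRnaFasta <- function(file, nodeType) {
  stopifnot(nodeType %in% NODE_TYPES)
  raw <- Biostrings::readBStringSet(file)
  ids <- sub("\\s.*$", "", names(raw)) # FASTA id = first token of header
  rnaSet(ids, nodeType, as.character(raw))
}

#' Write an RnaSet to FASTA
#' @param x an [RnaSet-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeRnaFasta <- function(x, file) {
  stopifnot(is(x, "RnaSet"))
  Biostrings::writeXStringSet(x@sequences, file, width = 70)
  invisible(file)
}

#' Write a feature matrix as TSV (id column, then f0..f93)
#' @param features numeric matrix with rownames = ids
#' @param file output path
#' @return `file`, invisibly
#' @export
writeFeatureTable <- function(features, file) {
  df <- data.frame(id = rownames(features), features,
                   check.names = FALSE, row.names = NULL)
  colnames(df) <- c("id", paste0("f", seq_len(ncol(features)) - 1))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a feature matrix written by [writeFeatureTable()]
#' @param file TSV path
#' @return numeric matrix with rownames = ids
#' @export
readFeatureTable <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
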