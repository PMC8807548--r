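Package: lncTargetNet
Title: Predicting lncRNA Target Genes by Fused Heterogeneous Network Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate target genes (mRNAs) of long non-coding RNAs by
    link prediction on a five-layer heterogeneous network. Sequence k-mer and
    CTD descriptors feed linear-neighborhood similarity graphs for lncRNAs and
    mRNAs; these are merged with lncRNA-mRNA, lncRNA-miRNA and mRNA-miRNA
    interaction layers into one typed weighted graph. Four network
    representation learning methods (LINE, GraRep, node2vec with skip-gram,
    and text-associated matrix factorization) embed the nodes; the embeddings
    are fused by AUC-weighted averaging and lncRNA-mRNA pairs are scored with
    a gradient-boosted tree classifier. A planted-block synthetic benchmark
    generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'classify.R'
    'hetnet.R'
    'embed-common.R'
    'embed-grarep.R'
    'embed-line.R'
    'embed-node2vec.R'
    'embed-tadw.R'
    'pairs.R'
    'evaluate.R'
    'fuse.R'
    'seqfeat.R'
    'synthdata.R'
    'pipeline.R'
    'simnet.R'
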