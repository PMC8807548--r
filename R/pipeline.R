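#' @include AllClasses.R AllGenerics.R synthdata.R evaluate.R fuse.R
NULL

PIPELINE_STAGES <- c("synth", "features", "simnet", "hetnet", "embed",
                     "fuse", "train", "evaluate", "rank")

#' Default pipeline configuration
#'
#' All stage hyperparameters with their defaults: the tuned per-method
#' embedding settings, the common fusion dimension (128; weighted-average
#' fusion is only defined at one shared dimension), the 1:1 negative
#' sampling with 5/6 train fraction, 5-fold CV and the boosted-tree
#' classifier. The master `seed` fans out deterministically to every
#' stochastic stage via [stageSeed()].
#'
#' @param outDir run output directory
#' @param seed master seed
#' @return nested configuration list
#' @export
defaultConfig <- function(outDir = "run", seed = 1L) {
  list(
    outDir = outDir,
    seed = assert_scalar_int(seed, "seed", min = 0),
    synth = list(nLnc = 120L, nMrna = 150L, nMirna = 40L, nBlocks = 4L,
                 seqLenRange = c(200L, 400L), withinProb = 0.25,
                 crossProb = 0.02, mirnaLen = 22L),
    input = list(lncFasta = NULL, mrnaFasta = NULL, mirnaFasta = NULL,
                 lncMrna = NULL, lncMirna = NULL, mrnaMirna = NULL),
    simnet = list(neighborhoodSize = 10L, regularizer = 1e-6, topK = 10L),
    hetnet = list(interactionWeight = 1, binarizeSim = FALSE),
    embed = list(fusionDim = 128L,
                 methods = c("LINE", "GraRep", "node2vec", "TADW"),
                 line = list(order = 3L, negativeSamples = 5L, epochs = 5L,
                             learningRate = 0.025),
                 grarep = list(kMax = 4L, negativeSamples = 5L),
                 node2vec = list(n = 20L, l = 80L, p = 1, q = 1,
                                 window = 5L, negativeSamples = 5L,
                                 epochs = 5L, learningRate = 0.025),
                 tadw = list(lambda = 0.1, iterations = 20L, fT = 64L,
                             mirnaText = "mean")),
    pairs = list(trainFraction = 5 / 6),
    fuse = list(mode = "weighted", cvFolds = 5L),
    classify = list(algorithm = "xgboost", params = list()),
    evaluate = list(k = 5L, threshold = 0.5, maskTestEdges = FALSE,
                    perMethod = TRUE),
    rank = list(query = NULL, topN = 10L))
}

#' Validate a pipeline configuration
#'
#' Rejects unknown fields (with their path) and type-checks the key
#' values before any stage runs.
#'
#' @param cfg configuration list
#' @return the validated configuration, invisibly
#' @export
validateConfig <- function(cfg) {
  ref <- defaultConfig()
  check_names <- function(x, ref, path) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop(sprintf("unknown config field: %s%s", path, unknown[1]),
           call. = FALSE)
    for (nm in names(x))
      if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
          nm != "params" && is.list(x[[nm]]))
        check_names(x[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
  check_names(cfg, ref, "")
  if (is.null(cfg$outDir) || !is.character(cfg$outDir))
    stop("config field outDir must be a path string", call. = FALSE)
  assert_scalar_int(cfg$seed %||% 1L, "seed", min = 0)
  if (!all(cfg$embed$methods %in% c("LINE", "GraRep", "node2vec", "TADW")))
    stop("unknown config field: embed$methods entry", call. = FALSE)
  if (!cfg$fuse$mode %in% c("weighted", "concatenate", "average"))
    stop("config field fuse$mode must be weighted|concatenate|average",
         call. = FALSE)
  if (!cfg$classify$algorithm %in% ALGORITHMS)
    stop("config field classify$algorithm is not a known algorithm",
         call. = FALSE)
  invisible(cfg)
}

## merge user config over defaults (params lists replaced, not merged deep)
mergeConfig <- function(cfg) {
  base <- defaultConfig(outDir = cfg$outDir %||% "run", seed = cfg$seed %||% 1L)
  merged <- utils::modifyList(base, cfg)
  validateConfig(merged)
  merged
}

stage_paths <- function(cfg) {
  od <- cfg$outDir
  list(
    data = file.path(od, "data"),
    lnc_fasta = cfg$input$lncFasta %||% file.path(od, "data", "lncrna.fasta"),
    mrna_fasta = cfg$input$mrnaFasta %||% file.path(od, "data", "mrna.fasta"),
    mirna_fasta = cfg$input$mirnaFasta %||% file.path(od, "data", "mirna.fasta"),
    lnc_mrna = cfg$input$lncMrna %||% file.path(od, "data", "lnc_mrna.tsv"),
    lnc_mirna = cfg$input$lncMirna %||% file.path(od, "data", "lnc_mirna.tsv"),
    mrna_mirna = cfg$input$mrnaMirna %||% file.path(od, "data", "mrna_mirna.tsv"),
    feat_lnc = file.path(od, "features_lncRNA.tsv"),
    feat_mrna = file.path(od, "features_mRNA.tsv"),
    sim_lnc = file.path(od, "lnc_sim.tsv"),
    sim_mrna = file.path(od, "mrna_sim.tsv"),
    nodes = file.path(od, "nodes.tsv"),
    edges = file.path(od, "edges.tsv"),
    emb = function(m) file.path(od, sprintf("emb_%s.tsv", m)),
    pairs = file.path(od, "pairs.tsv"),
    weights = file.path(od, "fusion_weights.json"),
    emb_fused = file.path(od, "emb_fused.tsv"),
    model = file.path(od, "model.json"),
    metrics_json = file.path(od, "metrics.json"),
    metrics_tsv = file.path(od, "metrics.tsv"),
    manifest = file.path(od, "manifest.json"))
}

require_inputs <- function(paths, producer) {
  missing_p <- paths[!file.exists(paths)]
  if (length(missing_p))
    stop(sprintf("missing upstream artifact %s (produced by stage '%s')",
                 missing_p[1], producer), call. = FALSE)
}

manifest_update <- function(cfg, stage, inputs, outputs, elapsed) {
  p <- stage_paths(cfg)$manifest
  man <- if (file.exists(p)) jsonlite::read_json(p) else list()
  man[[stage]] <- list(
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])),
    seed = cfg$seed, wallTime = round(elapsed, 3),
    configHash = unname(tools::md5sum(
      tf <- {tf0 <- tempfile(); writeLines(
        jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE), tf0); tf0})))
  unlink(tf)
  jsonlite::write_json(man, p, auto_unbox = TRUE, null = "null")
  invisible(man)
}

## load the union text features of lncRNA + mRNA nodes (TADW input)
load_text_features <- function(p) {
  rbind(readFeatureTable(p$feat_lnc), readFeatureTable(p$feat_mrna))
}

build_graph_from_files <- function(cfg, p) {
  lm <- readInteractionTSV(p$lnc_mrna)
  ## database-protocol restriction: miRNA layers keep only endpoints that
  ## appear in the lncRNA-mRNA layer (and its induced miRNA set)
  li <- filterInteractions(readInteractionTSV(p$lnc_mirna), allowedA = lm$a)
  mi <- filterInteractions(readInteractionTSV(p$mrna_mirna),
                           allowedA = lm$b, allowedB = li$b)
  assembleHeteroGraph(
    lncSim = readSimEdges(p$sim_lnc), mrnaSim = readSimEdges(p$sim_mrna),
    lncMrna = lm, lncMirna = li, mrnaMirna = mi,
    interactionWeight = cfg$hetnet$interactionWeight,
    binarizeSim = cfg$hetnet$binarizeSim)
}

embed_one <- function(g, method, cfg, text, seed) {
  ep <- cfg$embed
  d <- ep$fusionDim
  switch(method,
    LINE = lineEmbed(g, d = d, order = ep$line$order,
                     negativeSamples = ep$line$negativeSamples,
                     epochs = ep$line$epochs,
                     learningRate = ep$line$learningRate,
                     seed = stageSeed(seed, "embed-LINE")),
    GraRep = grarepEmbed(g, d = d, kMax = ep$grarep$kMax,
                         negativeSamples = ep$grarep$negativeSamples),
    node2vec = node2vecEmbed(g, d = d, n = ep$node2vec$n, l = ep$node2vec$l,
                             p = ep$node2vec$p, q = ep$node2vec$q,
                             window = ep$node2vec$window,
                             negativeSamples = ep$node2vec$negativeSamples,
                             epochs = ep$node2vec$epochs,
                             learningRate = ep$node2vec$learningRate,
                             seed = stageSeed(seed, "embed-node2vec")),
    TADW = tadwEmbed(g, text, d = d, lambda = ep$tadw$lambda,
                     iterations = ep$tadw$iterations, fT = ep$tadw$fT,
                     mirnaText = ep$tadw$mirnaText,
                     seed = stageSeed(seed, "embed-TADW")))
}

#' Run one pipeline stage
#'
#' Stages: `synth` (write the synthetic benchmark), `features` (FASTA to
#' union feature tables), `simnet` (LNS + top-k similarity layers),
#' `hetnet` (assemble the five-layer graph), `embed` (the four embedding
#' methods at the fusion dimension), `fuse` (pair dataset, AUC weights,
#' fused embedding), `train` (final classifier on the training
#' partition), `evaluate` (CV + independent metrics), `rank` (top-N
#' candidate targets for a query lncRNA). Each stage reads its upstream
#' artifacts from `cfg$outDir`, fails with the producing stage's name if
#' one is missing, and records inputs/outputs (md5), seed and wall time
#' in `manifest.json`.
#'
#' @param name stage name
#' @param cfg configuration list (merged over [defaultConfig()])
#' @return stage-dependent value, invisibly (e.g. the metrics list for
#'   `evaluate`)
#' @export
runStage <- function(name, cfg) {
  name <- match.arg(name, PIPELINE_STAGES)
  cfg <- mergeConfig(cfg)
  p <- stage_paths(cfg)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  seed <- cfg$seed

  result <- switch(name,
    synth = {
      sc <- cfg$synth
      bench <- genBenchmark(
        synthConfig(nLnc = sc$nLnc, nMrna = sc$nMrna, nMirna = sc$nMirna,
                    nBlocks = sc$nBlocks, seqLenRange = sc$seqLenRange,
                    withinProb = sc$withinProb, crossProb = sc$crossProb,
                    mirnaLen = sc$mirnaLen,
                    seed = stageSeed(seed, "synth")),
        p$data)
      manifest_update(cfg, name, character(), unlist(bench$paths),
                      proc.time()[["elapsed"]] - t0)
      bench
    },
    features = {
      require_inputs(c(p$lnc_fasta, p$mrna_fasta), "synth")
      lnc <- readRnaFasta(p$lnc_fasta, "lncRNA")
      mrna <- readRnaFasta(p$mrna_fasta, "mRNA")
      writeFeatureTable(unionFeatures(lnc), p$feat_lnc)
      writeFeatureTable(unionFeatures(mrna), p$feat_mrna)
      manifest_update(cfg, name, c(p$lnc_fasta, p$mrna_fasta),
                      c(p$feat_lnc, p$feat_mrna),
                      proc.time()[["elapsed"]] - t0)
      c(p$feat_lnc, p$feat_mrna)
    },
    simnet = {
      require_inputs(c(p$feat_lnc, p$feat_mrna), "features")
      for (side in list(c(p$feat_lnc, p$sim_lnc), c(p$feat_mrna, p$sim_mrna))) {
        fm <- readFeatureTable(side[1])
        sim <- lnsSimilarity(fm, cfg$simnet$neighborhoodSize,
                             cfg$simnet$regularizer)
        writeSimEdges(topkGraph(sim, cfg$simnet$topK), side[2])
      }
      manifest_update(cfg, name, c(p$feat_lnc, p$feat_mrna),
                      c(p$sim_lnc, p$sim_mrna),
                      proc.time()[["elapsed"]] - t0)
      c(p$sim_lnc, p$sim_mrna)
    },
    hetnet = {
      require_inputs(c(p$sim_lnc, p$sim_mrna), "simnet")
      require_inputs(c(p$lnc_mrna, p$lnc_mirna, p$mrna_mirna), "synth")
      g <- build_graph_from_files(cfg, p)
      g <- suppressWarnings(dropIsolatedNodes(g))
      writeHeteroGraph(g, p$nodes, p$edges)
      manifest_update(cfg, name,
                      c(p$sim_lnc, p$sim_mrna, p$lnc_mrna, p$lnc_mirna,
                        p$mrna_mirna), c(p$nodes, p$edges),
                      proc.time()[["elapsed"]] - t0)
      g
    },
    embed = {
      require_inputs(c(p$nodes, p$edges), "hetnet")
      g <- readHeteroGraph(p$nodes, p$edges)
      text <- if ("TADW" %in% cfg$embed$methods) {
        require_inputs(c(p$feat_lnc, p$feat_mrna), "features")
        load_text_features(p)
      }
      outs <- character()
      for (m in cfg$embed$methods) {
        emb <- embed_one(g, m, cfg, text, seed)
        writeEmbedding(emb, p$emb(m))
        outs <- c(outs, p$emb(m))
      }
      manifest_update(cfg, name, c(p$nodes, p$edges), outs,
                      proc.time()[["elapsed"]] - t0)
      outs
    },
    fuse = {
      embfiles <- vapply(cfg$embed$methods, p$emb, "")
      require_inputs(c(embfiles, p$lnc_mrna, p$nodes), "embed")
      g <- readHeteroGraph(p$nodes, p$edges)
      types <- nodeTypes(g)
      positives <- readInteractionTSV(p$lnc_mrna)
      ## restrict to nodes that survived graph assembly
      positives <- positives[positives$a %in% names(types) &
                               positives$b %in% names(types), ]
      ds <- buildPairDataset(positives,
                             lncIds = names(types)[types == "lncRNA"],
                             mrnaIds = names(types)[types == "mRNA"],
                             trainFraction = cfg$pairs$trainFraction,
                             seed = stageSeed(seed, "pairs"))
      writePairDataset(ds, p$pairs)
      embs <- stats::setNames(lapply(embfiles, readEmbedding),
                              cfg$embed$methods)
      fused <- if (cfg$fuse$mode == "weighted") {
        w <- aucWeights(embs, ds, cvFolds = cfg$fuse$cvFolds,
                        seed = stageSeed(seed, "aucw"),
                        algorithm = cfg$classify$algorithm,
                        params = cfg$classify$params)
        jsonlite::write_json(list(auc = as.list(w@auc),
                                  provenance = w@provenance),
                             p$weights, auto_unbox = TRUE, digits = NA)
        weightedAverage(embs, w)
      } else {
        fuseBaseline(embs, cfg$fuse$mode)
      }
      writeEmbedding(fused, p$emb_fused)
      manifest_update(cfg, name, embfiles,
                      c(p$pairs, p$emb_fused,
                        if (cfg$fuse$mode == "weighted") p$weights),
                      proc.time()[["elapsed"]] - t0)
      fused
    },
    train = {
      require_inputs(c(p$emb_fused, p$pairs), "fuse")
      emb <- readEmbedding(p$emb_fused)
      ds <- readPairDataset(p$pairs)
      tr <- pairTable(ds, "train")
      model <- trainClassifier(pairFeatures(emb, tr), tr$label,
                               algorithm = cfg$classify$algorithm,
                               params = cfg$classify$params,
                               seed = stageSeed(seed, "train"))
      writeModel(model, p$model)
      manifest_update(cfg, name, c(p$emb_fused, p$pairs), p$model,
                      proc.time()[["elapsed"]] - t0)
      model
    },
    evaluate = {
      require_inputs(c(p$emb_fused, p$pairs, p$model), "train")
      emb <- readEmbedding(p$emb_fused)
      ds <- readPairDataset(p$pairs)
      model <- readModel(p$model)
      ev <- cfg$evaluate
      g <- if (ev$maskTestEdges) readHeteroGraph(p$nodes, p$edges)
      reports <- list()
      reports$fused_cv <- crossValidate(
        emb, ds, k = ev$k, seed = stageSeed(seed, "eval-cv"),
        algorithm = cfg$classify$algorithm, params = cfg$classify$params,
        threshold = ev$threshold, maskTestEdges = ev$maskTestEdges,
        graph = g,
        embedBuilder = if (ev$maskTestEdges) function(gm) {
          text <- load_text_features(p)
          embs <- stats::setNames(
            lapply(cfg$embed$methods, embed_one, g = gm, cfg = cfg,
                   text = text, seed = seed), cfg$embed$methods)
          fuseBaseline(embs, "average")
        })
      if (isTRUE(ev$perMethod)) {
        for (m in cfg$embed$methods) {
          require_inputs(p$emb(m), "embed")
          reports[[paste0(m, "_cv")]] <- crossValidate(
            readEmbedding(p$emb(m)), ds, k = ev$k,
            seed = stageSeed(seed, "eval-cv"),
            algorithm = cfg$classify$algorithm,
            params = cfg$classify$params, threshold = ev$threshold)
        }
      }
      reports$independent <- evaluateIndependent(model, emb, ds,
                                                 threshold = ev$threshold)
      payload <- lapply(reports, function(r)
        list(summary = as.list(metricSummary(r)), n = r@n, k = r@k))
      jsonlite::write_json(payload, p$metrics_json, auto_unbox = TRUE,
                           digits = NA)
      tsv <- do.call(rbind, lapply(names(reports), function(nm)
        data.frame(model = nm, t(metricSummary(reports[[nm]])))))
      colnames(tsv) <- c("model", METRIC_NAMES)
      utils::write.table(tsv, p$metrics_tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest_update(cfg, name, c(p$emb_fused, p$pairs, p$model),
                      c(p$metrics_json, p$metrics_tsv),
                      proc.time()[["elapsed"]] - t0)
      reports
    },
    rank = {
      require_inputs(c(p$emb_fused, p$model, p$lnc_mrna), "train")
      if (is.null(cfg$rank$query))
        stop("config field rank$query must name a lncRNA id", call. = FALSE)
      emb <- readEmbedding(p$emb_fused)
      model <- readModel(p$model)
      known <- readInteractionTSV(p$lnc_mrna)
      candidates <- intersect(
        unique(known$b), rownames(embeddingVectors(emb)))
      rt <- rankTargets(model, emb, cfg$rank$query, candidates,
                        knownPositives = known, topN = cfg$rank$topN)
      out <- file.path(cfg$outDir,
                       sprintf("ranking_%s.tsv", cfg$rank$query))
      utils::write.table(rt, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest_update(cfg, name, c(p$emb_fused, p$model), out,
                      proc.time()[["elapsed"]] - t0)
      rt
    })
  invisible(result)
}

#' Run the full pipeline end to end
#'
#' Executes `synth` (unless external inputs are configured), then
#' `features`, `simnet`, `hetnet`, `embed`, `fuse`, `train` and
#' `evaluate`; `rank` additionally when `cfg$rank$query` is set.
#'
#' @param cfg configuration list, merged over [defaultConfig()]
#' @return invisibly, the evaluation reports
#' @export
runPipeline <- function(cfg = defaultConfig()) {
  cfg <- mergeConfig(cfg)
  stages <- c(if (is.null(cfg$input$lncFasta)) "synth",
              "features", "simnet", "hetnet", "embed", "fuse", "train",
              "evaluate", if (!is.null(cfg$rank$query)) "rank")
  res <- NULL
  for (s in stages) {
    message("== stage: ", s)
    out <- runStage(s, cfg)
    if (s == "evaluate") res <- out
  }
  invisible(res)
}
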