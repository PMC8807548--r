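#' @include AllClasses.R AllGenerics.R utils.R
NULL

ALGORITHMS <- c("xgboost", "gbdt", "adaboost", "rf", "knn", "svm")

## default hyperparameters per algorithm (overridable through `params`)
classifier_defaults <- function(algorithm) {
  switch(algorithm,
    xgboost = list(nrounds = 200, eta = 0.1, maxDepth = 6, lambda = 1,
                   minChildWeight = 1, subsample = 1, colsample = 1),
    gbdt = list(nrounds = 100, eta = 0.1, maxDepth = 3, lambda = 0,
                minChildWeight = 1, subsample = 1, colsample = 1),
    rf = list(ntrees = 200, maxDepth = 10, mtryFrac = NA, subsample = 0.7,
              lambda = 0, minChildWeight = 2),
    adaboost = list(nstumps = 50),
    knn = list(k = 15),
    svm = list(cost = 1, epochs = 20))
}

## ---- AdaBoost with decision stumps (discrete AdaBoost) ----

## best weighted-error stump over all features; X presorted orders passed in
fit_stump <- function(X, y01, w, orders) {
  n <- nrow(X); p <- ncol(X)
  ys <- 2 * y01 - 1
  best <- list(err = Inf)
  total_pos <- sum(w * (ys > 0))
  for (f in seq_len(p)) {
    o <- orders[[f]]
    xv <- X[o, f]
    wy <- w[o] * ys[o]
    ## err(threshold after position t, polarity +): left predicted -1, right +1
    cum <- cumsum(wy)
    distinct <- which(diff(xv) > 0)
    if (!length(distinct)) next
    ## weighted error for polarity "right is +1": pos weight on left + neg weight on right
    ## = total_pos - cum[t] ... derive: err = sum w [pred != y];
    ## pred=-1 for i<=t, +1 for i>t  => err = sum_{i<=t} w 1[y=+1] + sum_{i>t} w 1[y=-1]
    wpos <- w[o] * (ys[o] > 0); wneg <- w[o] * (ys[o] < 0)
    cpos <- cumsum(wpos); cneg <- cumsum(wneg)
    err_right_pos <- cpos[distinct] + (cneg[n] - cneg[distinct])
    err_left_pos <- 1 - err_right_pos      # weights sum to 1
    errs <- pmin(err_right_pos, err_left_pos)
    i_best <- which.min(errs)
    if (errs[i_best] < best$err - 1e-15) {
      t <- distinct[i_best]
      best <- list(err = errs[i_best], feature = f,
                   threshold = (xv[t] + xv[t + 1]) / 2,
                   polarity = if (err_right_pos[i_best] <= err_left_pos[i_best]) 1 else -1)
    }
  }
  best
}

fit_adaboost <- function(X, y01, nstumps) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  ys <- 2 * y01 - 1
  orders <- lapply(seq_len(ncol(X)), function(f) order(X[, f]))
  stumps <- list()
  for (t in seq_len(nstumps)) {
    st <- fit_stump(X, y01, w, orders)
    if (!is.finite(st$err)) break
    err <- min(max(st$err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    pred <- st$polarity * ifelse(X[, st$feature] > st$threshold, 1, -1)
    w <- w * exp(-alpha * ys * pred)
    w <- w / sum(w)
    st$alpha <- alpha
    stumps[[length(stumps) + 1]] <- st
    if (err < 1e-9) break
  }
  stumps
}

predict_adaboost <- function(stumps, X) {
  f <- rep(0, nrow(X))
  for (st in stumps)
    f <- f + st$alpha * st$polarity * ifelse(X[, st$feature] > st$threshold, 1, -1)
  1 / (1 + exp(-2 * f))   # margin -> probability (logistic link)
}

## ---- linear SVM by Pegasos SGD; scores squashed to [0,1] ----

fit_svm <- function(X, y01, cost, epochs, seed) {
  n <- nrow(X); p <- ncol(X)
  ys <- 2 * y01 - 1
  lambda <- 1 / (cost * n)
  wvec <- rep(0, p); b <- 0
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (lambda * t)
        margin <- ys[i] * (sum(wvec * X[i, ]) + b)
        wvec <- (1 - eta * lambda) * wvec
        if (margin < 1) {
          wvec <- wvec + eta * ys[i] * X[i, ]
          b <- b + eta * ys[i]
        }
      }
    }
  })
  list(w = wvec, b = b)
}

## ---- KNN ----

predict_knn <- function(fit, X) {
  tr <- fit$X
  k <- min(fit$k, nrow(tr))
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  apply(d2, 1, function(dr) {
    nb <- order(dr)[seq_len(k)]
    mean(fit$y[nb])
  })
}

#' Train a pair classifier
#'
#' The primary algorithm is `"xgboost"`: this package's gradient-boosted
#' regression trees with second-order (Newton) split gains, L2 leaf
#' regularization and a logistic objective -- the standard regularized
#' boosted-tree formulation. Also provided behind the same switch:
#' `"gbdt"` (shallower unregularized boosting), `"rf"` (averaged
#' independently-fit trees on row/column subsamples), `"adaboost"`
#' (decision stumps), `"knn"` and `"svm"` (linear, Pegasos SGD). All are
#' deterministic given `seed` and return scores in `[0, 1]`.
#'
#' @param features numeric matrix, one row per example
#' @param labels 0/1 vector (both classes must be present)
#' @param algorithm one of xgboost, gbdt, adaboost, rf, knn, svm
#' @param params named list overriding the per-algorithm defaults (e.g.
#'   `nrounds`, `eta`, `maxDepth` for the boosted trees)
#' @param seed integer seed
#' @return a [TrainedModel-class]
#' @export
trainClassifier <- function(features, labels, algorithm = "xgboost",
                            params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  X <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 examples of each class to train", call. = FALSE)
  seed <- assert_scalar_int(seed, "seed", min = 0)
  pr <- utils::modifyList(classifier_defaults(algorithm), params)

  fit <- switch(algorithm,
    xgboost = ,
    gbdt = cpp_boost_train(X, as.numeric(y), as.integer(pr$nrounds), pr$eta,
                           as.integer(pr$maxDepth), pr$lambda,
                           pr$minChildWeight, pr$subsample, pr$colsample,
                           "logistic", stageSeed(seed, algorithm)),
    rf = {
      mtry <- if (is.na(pr$mtryFrac)) sqrt(ncol(X)) / ncol(X) else pr$mtryFrac
      cpp_boost_train(X, as.numeric(y), as.integer(pr$ntrees), 1,
                      as.integer(pr$maxDepth), pr$lambda, pr$minChildWeight,
                      pr$subsample, mtry, "forest", stageSeed(seed, "rf"))
    },
    adaboost = list(stumps = fit_adaboost(X, y, as.integer(pr$nstumps))),
    knn = list(X = X, y = y, k = as.integer(pr$k)),
    svm = {
      mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
      c(fit_svm(Xs, y, pr$cost, as.integer(pr$epochs),
                stageSeed(seed, "svm")), list(mu = mu, sd = sdv))
    })

  new("TrainedModel", algorithm = algorithm, fit = as.list(fit),
      params = pr, seed = seed, featureWidth = ncol(X))
}

#' Score pairs with a trained classifier
#'
#' @param model a [TrainedModel-class]
#' @param features numeric matrix with the model's feature width
#' @return numeric scores in `[0, 1]`, one per row
#' @export
predictScores <- function(model, features) {
  stopifnot(is(model, "TrainedModel"))
  X <- as.matrix(features)
  if (nrow(X) == 0) return(numeric(0))
  if (ncol(X) != model@featureWidth)
    stop(sprintf("feature width %d does not match the model's width %d",
                 ncol(X), model@featureWidth), call. = FALSE)
  switch(model@algorithm,
    xgboost = ,
    gbdt = ,
    rf = as.numeric(cpp_boost_predict(model@fit, X)),
    adaboost = predict_adaboost(model@fit$stumps, X),
    knn = as.numeric(predict_knn(model@fit, X)),
    svm = {
      Xs <- sweep(sweep(X, 2, model@fit$mu), 2, model@fit$sd, "/")
      1 / (1 + exp(-(as.numeric(Xs %*% model@fit$w) + model@fit$b)))
    })
}

#' Rank candidate target genes for a query lncRNA
#'
#' Scores every (query, candidate) pair whose mRNA is not already a known
#' partner of the query, sorts by descending score (ties broken by mRNA
#' id) and returns the top `topN`.
#'
#' @param model a [TrainedModel-class] trained on pair features from `emb`
#' @param emb the [EmbeddingMatrix-class] used for the pair features
#' @param query lncRNA id (must be embedded)
#' @param candidates character vector of candidate mRNA ids
#' @param knownPositives data.frame of known pairs (columns lnc, mrna);
#'   the query's known partners are excluded from the ranking
#' @param topN maximum rows returned, default 10
#' @param combine pair feature combination, as in [pairFeatures()]
#' @return data.frame with columns `rank`, `mrna`, `score` (attribute
#'   `query` records the query id)
#' @export
rankTargets <- function(model, emb, query, candidates, knownPositives = NULL,
                        topN = 10L, combine = "concat") {
  stopifnot(length(query) == 1)
  v <- embeddingVectors(emb)
  if (!query %in% rownames(v))
    stop(sprintf("unknown query id '%s' (not embedded)", query), call. = FALSE)
  candidates <- unique(as.character(candidates))
  if (!is.null(knownPositives) && nrow(knownPositives)) {
    partners <- knownPositives[[2]][as.character(knownPositives[[1]]) == query]
    candidates <- setdiff(candidates, partners)
  }
  if (!length(candidates)) {
    out <- data.frame(rank = integer(), mrna = character(), score = numeric())
    attr(out, "query") <- query
    return(out)
  }
  feats <- pairFeatures(emb, data.frame(lnc = query, mrna = candidates),
                        combine = combine)
  sc <- predictScores(model, feats)
  ord <- order(-sc, candidates)
  keep <- ord[seq_len(min(topN, length(ord)))]
  out <- data.frame(rank = seq_along(keep), mrna = candidates[keep],
                    score = sc[keep])
  attr(out, "query") <- query
  out
}

#' Persist a trained model as JSON (with metadata sidecar fields)
#' @param model a [TrainedModel-class]
#' @param file output path (JSON)
#' @return `file`, invisibly
#' @export
writeModel <- function(model, file) {
  stopifnot(is(model, "TrainedModel"))
  payload <- list(algorithm = model@algorithm, params = model@params,
                  seed = model@seed, featureWidth = model@featureWidth,
                  fit = model@fit)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(file)
}

#' Read a model written by [writeModel()]
#' @param file JSON path
#' @return a [TrainedModel-class]
#' @export
readModel <- function(file) {
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  fit <- p$fit
  if (p$algorithm %in% c("xgboost", "gbdt", "rf")) {
    fit$trees <- lapply(fit$trees, function(tm) {
      m <- as.matrix(tm); storage.mode(m) <- "double"; m
    })
  }
  if (p$algorithm == "adaboost")
    fit$stumps <- apply(as.data.frame(fit$stumps), 1, as.list)
  new("TrainedModel", algorithm = p$algorithm, fit = as.list(fit),
      params = as.list(p$params), seed = as.integer(p$seed),
      featureWidth = as.integer(p$featureWidth))
}
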