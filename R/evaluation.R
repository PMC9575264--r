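#' Classification metrics for one scored fold
#'
#' AUC is the area under the ROC curve (computed with \pkg{pROC});
#' AUPR is the area under the precision-recall curve as a step function over
#' the distinct score thresholds (equal scores move together, so constant
#' scores on a balanced set give the prevalence baseline). Precision,
#' recall, F1 and accuracy are taken at the 0.5 decision threshold, the
#' convention for balanced sets; precision (and hence F1) is 0 when nothing
#' is called positive.
#'
#' @param scores numeric predicted probabilities.
#' @param labels 0/1 (or logical) true labels; both classes must appear for
#'   AUC/AUPR.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric: auc, aupr, precision, recall, f1, accuracy.
#' @export
classificationMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L) {
    stop("both classes are required to compute ranking metrics")
  }
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
  aupr <- .auprStep(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- mean(pred == labels)
  c(auc = auc, aupr = aupr, precision = precision, recall = recall,
    f1 = f1, accuracy = accuracy)
}

# Step-function area under the precision-recall curve over distinct
# thresholds (average-precision form: sum of precision x recall increment).
.auprStep <- function(scores, labels) {
  nPos <- sum(labels == 1L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpCum <- 0; fpCum <- 0; prevRecall <- 0; area <- 0
  for (t in thr) {
    sel <- scores == t
    tpCum <- tpCum + sum(labels[sel] == 1L)
    fpCum <- fpCum + sum(labels[sel] == 0L)
    recall <- tpCum / nPos
    precision <- tpCum / (tpCum + fpCum)
    area <- area + precision * (recall - prevRecall)
    prevRecall <- recall
  }
  area
}

#' Stratified fold assignment
#'
#' @param labels 0/1 vector.
#' @param k fold count (default 5).
#' @param seed integer seed.
#' @return integer fold id per sample, each class spread evenly.
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("stratification needs at least two classes")
  }
  if (min(table(labels)) < k) {
    stop(sprintf("each class needs at least %d samples for %d-fold stratification",
                 k, k))
  }
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Classifier presets behind one fit/predict interface
#'
#' Each preset is a list with \code{name}, \code{fit(X, y)} returning a
#' model and \code{predictProb(model, X)} returning positive-class
#' probabilities. Logistic regression is the reference benchmark classifier.
#' The optional presets mirror the common comparison zoo with their usual
#' hyperparameters: gradient-boosted trees (1000 rounds, learning rate
#' 0.05), an RBF-kernel SVM, and a random forest; each needs its Suggests
#' package at run time.
#'
#' @return a classifier spec list.
#' @export
classifierLR <- function() {
  asDf <- function(X) {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_along(df))  # avoid name collisions
    df
  }
  list(name = "lr",
       fit = function(X, y) {
         df <- asDf(X)
         df$.y <- y
         suppressWarnings(stats::glm(.y ~ ., data = df,
                                     family = stats::binomial()))
       },
       predictProb = function(model, X) {
         as.numeric(suppressWarnings(
           stats::predict(model, newdata = asDf(X), type = "response")))
       })
}

#' @rdname classifierLR
#' @export
classifierRF <- function() {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("the random-forest preset needs the 'ranger' package")
  }
  list(name = "rf",
       fit = function(X, y) {
         ranger::ranger(x = as.data.frame(X), y = factor(y),
                        probability = TRUE, num.trees = 500, seed = 1L)
       },
       predictProb = function(model, X) {
         stats::predict(model, data = as.data.frame(X))$predictions[, "1"]
       })
}

#' @rdname classifierLR
#' @export
classifierSVM <- function() {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("the SVM preset needs the 'e1071' package")
  }
  list(name = "svm",
       fit = function(X, y) {
         e1071::svm(x = X, y = factor(y), kernel = "radial",
                    probability = TRUE)
       },
       predictProb = function(model, X) {
         attr(stats::predict(model, X, probability = TRUE),
              "probabilities")[, "1"]
       })
}

#' @rdname classifierLR
#' @param nrounds,eta boosting rounds and learning rate for the
#'   gradient-boosted preset.
#' @export
classifierGBT <- function(nrounds = 1000L, eta = 0.05) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("the boosted-tree preset needs the 'xgboost' package")
  }
  list(name = "gbt",
       fit = function(X, y) {
         xgboost::xgboost(data = as.matrix(X), label = y,
                          nrounds = nrounds, eta = eta,
                          objective = "binary:logistic", verbose = 0)
       },
       predictProb = function(model, X) {
         as.numeric(stats::predict(model, as.matrix(X)))
       })
}

#' Stratified fivefold cross-validation
#'
#' Splits the balanced sample into five stratified parts; each part serves
#' once as the test set while the other four train the classifier. Reports
#' the six metrics per fold and pooled as the mean over folds.
#'
#' @param features numeric feature matrix (rows = samples).
#' @param labels 0/1 labels, both classes with at least \code{k} members.
#' @param classifier a classifier spec (default \code{\link{classifierLR}}).
#' @param seed integer seed for the fold split.
#' @param k fold count (default 5).
#' @return a \code{MetricsReport}: list with \code{pooled} (named numeric),
#'   \code{perFold} (data.frame), \code{nPos}, \code{nNeg}.
#' @export
fivefoldCV <- function(features, labels, classifier = classifierLR(),
                       seed = 1L, k = 5L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  folds <- stratifiedFolds(labels, k = k, seed = seed)
  perFold <- lapply(seq_len(k), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(labels[te])) < 2L) {
      stop(sprintf("fold %d is missing a class", f))
    }
    model <- classifier$fit(features[tr, , drop = FALSE], labels[tr])
    prob <- classifier$predictProb(model, features[te, , drop = FALSE])
    classificationMetrics(prob, labels[te])
  })
  perFold <- as.data.frame(do.call(rbind, perFold))
  perFold$fold <- seq_len(k)
  structure(list(pooled = colMeans(perFold[, 1:6]),
                 perFold = perFold,
                 nPos = sum(labels == 1L), nNeg = sum(labels == 0L)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport (%d folds, %d positives / %d negatives)\n",
              nrow(x$perFold), x$nPos, x$nNeg))
  print(round(x$pooled, 4))
  invisible(x)
}

#' Negative-selection strategies
#'
#' One entry point for the full method, its two single-stage ablation arms,
#' and the two literature baselines:
#' \describe{
#'   \item{kr_nssm}{full two-stage screen, then a seeded random draw of
#'     \code{n} from RN.}
#'   \item{ss_kmeans_only}{semi-supervised K-means only; draw from LN1.}
#'   \item{rocchio_only}{both Rocchio rounds applied directly to all of U
#'     (no K-means pre-screen); draw from the resulting RN.}
#'   \item{random}{uniform draw from U.}
#'   \item{kmeans_cluster_random}{plain K-means on U (k =
#'     \code{cfg$kSubsets}), then per-cluster draws proportional to cluster
#'     size.}
#' }
#' When a strategy yields fewer than \code{n} candidates, all of them are
#' returned with a warning.
#'
#' @param strategy strategy name (see above).
#' @param data a \code{ScreenData}.
#' @param n requested negative count.
#' @param seed integer seed for all random draws.
#' @param cfg a \code{\link{screenConfig}}.
#' @return integer vector of pair indices.
#' @export
selectNegatives <- function(strategy = c("kr_nssm", "ss_kmeans_only",
                                         "rocchio_only", "random",
                                         "kmeans_cluster_random"),
                            data, n, seed = 1L, cfg = screenConfig()) {
  strategy <- match.arg(strategy)
  stopifnot(is(data, "ScreenData"), n >= 1L)
  drawFrom <- function(pool) {
    if (length(pool) <= n) {
      if (length(pool) < n) {
        warning(sprintf("strategy '%s' yielded %d < %d candidates; returning all",
                        strategy, length(pool), n), call. = FALSE)
      }
      return(sort(as.integer(pool)))
    }
    withr::with_seed(seed, sort(sample(pool, n)))
  }
  sets <- partitionSamples(data)
  if (strategy == "random") return(drawFrom(sets@U))

  if (strategy == "kmeans_cluster_random") {
    Ufeat <- pairFeatures(data, sets@U)
    part <- kmeansPartition(Ufeat, cfg$kSubsets, seed)
    sizes <- lengths(part$subsets)
    alloc <- floor(n * sizes / sum(sizes))
    # distribute the rounding remainder to the largest fractional parts
    rem <- n - sum(alloc)
    frac <- n * sizes / sum(sizes) - alloc
    if (rem > 0L) {
      alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        alloc[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    alloc <- pmin(alloc, sizes)
    picked <- withr::with_seed(seed, unlist(lapply(seq_along(alloc), function(i) {
      pool <- sets@U[part$subsets[[i]]]
      if (alloc[i] >= length(pool)) pool else sample(pool, alloc[i])
    })))
    if (length(picked) < n) {
      warning(sprintf("strategy '%s' yielded %d < %d candidates; returning all",
                      strategy, length(picked), n), call. = FALSE)
    }
    return(sort(as.integer(picked)))
  }

  if (strategy == "ss_kmeans_only") {
    Pfeat <- pairFeatures(data, sets@P)
    Ufeat <- pairFeatures(data, sets@U)
    km <- runSSKmeans(Pfeat, Ufeat, tol = cfg$tol, maxIter = cfg$maxIter)
    return(drawFrom(sets@U[km$ln]))
  }

  if (strategy == "rocchio_only") {
    Pfeat <- pairFeatures(data, sets@P)
    Ufeat <- pairFeatures(data, sets@U)
    rcfg <- rocchioConfig(cfg$alpha, cfg$beta, cfg$kSubsets, cfg$kmeansSeed,
                          cfg$rocchio2Rule)
    r1 <- rocchio1(Pfeat, Ufeat, rcfg)
    if (length(r1$ln2) == 0L) return(drawFrom(integer()))
    r2 <- rocchio2(Pfeat, Ufeat[r1$ln2, , drop = FALSE], rcfg)
    return(drawFrom(sets@U[r1$ln2][r2$rn]))
  }

  res <- krNSSM(data, cfg, verbose = FALSE)
  drawFrom(reliableNegatives(res))
}

#' Build a balanced labelled set from positives and selected negatives
#'
#' @param data a \code{ScreenData}.
#' @param negatives integer pair indices of the selected negatives.
#' @return list with \code{features} matrix and 0/1 \code{labels}; the
#'   positive class is the observed association set P only.
#' @export
balancedSet <- function(data, negatives) {
  sets <- partitionSamples(data)
  idx <- c(sets@P, as.integer(negatives))
  list(features = pairFeatures(data, idx),
       labels = rep(c(1L, 0L), c(length(sets@P), length(negatives))))
}

#' Ablation table: single-stage arms versus the full screen
#'
#' For each seed and each arm (K-means-only screen, Rocchio-only screen,
#' full two-stage screen), selects a balanced negative set, runs stratified
#' fivefold cross-validation with the benchmark classifier, and tabulates
#' the six metrics as mean and sd over seeds.
#'
#' @param data a \code{ScreenData}.
#' @param cfg a \code{\link{screenConfig}}.
#' @param seeds integer vector of seeds (>= 3 recommended for the sd
#'   column).
#' @param classifier classifier spec, default logistic regression.
#' @param strategies arms to include.
#' @param file optional CSV path for the summary table.
#' @return list with \code{summary} (strategy x metric mean/sd data.frame)
#'   and \code{runs} (long per-seed data.frame).
#' @export
ablationTable <- function(data, cfg = screenConfig(), seeds = 1:3,
                          classifier = classifierLR(),
                          strategies = c("ss_kmeans_only", "rocchio_only",
                                         "kr_nssm"),
                          file = NULL) {
  sets <- partitionSamples(data)
  n <- length(sets@P)
  runs <- do.call(rbind, lapply(strategies, function(st) {
    do.call(rbind, lapply(seeds, function(sd) {
      neg <- selectNegatives(st, data, n, seed = sd, cfg = cfg)
      bs <- balancedSet(data, neg)
      mr <- fivefoldCV(bs$features, bs$labels, classifier, seed = sd)
      data.frame(strategy = st, seed = sd, t(mr$pooled))
    }))
  }))
  metricCols <- c("auc", "aupr", "precision", "recall", "f1", "accuracy")
  summary <- do.call(rbind, lapply(split(runs, runs$strategy), function(g) {
    mu <- colMeans(g[metricCols])
    sdv <- apply(g[metricCols], 2L, stats::sd)
    sdv[is.na(sdv)] <- 0  # single seed: zero-width sd
    data.frame(strategy = g$strategy[1L],
               t(mu), t(stats::setNames(sdv, paste0(metricCols, "_sd"))))
  }))
  summary <- summary[match(strategies, summary$strategy), , drop = FALSE]
  rownames(summary) <- NULL
  if (!is.null(file)) utils::write.csv(summary, file, row.names = FALSE)
  list(summary = summary, runs = runs)
}
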