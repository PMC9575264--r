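#' Full screening configuration
#'
#' One object holding every tunable of the two-stage screen, recorded in the
#' result so a run can be reproduced exactly.
#'
#' @param alpha,beta,kSubsets,kmeansSeed,rocchio2Rule Rocchio settings, see
#'   \code{\link{rocchioConfig}}.
#' @param tol,maxIter semi-supervised K-means stopping controls, see
#'   \code{\link{runSSKmeans}}.
#' @param positiveRule how the reliable positive set RP is formed:
#'   \code{"rp1_and_lp1"} (default) keeps pairs that look positive to both
#'   screens (round-1 Rocchio positives that were also likely positives),
#'   \code{"rp1_only"} or \code{"lp1_only"} keep a single screen's set.
#' @return a classed list.
#' @export
screenConfig <- function(alpha = 16, beta = 4, kSubsets = 3L,
                         kmeansSeed = 1L,
                         rocchio2Rule = c("any", "all", "nearest"),
                         tol = 1e-6, maxIter = 100L,
                         positiveRule = c("rp1_and_lp1", "rp1_only",
                                          "lp1_only")) {
  rocchio2Rule <- match.arg(rocchio2Rule)
  positiveRule <- match.arg(positiveRule)
  structure(list(alpha = alpha, beta = beta, kSubsets = as.integer(kSubsets),
                 kmeansSeed = as.integer(kmeansSeed),
                 rocchio2Rule = rocchio2Rule, tol = tol,
                 maxIter = as.integer(maxIter), positiveRule = positiveRule),
            class = "screenConfig")
}

.stageWrap <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Two-stage reliable negative screen of miRNA-disease pairs
#'
#' Runs the whole workflow: the pairs are partitioned into positives P and
#' unlabelled U; the semi-supervised K-means splits U into likely positives
#' LP1 and likely negatives LN1; Rocchio round 1 screens LN1 into LN2 (and
#' flags round-1 reliable positives RP1); Rocchio round 2 sub-clusters LN2
#' and keeps as final reliable negatives RN only the samples that look
#' negative against the local prototype pairs. Reliable positives RP are
#' formed per \code{positiveRule} (default: RP1 and LP1 must agree).
#'
#' Stage sizes are reported via \code{message()}. An empty RN is a valid,
#' warned outcome, never an error.
#'
#' @param data a \code{\linkS4class{ScreenData}}.
#' @param config a \code{\link{screenConfig}}.
#' @param verbose emit stage-size messages (default TRUE).
#' @return a \code{\linkS4class{ScreenResult}}.
#' @examples
#' syn <- generateSynthetic(syntheticConfig(nMirna = 12, nDisease = 8,
#'                                          seed = 7))
#' res <- krNSSM(syn$data, verbose = FALSE)
#' stageSizes(res)
#' @export
krNSSM <- function(data, config = screenConfig(), verbose = TRUE) {
  stopifnot(is(data, "ScreenData"))
  say <- function(...) if (verbose) message(sprintf(...))

  sets <- .stageWrap("partition", partitionSamples(data))
  Pfeat <- .stageWrap("features", pairFeatures(data, sets@P))
  Ufeat <- .stageWrap("features", pairFeatures(data, sets@U))
  say("partition: |P| = %d, |U| = %d", length(sets@P), length(sets@U))

  km <- .stageWrap("ss-kmeans",
                   runSSKmeans(Pfeat, Ufeat, tol = config$tol,
                               maxIter = config$maxIter))
  LP1 <- sets@U[km$lp]; LN1 <- sets@U[km$ln]
  say("ss-kmeans: |LP1| = %d, |LN1| = %d (%d iterations)",
      length(LP1), length(LN1), km$iterations)

  rcfg <- rocchioConfig(config$alpha, config$beta, config$kSubsets,
                        config$kmeansSeed, config$rocchio2Rule)
  LN1feat <- Ufeat[km$ln, , drop = FALSE]
  r1 <- .stageWrap("rocchio1", rocchio1(Pfeat, LN1feat, rcfg))
  LN2 <- LN1[r1$ln2]; RP1 <- LN1[r1$rp1]
  say("rocchio1: |LN2| = %d, |RP1| = %d", length(LN2), length(RP1))

  if (length(LN2) > 0L) {
    LN2feat <- LN1feat[r1$ln2, , drop = FALSE]
    r2 <- .stageWrap("rocchio2", rocchio2(Pfeat, LN2feat, rcfg))
    RN <- LN2[r2$rn]
    rnMargin <- r2$margin[r2$rn]
  } else {
    RN <- integer(); rnMargin <- numeric()
  }
  if (length(RN) == 0L) {
    warning("screen produced an empty reliable negative set", call. = FALSE)
  }

  # "positive to both screens": an LP1 pair (K-means screen) must also score
  # positive under the round-1 prototype pair (Rocchio screen). RP1 alone is
  # the Rocchio-only reading, LP1 alone the K-means-only reading.
  lp1Margin <- if (length(LP1) > 0L && !is.null(r1$prototypes)) {
    LP1feat <- Ufeat[km$lp, , drop = FALSE]
    .cosineRows(LP1feat, r1$prototypes$cPos) -
      .cosineRows(LP1feat, r1$prototypes$cNeg)
  } else numeric(length(LP1))
  switch(config$positiveRule,
    rp1_and_lp1 = {
      keep <- lp1Margin >= 0
      RP <- LP1[keep]; rpMargin <- lp1Margin[keep]
    },
    rp1_only = {
      RP <- RP1; rpMargin <- r1$margin[r1$rp1]
    },
    lp1_only = {
      RP <- LP1; rpMargin <- lp1Margin
    })
  keep <- !(RP %in% RN)
  RP <- RP[keep]; rpMargin <- rpMargin[keep]
  say("final: |RN| = %d, |RP| = %d", length(RN), length(RP))

  outSets <- new("SampleSets", nMirna = sets@nMirna, nDisease = sets@nDisease,
                 P = sets@P, U = sets@U,
                 LP1 = as.integer(LP1), LN1 = as.integer(LN1),
                 LN2 = as.integer(LN2), RN = as.integer(RN),
                 RP = as.integer(RP))
  sizes <- c(U = length(sets@U), LP1 = length(LP1), LN1 = length(LN1),
             LN2 = length(LN2), RN = length(RN), RP = length(RP))
  rn <- as.numeric(rnMargin); names(rn) <- as.character(RN)
  rp <- as.numeric(rpMargin); names(rp) <- as.character(RP)
  new("ScreenResult", sets = outSets, rnScores = rn, rpScores = rp,
      config = c(unclass(config),
                 list(nMirna = sets@nMirna, nDisease = sets@nDisease)),
      stageSizes = sizes)
}

#' Balanced negative sampling from the reliable negative set
#'
#' Draws \code{n} negatives from RN to pair with the \code{n} known
#' positives of a balanced training set. \code{mode = "random"} draws
#' uniformly under \code{seed} (the design used for the balanced
#' benchmark); \code{mode = "top_margin"} instead keeps the \code{n} most
#' confidently negative samples by screening margin — an extension for users
#' who want ranked negatives.
#'
#' @param result a \code{ScreenResult}.
#' @param n requested sample size (> 0). If \code{n > |RN|} all of RN is
#'   returned with a warning.
#' @param seed integer seed for the random mode.
#' @param mode \code{"random"} or \code{"top_margin"}.
#' @return integer vector of pair indices, a subset of RN.
#' @export
sampleBalancedNegatives <- function(result, n, seed = 1L,
                                    mode = c("random", "top_margin")) {
  stopifnot(is(result, "ScreenResult"))
  mode <- match.arg(mode)
  if (n <= 0) stop("n must be a positive integer")
  RN <- reliableNegatives(result)
  if (n >= length(RN)) {
    if (n > length(RN)) {
      warning(sprintf("requested %d negatives but |RN| = %d; returning all",
                      n, length(RN)), call. = FALSE)
    }
    return(RN)
  }
  if (mode == "random") {
    withr::with_seed(seed, sort(sample(RN, n)))
  } else {
    sc <- rnScores(result)[as.character(RN)]
    sort(RN[order(sc, decreasing = TRUE)[seq_len(n)]])
  }
}

#' Write the full outputs of a screening run
#'
#' Writes \code{stages.csv} (pair labels and deepest stage),
#' \code{negatives.csv}, \code{positives.csv} (labels plus screening
#' margins) and \code{run_manifest.json} (config snapshot and stage sizes)
#' into a directory, so downstream arms can reuse intermediate sets without
#' recomputation.
#'
#' @param result a \code{ScreenResult}.
#' @param data the originating \code{ScreenData}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeScreenOutputs <- function(result, data, dir) {
  stopifnot(is(result, "ScreenResult"), is(data, "ScreenData"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeStages(result, data, file.path(dir, "stages.csv"))
  sets <- stageSets(result)
  pairDf <- function(idx, score) {
    ent <- pairEntities(idx, sets@nDisease)
    data.frame(mirna = data@simM@labels[ent$mirna],
               disease = data@simD@labels[ent$disease],
               margin = unname(score[as.character(idx)]))
  }
  utils::write.csv(pairDf(sets@RN, rnScores(result)),
                   file.path(dir, "negatives.csv"), row.names = FALSE)
  utils::write.csv(pairDf(sets@RP, result@rpScores),
                   file.path(dir, "positives.csv"), row.names = FALSE)
  manifest <- list(config = configSnapshot(result),
                   stage_sizes = as.list(stageSizes(result)))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    dput(manifest, file.path(dir, "run_manifest.txt"))
  }
  invisible(dir)
}
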