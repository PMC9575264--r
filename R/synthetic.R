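#' Configuration of the block-structured synthetic generator
#'
#' The generator instantiates the assumption the screen exploits: miRNAs
#' with similar functions tend to associate with similar diseases. miRNAs
#' and diseases are assigned to co-clusters ("blocks"); similarity is high
#' within a block and low across blocks (plus Gaussian noise), and true
#' positive associations concentrate in within-block pairs. A fraction of
#' the true positives is hidden from the observed association table — those
#' pairs sit inside the unlabelled set U and are the stressor the screen
#' must avoid selecting.
#'
#' @param nMirna,nDisease grid dimensions (defaults 60 x 40).
#' @param nBlocks number of co-clusters (default 3).
#' @param withinSim mean similarity inside a block, in (0, 1] (default 0.7).
#' @param betweenSim mean similarity across blocks, in [0, 1) (default 0.2);
#'   must be below \code{withinSim}.
#' @param simNoiseSd standard deviation of the Gaussian similarity noise
#'   (default 0.1).
#' @param posRateIn probability that a within-block pair is a true positive
#'   (default 0.5).
#' @param posRateOut probability for an out-of-block pair (default 0.02).
#' @param hideFrac fraction of true positives hidden into U (default 0.2).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a classed list.
#' @export
syntheticConfig <- function(nMirna = 60L, nDisease = 40L, nBlocks = 3L,
                            withinSim = 0.7, betweenSim = 0.2,
                            simNoiseSd = 0.1, posRateIn = 0.5,
                            posRateOut = 0.02, hideFrac = 0.2, seed = 1L) {
  stopifnot(nMirna >= 1L, nDisease >= 1L, nBlocks >= 1L,
            withinSim > betweenSim, withinSim > 0, withinSim <= 1,
            betweenSim >= 0, betweenSim < 1, simNoiseSd >= 0,
            posRateIn >= 0, posRateIn <= 1, posRateOut >= 0, posRateOut <= 1,
            hideFrac >= 0, hideFrac <= 1)
  if (nBlocks > min(nMirna, nDisease)) {
    stop("nBlocks exceeds the smaller entity count: a block would be empty")
  }
  structure(list(nMirna = as.integer(nMirna), nDisease = as.integer(nDisease),
                 nBlocks = as.integer(nBlocks), withinSim = withinSim,
                 betweenSim = betweenSim, simNoiseSd = simNoiseSd,
                 posRateIn = posRateIn, posRateOut = posRateOut,
                 hideFrac = hideFrac, seed = as.integer(seed)),
            class = "syntheticConfig")
}

# Block sizes follow a geometric 1:2:4:... profile, emulating the
# heavy-tailed coverage of real association databases where the largest
# disease and miRNA families hold most known associations. An exactly
# balanced design is a degenerate corner: by symmetry the mean of
# within-block pairs coincides with the mean of cross-block pairs, so no
# centroid-based screen could separate them.
.blockAssign <- function(n, nBlocks) {
  w <- 2^(seq_len(nBlocks) - 1L)
  sizes <- floor(n * w / sum(w))
  rem <- n - sum(sizes)
  if (rem > 0L) {
    sizes[order(n * w / sum(w) - sizes, decreasing = TRUE)[seq_len(rem)]] <-
      sizes[order(n * w / sum(w) - sizes, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  if (any(sizes == 0L)) stop("a block would be empty; reduce nBlocks")
  rep(seq_len(nBlocks), sizes)
}

.blockSimilarity <- function(n, blocks, within, between, sd) {
  base <- matrix(between, n, n)
  same <- outer(blocks, blocks, "==")
  base[same] <- within
  if (sd > 0) base <- base + matrix(stats::rnorm(n * n, 0, sd), n, n)
  base <- pmin(pmax(base, 0), 1)  # pmin/pmax keep dims of the first arg
  base <- (base + t(base)) / 2
  diag(base) <- 1
  base
}

#' Generate a synthetic screening problem with known truth
#'
#' Draws block-structured miRNA and disease similarity matrices
#' (symmetrised, clipped to [0, 1], unit diagonal), plants true positive
#' pairs by per-pair Bernoulli draws whose rate depends on block
#' co-membership, and hides \code{hideFrac} of them from the observed
#' association table. The observed positives form P; the hidden positives
#' remain truly positive inside U.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return list with \code{data} (a \code{\linkS4class{ScreenData}}),
#'   \code{truth} (a \code{\linkS4class{SyntheticTruth}}) and the block
#'   assignments \code{mirnaBlock}, \code{diseaseBlock}.
#' @examples
#' syn <- generateSynthetic(syntheticConfig(nMirna = 10, nDisease = 8))
#' syn$truth
#' @export
generateSynthetic <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  withr::with_seed(cfg$seed, {
    bm <- .blockAssign(cfg$nMirna, cfg$nBlocks)
    bd <- .blockAssign(cfg$nDisease, cfg$nBlocks)
    simM <- .blockSimilarity(cfg$nMirna, bm, cfg$withinSim, cfg$betweenSim,
                             cfg$simNoiseSd)
    simD <- .blockSimilarity(cfg$nDisease, bd, cfg$withinSim, cfg$betweenSim,
                             cfg$simNoiseSd)
    sameBlock <- outer(bm, bd, "==")
    rate <- ifelse(sameBlock, cfg$posRateIn, cfg$posRateOut)
    isPos <- matrix(stats::runif(cfg$nMirna * cfg$nDisease) <
                      as.vector(rate),
                    cfg$nMirna, cfg$nDisease)
    # canonical row-major pair order over (miRNA, disease)
    truePos <- which(t(isPos))
    nHide <- round(cfg$hideFrac * length(truePos))
    hidden <- if (nHide > 0L) sort(sample(truePos, nHide)) else integer()
    observed <- setdiff(truePos, hidden)
  })
  mlab <- sprintf("mir%03d", seq_len(cfg$nMirna))
  dlab <- sprintf("dis%03d", seq_len(cfg$nDisease))
  sm <- SimilarityMatrix(simM, mlab)
  sdm <- SimilarityMatrix(simD, dlab)
  ent <- pairEntities(observed, cfg$nDisease)
  data <- screenData(
    data.frame(mirna = ent$mirna, disease = ent$disease), sm, sdm)
  truth <- new("SyntheticTruth", nMirna = cfg$nMirna,
               nDisease = cfg$nDisease,
               truePositive = as.integer(truePos),
               observedPositive = as.integer(observed),
               hiddenPositive = as.integer(hidden))
  list(data = data, truth = truth, mirnaBlock = bm, diseaseBlock = bd)
}

#' Purity of a selected negative set under synthetic truth
#'
#' The operational meaning of "more reliable negatives": the fraction of the
#' selected pairs that are truly negative. Only unlabelled pairs may be
#' scored (selecting from P is an argument error). An empty selection has
#' purity 1 by convention, with a warning.
#'
#' @param selected integer pair indices, a subset of U.
#' @param truth a \code{\linkS4class{SyntheticTruth}}.
#' @return scalar in [0, 1].
#' @export
negativePurity <- function(selected, truth) {
  stopifnot(is(truth, "SyntheticTruth"))
  selected <- as.integer(selected)
  if (length(selected) == 0L) {
    warning("empty selection: purity 1 by convention", call. = FALSE)
    return(1)
  }
  nAll <- truth@nMirna * truth@nDisease
  if (any(selected < 1L | selected > nAll) ||
      any(selected %in% truth@observedPositive)) {
    stop("selected pairs must lie inside the unlabelled set U")
  }
  mean(!(selected %in% truth@truePositive))
}
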