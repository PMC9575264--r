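#' Configuration of the Rocchio screening rounds
#'
#' @param alpha positive weight of the in-class term of each prototype
#'   (default 16).
#' @param beta non-negative weight of the out-class term (default 4).
#' @param kSubsets number of K-means subsets in round 2 (default 3).
#' @param kmeansSeed integer seed making the round-2 partition
#'   deterministic.
#' @param rule round-2 acceptance rule: \code{"any"} (default) keeps a
#'   sample if the negative prototype wins against at least one subset's
#'   prototype pair — the literal reading of the per-pair comparison;
#'   \code{"all"} demands unanimity over every pair (very conservative: on
#'   crisply clustered data a sample-independent bias in cross-subset
#'   comparisons can empty RN entirely); \code{"nearest"} tests only the
#'   pair of the sample's own K-means subset.
#' @return a classed list of settings.
#' @export
rocchioConfig <- function(alpha = 16, beta = 4, kSubsets = 3L,
                          kmeansSeed = 1L, rule = c("any", "all", "nearest")) {
  rule <- match.arg(rule)
  stopifnot(alpha > 0, beta >= 0, kSubsets >= 1L)
  structure(list(alpha = alpha, beta = beta, kSubsets = as.integer(kSubsets),
                 kmeansSeed = as.integer(kmeansSeed), rule = rule),
            class = "rocchioConfig")
}

#' Rocchio prototype vector pair
#'
#' Each class prototype is the weighted difference of the normalised-member
#' means of the two sets:
#' \deqn{c^{+} = \alpha \frac{1}{|P|}\sum_{x \in P} \frac{x}{\|x\|_2}
#'            - \beta  \frac{1}{|N|}\sum_{x \in N} \frac{x}{\|x\|_2}}
#' and symmetrically for the negative prototype with the roles swapped.
#' Zero-norm members cannot be normalised and are excluded from the mean,
#' with a message reporting how many were dropped.
#'
#' @param posFeat,negFeat numeric matrices of member feature vectors (rows);
#'   both non-empty after zero-norm exclusion.
#' @param alpha,beta non-negative weights.
#' @return list with vectors \code{cPos}, \code{cNeg}.
#' @examples
#' prototypePair(rbind(c(3, 4)), rbind(c(0, 1)), alpha = 1, beta = 0)$cPos
#' @export
prototypePair <- function(posFeat, negFeat, alpha = 16, beta = 4) {
  normMean <- function(X, what) {
    X <- rbind(X)
    if (nrow(X) == 0L) stop(sprintf("empty %s set: cannot build a prototype", what))
    nx <- sqrt(rowSums(X * X))
    drop <- nx == 0
    if (any(drop)) {
      message(sprintf("prototypePair: excluded %d zero-norm %s vectors",
                      sum(drop), what))
      X <- X[!drop, , drop = FALSE]; nx <- nx[!drop]
      if (nrow(X) == 0L) stop(sprintf("all %s vectors have zero norm", what))
    }
    colMeans(X / nx)
  }
  mp <- normMean(posFeat, "positive")
  mn <- normMean(negFeat, "negative")
  list(cPos = alpha * mp - beta * mn, cNeg = alpha * mn - beta * mp)
}

#' Rocchio round 1: screen LN1 into reliable negatives
#'
#' Builds one prototype pair with the known positives P as the positive
#' class and all of LN1 as the (tentative) negative class, then classifies
#' every LN1 sample by cosine similarity: strictly closer to the negative
#' prototype means reliable negative (LN2), otherwise — including exact
#' ties — the sample is flagged reliable positive (RP1).
#'
#' @param Pfeat numeric matrix of positive feature vectors.
#' @param LN1feat numeric matrix of likely-negative feature vectors.
#' @param cfg a \code{\link{rocchioConfig}}.
#' @return list with row indices \code{ln2}, \code{rp1} (into
#'   \code{LN1feat}), per-sample score \code{margin}
#'   (cosine to positive minus cosine to negative prototype), and the
#'   \code{prototypes} used.
#' @export
rocchio1 <- function(Pfeat, LN1feat, cfg = rocchioConfig()) {
  LN1feat <- rbind(LN1feat)
  if (nrow(LN1feat) == 0L) {
    warning("rocchio1: empty likely-negative set", call. = FALSE)
    return(list(ln2 = integer(), rp1 = integer(), margin = numeric(),
                prototypes = NULL))
  }
  pr <- prototypePair(Pfeat, LN1feat, cfg$alpha, cfg$beta)
  sp <- .cosineRows(LN1feat, pr$cPos)
  sn <- .cosineRows(LN1feat, pr$cNeg)
  ln2 <- which(sp < sn)
  list(ln2 = ln2, rp1 = setdiff(seq_len(nrow(LN1feat)), ln2),
       margin = sp - sn, prototypes = pr)
}

#' Deterministic K-means partition
#'
#' Partitions feature vectors into \code{k} non-empty subsets with standard
#' Euclidean K-means (10 restarts under a fixed seed, so the partition is
#' reproducible across runs and platforms). If fewer than \code{k} samples
#' (or fewer distinct points) are available, \code{k} is reduced with a
#' warning.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param k requested subset count.
#' @param seed integer seed.
#' @return list with \code{subsets} (list of row-index vectors) and
#'   \code{cluster} (per-row subset id).
#' @export
kmeansPartition <- function(X, k, seed = 1L) {
  X <- rbind(X)
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  nDistinct <- length(unique(key))
  if (k > nDistinct) {
    warning(sprintf("reducing k from %d to %d (distinct samples)",
                    k, nDistinct), call. = FALSE)
    k <- nDistinct
  }
  if (k == 1L) {
    cl <- rep(1L, nrow(X))
  } else if (k == nDistinct) {
    # every distinct point is its own subset; stats::kmeans needs
    # strictly fewer centres than points
    cl <- match(key, unique(key))
  } else {
    km <- withr::with_seed(seed,
      stats::kmeans(X, centers = k, nstart = 10L, iter.max = 50L))
    cl <- km$cluster
  }
  list(subsets = split(seq_len(nrow(X)), cl), cluster = cl)
}

#' Rocchio round 2: local prototype screen of LN2
#'
#' LN2 is divided into \code{kSubsets} K-means subsets; each subset forms a
#' local prototype pair against P (subset as the negative class, P as the
#' positive class). A sample is kept as a final reliable negative only if
#' the negative prototype strictly beats the positive one by cosine
#' similarity under the configured rule (at least one subset, by default).
#' Ties and zero-norm samples are never admitted.
#'
#' @inheritParams rocchio1
#' @param LN2feat numeric matrix of round-1 reliable negative features.
#' @return list with row indices \code{rn} (into \code{LN2feat}),
#'   per-sample \code{margin} = min over subsets of (cosine to negative
#'   prototype - cosine to positive prototype), the subset \code{partition},
#'   and the list of \code{prototypes}.
#' @export
rocchio2 <- function(Pfeat, LN2feat, cfg = rocchioConfig()) {
  LN2feat <- rbind(LN2feat)
  n <- nrow(LN2feat)
  if (n == 0L) {
    warning("rocchio2: empty input set", call. = FALSE)
    return(list(rn = integer(), margin = numeric(), partition = NULL,
                prototypes = list()))
  }
  part <- kmeansPartition(LN2feat, cfg$kSubsets, cfg$kmeansSeed)
  protos <- vector("list", length(part$subsets))
  winMat <- matrix(NA, n, length(part$subsets))
  marginMat <- matrix(NA_real_, n, length(part$subsets))
  for (j in seq_along(part$subsets)) {
    idx <- part$subsets[[j]]
    if (length(idx) == 0L) {
      warning(sprintf("rocchio2: subset %d is empty, skipped", j),
              call. = FALSE)
      next
    }
    pr <- prototypePair(Pfeat, LN2feat[idx, , drop = FALSE],
                        cfg$alpha, cfg$beta)
    protos[[j]] <- pr
    sn <- .cosineRows(LN2feat, pr$cNeg)
    sp <- .cosineRows(LN2feat, pr$cPos)
    winMat[, j] <- sn > sp
    marginMat[, j] <- sn - sp
  }
  used <- which(colSums(is.na(winMat)) < n)
  winMat <- winMat[, used, drop = FALSE]
  marginMat <- marginMat[, used, drop = FALSE]
  keep <- switch(cfg$rule,
    all = rowSums(winMat) == ncol(winMat),
    any = rowSums(winMat) > 0,
    nearest = {
      own <- match(as.character(part$cluster), names(part$subsets))
      vapply(seq_len(n), function(i) {
        j <- match(own[i], used)
        !is.na(j) && isTRUE(winMat[i, j])
      }, logical(1))
    })
  zero <- rowSums(LN2feat * LN2feat) == 0
  rn <- which(keep & !zero)
  list(rn = rn,
       margin = apply(marginMat, 1L, min),
       partition = part, prototypes = protos)
}
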