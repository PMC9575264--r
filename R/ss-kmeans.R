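#' Componentwise centroid of a set of feature vectors
#'
#' @param features numeric matrix, one sample per row.
#' @return numeric vector, the arithmetic mean of the rows.
#' @export
centroid <- function(features) {
  features <- rbind(features)
  if (nrow(features) == 0L) stop("cannot compute the centroid of an empty set")
  colMeans(features)
}

#' Cosine similarity with a zero-vector policy
#'
#' Returns \code{u . v / (|u| |v|)}. A zero-norm argument yields -1 rather
#' than NaN: a zero similarity profile carries no evidence of positivity, so
#' it is maximally dissimilar to every centroid and falls to the negative
#' side of any comparison.
#'
#' @param u,v numeric vectors of equal length.
#' @return scalar in \code{[-1, 1]}.
#' @export
cosineSimilarity <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) return(-1)
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

# Row-wise cosine of a matrix against one vector, same zero policy.
.cosineRows <- function(X, v) {
  nv <- sqrt(sum(v * v))
  nx <- sqrt(rowSums(X * X))
  s <- as.numeric(X %*% v)
  out <- rep(-1, nrow(X))
  ok <- nx > 0 & nv > 0
  out[ok] <- pmax(-1, pmin(1, s[ok] / (nx[ok] * nv)))
  out
}

.sqDistRows <- function(X, v) {
  rowSums(sweep(X, 2L, v)^2)
}

#' First assignment of unlabelled samples by cosine similarity
#'
#' Each unlabelled sample is compared by cosine similarity against the
#' positive-seeded centroid and the unlabelled centroid; it is called likely
#' positive only when the positive side strictly wins. Ties go to the
#' negative side: the screen exists to find negatives, so ambiguous points
#' are never called likely positive.
#'
#' @param U numeric matrix of unlabelled feature vectors (rows).
#' @param cPos,cNeg the two centroids.
#' @return list with integer row indices \code{lp} and \code{ln}
#'   partitioning \code{1:nrow(U)}.
#' @export
initialAssign <- function(U, cPos, cNeg) {
  U <- rbind(U)
  sp <- .cosineRows(U, cPos)
  sn <- .cosineRows(U, cNeg)
  lp <- which(sp > sn)
  list(lp = lp, ln = setdiff(seq_len(nrow(U)), lp))
}

#' Refined assignment by squared Euclidean distance
#'
#' Later iterations switch metric: each unlabelled sample joins the side
#' whose current centroid is nearer in squared Euclidean distance.
#' Equidistant points go to the negative side (same conservative tie rule as
#' \code{\link{initialAssign}}).
#'
#' @inheritParams initialAssign
#' @param lPos,lNeg current likely-positive / likely-negative centroids.
#' @return list with indices \code{lp} and \code{ln}.
#' @export
refineAssign <- function(U, lPos, lNeg) {
  U <- rbind(U)
  dp <- .sqDistRows(U, lPos)
  dn <- .sqDistRows(U, lNeg)
  lp <- which(dp < dn)
  list(lp = lp, ln = setdiff(seq_len(nrow(U)), lp))
}

#' Semi-supervised two-centroid K-means screen
#'
#' Preliminary split of the unlabelled set U into likely positives (LP1) and
#' likely negatives (LN1). The positive centroid is seeded from all known
#' positives and the negative centroid from all of U (which still contains
#' hidden positives; that is the method's premise, not a defect). The first
#' assignment uses cosine similarity; every subsequent iteration recomputes
#' both centroids from the current split and reassigns by squared Euclidean
#' distance. The loop stops when the assignment repeats, when the larger of
#' the two centroid movements falls to \code{tol} or below, or at
#' \code{maxIter} assignment rounds.
#'
#' If one side empties during refinement its previous centroid is kept so
#' the run can continue; a side still empty at convergence is returned empty
#' with a warning.
#'
#' @param Pfeat numeric matrix of positive feature vectors (>= 1 row).
#' @param Ufeat numeric matrix of unlabelled feature vectors (>= 2 rows).
#' @param tol non-negative centroid-movement threshold (Euclidean norm),
#'   default \code{1e-6}.
#' @param maxIter maximum assignment rounds, default 100.
#' @return list with \code{lp}, \code{ln} (row indices into \code{Ufeat}),
#'   \code{iterations}, and logical \code{converged} (FALSE only when the
#'   cap stopped the loop).
#' @examples
#' P <- rbind(c(1, 0))
#' U <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0, 1))
#' runSSKmeans(P, U)$ln
#' @export
runSSKmeans <- function(Pfeat, Ufeat, tol = 1e-6, maxIter = 100L) {
  Pfeat <- rbind(Pfeat); Ufeat <- rbind(Ufeat)
  if (nrow(Pfeat) < 1L) stop("need at least one positive sample")
  if (nrow(Ufeat) < 2L) stop("need at least two unlabelled samples")
  stopifnot(tol >= 0, maxIter >= 1L)

  cPos <- centroid(Pfeat)
  cNeg <- centroid(Ufeat)
  asg <- initialAssign(Ufeat, cPos, cNeg)
  iter <- 1L
  converged <- FALSE

  while (iter < maxIter) {
    lPos <- if (length(asg$lp)) centroid(Ufeat[asg$lp, , drop = FALSE]) else cPos
    lNeg <- if (length(asg$ln)) centroid(Ufeat[asg$ln, , drop = FALSE]) else cNeg
    move <- max(sqrt(sum((lPos - cPos)^2)), sqrt(sum((lNeg - cNeg)^2)))
    if (move <= tol) { converged <- TRUE; break }
    nxt <- refineAssign(Ufeat, lPos, lNeg)
    iter <- iter + 1L
    cPos <- lPos; cNeg <- lNeg
    if (identical(nxt$lp, asg$lp)) { asg <- nxt; converged <- TRUE; break }
    asg <- nxt
  }
  if (iter >= maxIter && !converged) {
    # cap reached; report the last assignment as-is
    converged <- FALSE
  }
  if (length(asg$ln) == 0L || length(asg$lp) == 0L) {
    warning("semi-supervised K-means finished with an empty side",
            call. = FALSE)
  }
  list(lp = asg$lp, ln = asg$ln, iterations = iter, converged = converged)
}
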