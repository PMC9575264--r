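# Independent brute-force simulations of the screening equations, coded with
# explicit scalar loops and no shared helpers with the package. Used as
# oracles for the vectorised implementations on small random instances.

bfCos <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(-1)
  sum(u * v) / (nu * nv)
}

bfMean <- function(X) {
  out <- numeric(ncol(X))
  for (i in seq_len(nrow(X))) out <- out + X[i, ]
  out / nrow(X)
}

# step-by-step semi-supervised two-centroid K-means: cosine on the first
# assignment, squared Euclidean afterwards, ties to the negative side
bfSSKmeans <- function(P, U, tol = 1e-6, maxIter = 100L) {
  c1 <- bfMean(P); c2 <- bfMean(U)
  lab <- character(nrow(U))
  for (i in seq_len(nrow(U))) {
    lab[i] <- if (bfCos(U[i, ], c1) > bfCos(U[i, ], c2)) "LP" else "LN"
  }
  iter <- 1L
  while (iter < maxIter) {
    l1 <- if (any(lab == "LP")) bfMean(U[lab == "LP", , drop = FALSE]) else c1
    l2 <- if (any(lab == "LN")) bfMean(U[lab == "LN", , drop = FALSE]) else c2
    if (max(sqrt(sum((l1 - c1)^2)), sqrt(sum((l2 - c2)^2))) <= tol) break
    newLab <- character(nrow(U))
    for (i in seq_len(nrow(U))) {
      d1 <- sum((U[i, ] - l1)^2); d2 <- sum((U[i, ] - l2)^2)
      newLab[i] <- if (d1 < d2) "LP" else "LN"
    }
    iter <- iter + 1L
    c1 <- l1; c2 <- l2
    if (identical(newLab, lab)) { lab <- newLab; break }
    lab <- newLab
  }
  list(lp = which(lab == "LP"), ln = which(lab == "LN"))
}

# weighted difference of normalised-member means; zero-norm members dropped
bfPrototypes <- function(pos, neg, alpha, beta) {
  nmean <- function(X) {
    acc <- numeric(ncol(X)); cnt <- 0
    for (i in seq_len(nrow(X))) {
      nrm <- sqrt(sum(X[i, ]^2))
      if (nrm > 0) { acc <- acc + X[i, ] / nrm; cnt <- cnt + 1 }
    }
    acc / cnt
  }
  list(pos = alpha * nmean(pos) - beta * nmean(neg),
       neg = alpha * nmean(neg) - beta * nmean(pos))
}

bfRocchio1 <- function(P, LN1, alpha = 16, beta = 4) {
  pr <- bfPrototypes(P, LN1, alpha, beta)
  ln2 <- integer(); rp1 <- integer()
  for (i in seq_len(nrow(LN1))) {
    if (bfCos(LN1[i, ], pr$pos) < bfCos(LN1[i, ], pr$neg)) {
      ln2 <- c(ln2, i)
    } else rp1 <- c(rp1, i)
  }
  list(ln2 = ln2, rp1 = rp1)
}

# subsets is a list of row-index vectors partitioning LN2 (the K-means split
# is taken as given; the oracle simulates the prototype comparisons)
bfRocchio2 <- function(P, LN2, subsets, alpha = 16, beta = 4,
                       rule = "any", cluster = NULL) {
  prs <- lapply(subsets, function(idx)
    bfPrototypes(P, LN2[idx, , drop = FALSE], alpha, beta))
  rn <- integer()
  for (i in seq_len(nrow(LN2))) {
    if (sqrt(sum(LN2[i, ]^2)) == 0) next
    wins <- vapply(prs, function(pr)
      bfCos(LN2[i, ], pr$neg) > bfCos(LN2[i, ], pr$pos), logical(1))
    ok <- switch(rule,
                 any = any(wins),
                 all = all(wins),
                 nearest = {
                   own <- which(vapply(subsets, function(s) i %in% s,
                                       logical(1)))
                   wins[own]
                 })
    if (ok) rn <- c(rn, i)
  }
  rn
}

# small random screening instance: nP positives, nU unlabelled, dim features
randomInstance <- function(seed, maxN = 20L, maxDim = 5L) {
  set.seed(seed)
  d <- sample(2:maxDim, 1)
  nP <- sample(1:5, 1)
  nU <- sample(4:(maxN - nP), 1)
  list(P = matrix(runif(nP * d), nP, d),
       U = matrix(runif(nU * d), nU, d))
}
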