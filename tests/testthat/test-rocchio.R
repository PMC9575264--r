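test_that("prototype pairs follow the weighted normalised-mean form", {
  pr <- prototypePair(rbind(c(3, 4)), rbind(c(0, 1)), alpha = 1, beta = 0)
  expect_equal(pr$cPos, c(0.6, 0.8))

  pr2 <- prototypePair(rbind(c(1, 0)), rbind(c(0, 1)))
  expect_equal(pr2$cPos, c(16, -4))   # defaults alpha = 16, beta = 4
  expect_equal(pr2$cNeg, c(-4, 16))

  # zero-norm members are excluded from the mean, with a message
  expect_message(
    pr3 <- prototypePair(rbind(c(0, 0), c(1, 0)), rbind(c(0, 1)),
                         alpha = 1, beta = 0),
    "zero-norm")
  expect_equal(pr3$cPos, c(1, 0))

  expect_error(prototypePair(matrix(numeric(), 0, 2), rbind(c(0, 1))),
               "empty")
})

test_that("rocchio round 1 splits by prototype cosine, ties to the positive side", {
  # sample aligned with the negative prototype direction
  P <- rbind(c(1, 0)); LN1 <- rbind(c(0, 1), c(1, 0))
  r <- rocchio1(P, LN1, rocchioConfig(alpha = 16, beta = 4))
  expect_equal(r$ln2, 1L)   # (0,1) is the negative direction
  expect_equal(r$rp1, 2L)   # (1,0) looks positive

  # an exact tie falls into "otherwise" = reliable positive
  Psym <- rbind(c(1, 0), c(0, 1)); LNsym <- rbind(c(1, 0), c(0, 1))
  rsym <- rocchio1(Psym, LNsym, rocchioConfig())
  tied <- which(abs(rsym$margin) < 1e-12)
  expect_true(all(tied %in% rsym$rp1))

  expect_warning(r0 <- rocchio1(P, matrix(numeric(), 0, 2)), "empty")
  expect_length(r0$ln2, 0)
})

test_that("round-1 membership equals the brute-force oracle", {
  for (s in 31:60) {
    inst <- randomInstance(s)
    got <- rocchio1(inst$P, inst$U)
    exp <- bfRocchio1(inst$P, inst$U)
    expect_equal(got$ln2, exp$ln2, info = sprintf("seed %d", s))
    expect_equal(got$rp1, exp$rp1, info = sprintf("seed %d", s))
  }
})

test_that("kmeansPartition is deterministic and respects k", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 0, .2), 10, 2),
             matrix(rnorm(20, 8, .2), 10, 2))
  p1 <- kmeansPartition(X, 1)
  expect_length(p1$subsets, 1)
  expect_setequal(p1$subsets[[1]], 1:20)

  pn <- kmeansPartition(X[1:4, ], 4, seed = 2)
  expect_length(pn$subsets, 4)
  expect_true(all(lengths(pn$subsets) == 1))

  p2 <- kmeansPartition(X, 2, seed = 9)
  grp <- vapply(p2$subsets, function(s) all(s <= 10) || all(s > 10),
                logical(1))
  expect_true(all(grp))  # blobs recovered
  expect_identical(p2, kmeansPartition(X, 2, seed = 9))

  expect_warning(pr <- kmeansPartition(X[1:2, ], 5), "reducing k")
  expect_length(pr$subsets, 2)
})

test_that("round 2 with k = 1 collapses to a single prototype comparison", {
  set.seed(8)
  P <- matrix(runif(8), 4, 2)
  LN2 <- matrix(runif(12), 6, 2)
  cfg1 <- rocchioConfig(kSubsets = 1)
  r2 <- rocchio2(P, LN2, cfg1)
  # same comparison as a rocchio1-style screen with roles from round 2
  pr <- prototypePair(P, LN2)
  expRN <- which(vapply(seq_len(6), function(i)
    cosineSimilarity(LN2[i, ], pr$cNeg) >
      cosineSimilarity(LN2[i, ], pr$cPos), logical(1)))
  expect_equal(r2$rn, expRN)
})

test_that("round-2 membership equals the brute-force oracle for every rule", {
  for (s in 61:80) {
    inst <- randomInstance(s)
    if (nrow(inst$U) < 3) next
    for (rule in c("any", "all", "nearest")) {
      cfg <- rocchioConfig(kSubsets = 2, kmeansSeed = 3, rule = rule)
      got <- rocchio2(inst$P, inst$U, cfg)
      part <- kmeansPartition(inst$U, 2, seed = 3)
      exp <- bfRocchio2(inst$P, inst$U, part$subsets, rule = rule)
      expect_equal(got$rn, exp, info = sprintf("seed %d rule %s", s, rule))
      expect_true(all(got$rn %in% seq_len(nrow(inst$U))))
    }
  }
})

test_that("classifications are invariant to positive rescaling of features", {
  set.seed(12)
  P <- matrix(runif(10), 5, 2)
  U <- matrix(runif(16), 8, 2)
  for (k in c(0.2, 7)) {
    expect_equal(rocchio1(P, U)$ln2, rocchio1(P * k, U * k)$ln2)
    cfg <- rocchioConfig(kSubsets = 2, kmeansSeed = 4)
    expect_equal(rocchio2(P, U, cfg)$rn, rocchio2(P * k, U * k, cfg)$rn)
  }
})

test_that("beta = 0, k = 1 reduces to nearest normalised mean by cosine", {
  P <- rbind(c(1, 0), c(0.8, 0.6))
  N <- rbind(c(0, 1), c(0.6, 0.8))
  cfg <- rocchioConfig(alpha = 1, beta = 0, kSubsets = 1)
  r <- rocchio2(P, N, cfg)
  mp <- colMeans(P / sqrt(rowSums(P^2)))
  mn <- colMeans(N / sqrt(rowSums(N^2)))
  expRN <- which(vapply(seq_len(2), function(i)
    cosineSimilarity(N[i, ], mn) > cosineSimilarity(N[i, ], mp),
    logical(1)))
  expect_equal(r$rn, expRN)
})

test_that("zero-norm samples are never admitted to RN", {
  P <- rbind(c(1, 0))
  LN2 <- rbind(c(0, 1), c(0, 0))
  r <- rocchio2(P, LN2, rocchioConfig(kSubsets = 1))
  expect_false(2L %in% r$rn)
})
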