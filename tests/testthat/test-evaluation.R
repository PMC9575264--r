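test_that("metrics are exact on hand-scored folds", {
  # perfectly separating scores
  m <- classificationMetrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(m), rep(1, 6))

  # AUC by exhaustive pair-ranking: 1 discordant of the 4 pos x neg pairs
  m2 <- classificationMetrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(m2["auc"]), 3 / 4)

  expect_error(classificationMetrics(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("auc agrees with the Mann-Whitney rank statistic", {
  set.seed(31)
  for (i in 1:20) {
    n <- 30
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- runif(n) + labels * runif(1)
    got <- classificationMetrics(scores, labels)[["auc"]]
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    expect_equal(got, mean(cmp))
  }
})

test_that("aupr reduces to prevalence for constant scores and to 1 for perfect", {
  labels <- c(1, 1, 0, 0, 0, 1)
  m <- classificationMetrics(rep(0.7, 6), labels, threshold = 0.5)
  expect_equal(unname(m["aupr"]), 0.5)
  m2 <- classificationMetrics(c(.9, .8, .2, .1, .3, .7), labels)
  expect_equal(unname(m2["aupr"]), 1)
})

test_that("random scores give chance-level auc on average", {
  set.seed(99)
  aucs <- replicate(200, {
    labels <- rep(c(0, 1), each = 10)
    classificationMetrics(runif(20), labels)[["auc"]]
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("stratified folds balance classes and demand enough samples", {
  labels <- rep(c(0, 1), c(40, 20))
  f <- stratifiedFolds(labels, k = 5, seed = 3)
  for (k in 1:5) {
    expect_equal(sum(f == k & labels == 1), 4)
    expect_equal(sum(f == k & labels == 0), 8)
  }
  expect_identical(f, stratifiedFolds(labels, k = 5, seed = 3))
  expect_error(stratifiedFolds(rep(c(0, 1), c(30, 3)), k = 5), "at least")
  expect_error(stratifiedFolds(rep(1, 20), k = 5), "at least")
})

test_that("cross-validation is perfect when features determine labels", {
  set.seed(7)
  labels <- rep(c(0, 1), each = 25)
  features <- cbind(x = labels + rnorm(50, 0, 0.01), y = rnorm(50))
  rep1 <- fivefoldCV(features, labels, seed = 2)
  expect_equal(unname(rep1$pooled), rep(1, 6), tolerance = 1e-6)
  expect_equal(nrow(rep1$perFold), 5)
  expect_equal(rep1$nPos, 25)
  # pooled metrics are the mean over folds
  expect_equal(unname(rep1$pooled["auc"]), mean(rep1$perFold$auc))
})

test_that("negative-selection strategies stay inside their candidate pools", {
  syn <- generateSynthetic(syntheticConfig(nMirna = 24, nDisease = 16,
                                           seed = 11))
  data <- syn$data
  sets <- partitionSamples(data)
  big <- length(sets@U) + 5L
  pools <- suppressWarnings(lapply(
    c(kr_nssm = "kr_nssm", ss = "ss_kmeans_only", roc = "rocchio_only",
      rand = "random"),
    function(st) selectNegatives(st, data, big)))
  # containment chain: full screen draws from within the K-means arm's pool
  expect_true(all(pools$kr_nssm %in% pools$ss))
  expect_true(all(unlist(pools) %in% sets@U))
  expect_setequal(pools$rand, sets@U)

  n4 <- selectNegatives("random", data, 4, seed = 5)
  expect_length(n4, 4)
  expect_identical(n4, selectNegatives("random", data, 4, seed = 5))
})

test_that("cluster-stratified random selection allocates proportionally", {
  # two crisp miRNA blocks of equal size -> two equal clusters of pairs
  v <- matrix(0, 4, 4); v[1:2, 1:2] <- 0.9; v[3:4, 3:4] <- 0.9; diag(v) <- 1
  simM <- SimilarityMatrix(v, sprintf("m%d", 1:4))
  simD <- SimilarityMatrix(diag(2), c("d1", "d2"))
  data <- screenData(data.frame(mirna = character(), disease = character()),
                     simM, simD)
  got <- selectNegatives("kmeans_cluster_random", data, 4, seed = 2,
                         cfg = screenConfig(kSubsets = 2L))
  expect_length(got, 4)
  # pairs 1:4 come from miRNA block 1, pairs 5:8 from block 2
  expect_equal(sum(got <= 4), 2)
  expect_equal(sum(got > 4), 2)
})

test_that("ablation rows are deterministic and sd collapses for one seed", {
  syn <- generateSynthetic(syntheticConfig(nMirna = 24, nDisease = 16,
                                           seed = 13))
  tab <- suppressWarnings(ablationTable(
    syn$data, seeds = 1L,
    strategies = c("ss_kmeans_only", "ss_kmeans_only", "random")))
  expect_equal(tab$summary$auc_sd, rep(0, 3))
  r1 <- tab$summary[1, -1]; r2 <- tab$summary[2, -1]
  expect_equal(unname(unlist(r1)), unname(unlist(r2)))
  expect_true(all(c("strategy", "seed", "auc", "aupr") %in%
                    names(tab$runs)))
  f <- tempfile(fileext = ".csv")
  tab2 <- suppressWarnings(ablationTable(
    syn$data, seeds = 1L, strategies = "random", file = f))
  expect_true(file.exists(f))
  expect_equal(nrow(read.csv(f)), 1)
})
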