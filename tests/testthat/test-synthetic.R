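test_that("generated similarity matrices are symmetric with unit diagonal", {
  syn <- generateSynthetic(syntheticConfig(nMirna = 20, nDisease = 12,
                                           seed = 2))
  for (sim in list(syn$data@simM, syn$data@simD)) {
    v <- simValues(sim)
    expect_identical(v, t(v))
    expect_equal(unname(diag(v)), rep(1, nrow(v)))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("the same seed reproduces the dataset exactly", {
  a <- generateSynthetic(syntheticConfig(seed = 17))
  b <- generateSynthetic(syntheticConfig(seed = 17))
  expect_identical(simValues(a$data@simM), simValues(b$data@simM))
  expect_identical(a$data@assoc, b$data@assoc)
  expect_identical(a$truth@hiddenPositive, b$truth@hiddenPositive)
  c <- generateSynthetic(syntheticConfig(seed = 18))
  expect_false(identical(a$truth@truePositive, c$truth@truePositive))
})

test_that("a noiseless single block is uniformly similar off-diagonal", {
  syn <- generateSynthetic(syntheticConfig(nMirna = 8, nDisease = 6,
                                           nBlocks = 1, simNoiseSd = 0,
                                           withinSim = 0.6, seed = 1))
  v <- simValues(syn$data@simM)
  expect_true(all(v[upper.tri(v)] == 0.6))
})

test_that("hideFrac = 0 leaves no hidden positives in U", {
  syn <- generateSynthetic(syntheticConfig(nMirna = 20, nDisease = 12,
                                           hideFrac = 0, seed = 4))
  expect_length(syn$truth@hiddenPositive, 0)
  u <- sampleSet(partitionSamples(syn$data), "U")
  expect_equal(negativePurity(u, syn$truth), 1)
})

test_that("planted positive counts sit inside their sampling interval", {
  cfg <- syntheticConfig(nMirna = 30, nDisease = 20, posRateIn = 0.5,
                         posRateOut = 0.02, seed = 21)
  syn <- generateSynthetic(cfg)
  # recompute the expected count from the block layout (sizes follow the
  # documented geometric 1:2:4 profile) and bound it by a 3-sigma interval
  sizes <- function(n) {
    w <- c(1, 2, 4); s <- floor(n * w / 7)
    rem <- n - sum(s)
    s[order(n * w / 7 - s, decreasing = TRUE)[seq_len(rem)]] <-
      s[order(n * w / 7 - s, decreasing = TRUE)[seq_len(rem)]] + 1L
    s
  }
  inCells <- sum(sizes(30) * sizes(20))
  outCells <- 30 * 20 - inCells
  mu <- inCells * 0.5 + outCells * 0.02
  sig <- sqrt(inCells * 0.25 + outCells * 0.02 * 0.98)
  got <- length(syn$truth@truePositive)
  expect_gt(got, mu - 3 * sig)
  expect_lt(got, mu + 3 * sig)
  # hidden fraction honoured
  expect_equal(length(syn$truth@hiddenPositive), round(0.2 * got))
})

test_that("negative purity counts truth labels exactly", {
  truth <- new("SyntheticTruth", nMirna = 5L, nDisease = 2L,
               truePositive = c(1L, 4L, 6L, 9L),
               observedPositive = c(1L, 4L),
               hiddenPositive = c(6L, 9L))
  # 10 pairs, U = {2,3,5,6,7,8,9,10}; 6 and 9 are hidden positives
  expect_equal(negativePurity(c(2L, 3L, 5L), truth), 1)
  expect_equal(negativePurity(c(2L, 6L, 9L, 10L), truth), 0.5)
  U <- setdiff(1:10, c(1L, 4L))
  expect_equal(negativePurity(U, truth), 6 / 8)
  expect_error(negativePurity(c(1L, 2L), truth), "inside the unlabelled")
  expect_error(negativePurity(c(11L), truth), "inside the unlabelled")
  expect_warning(p <- negativePurity(integer(), truth), "convention")
  expect_equal(p, 1)
})

test_that("stronger planted contrast never degrades mean screening purity", {
  spreads <- list(c(0.45, 0.35), c(0.60, 0.30), c(0.70, 0.20))
  mp <- vapply(spreads, function(sp) {
    mean(vapply(1:10, function(s) {
      syn <- generateSynthetic(syntheticConfig(
        nMirna = 30, nDisease = 20, withinSim = sp[1], betweenSim = sp[2],
        seed = s))
      res <- suppressWarnings(krNSSM(syn$data, verbose = FALSE))
      suppressWarnings(negativePurity(reliableNegatives(res), syn$truth))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mp) >= -0.005))
})

test_that("config validation rejects impossible block layouts", {
  expect_error(syntheticConfig(nMirna = 2, nDisease = 40, nBlocks = 3),
               "block")
  expect_error(syntheticConfig(withinSim = 0.3, betweenSim = 0.5))
})
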