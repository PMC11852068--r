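test_that("binarization keeps strictly supra-threshold edges only", {
  w <- matrix(0.2, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.6
  w[2, 3] <- w[3, 2] <- 0.7
  diag(w) <- 1
  g <- binarize(w, 0.5)
  expect_equal(edgeCount(g), 3)
  expect_equal(nodeDegrees(g), c(2L, 2L, 2L, 0L))

  dense <- matrix(0.9, 5, 5)
  expect_equal(edgeCount(binarize(dense, 0)), 10)
  expect_equal(edgeCount(binarize(dense, 1)), 0)
  # strict inequality: weights equal to tau are dropped
  expect_equal(edgeCount(binarize(dense, 0.9)), 0)

  bad <- matrix(runif(16), 4)
  expect_error(binarize(bad, 0.5), "data error")
})

test_that("binarization is monotone in the threshold", {
  set.seed(20)
  for (rep in 1:10) {
    w <- randomSymWeights(8)
    taus <- sort(runif(4))
    graphs <- lapply(taus, function(tau) adjacencyMatrix(binarize(w, tau)))
    for (i in seq_len(length(taus) - 1)) {
      expect_true(all(graphs[[i + 1]] <= graphs[[i]]))
    }
  }
})

test_that("Surprise matches the exact hypergeometric tail", {
  g <- binaryGraph(trianglePlusIsolate())
  expect_equal(surpriseOfPartition(g, partition(c(0, 0, 0, 1))), 1.30103,
               tolerance = 1e-5)
  # forced-trivial partitions score zero
  expect_equal(surpriseOfPartition(g, partition(rep(0, 4))), 0)
  expect_equal(surpriseOfPartition(g, partition(0:3)), 0)
  expect_message(s0 <- surpriseOfPartition(binaryGraph(matrix(0, 3, 3)),
                                           partition(c(0, 0, 1))), "edgeless")
  expect_equal(s0, 0)

  # random graphs, random partitions: log-space tail vs exact summation
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    adj <- randomAdjacency(n, runif(1, 0.2, 0.8))
    labels <- sample(0:(n - 1), n, replace = TRUE)
    gg <- binaryGraph(adj)
    got <- if (gg@m == 0) {
      suppressMessages(surpriseOfPartition(gg, partition(labels)))
    } else {
      surpriseOfPartition(gg, partition(labels))
    }
    expect_equal(got, surpriseOracle(adj, labels), tolerance = 1e-9)
  }
})

test_that("the Surprise greedy recovers exhaustive maxima at small n", {
  two <- binaryGraph(twoTriangles())
  p <- detectCommunitiesSurprise(two, seed = 1)
  expect_equal(communityLabels(p), c(0L, 0L, 0L, 1L, 1L, 1L))

  # complete graph: every partition scores 0 (verified exhaustively)
  comp <- binaryGraph(matrix(1, 5, 5) - diag(5))
  expect_equal(exhaustiveMax(adjacencyMatrix(comp), surpriseOracle), 0)
  pc <- detectCommunitiesSurprise(comp, seed = 1)
  expect_equal(surpriseOfPartition(comp, pc), 0)

  set.seed(22)
  hits <- 0
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    adj <- randomAdjacency(n, runif(1, 0.25, 0.7))
    if (sum(adj) == 0) adj[1, 2] <- adj[2, 1] <- 1
    g <- binaryGraph(adj)
    got <- surpriseOfPartition(g, detectCommunitiesSurprise(g, seed = rep))
    best <- exhaustiveMax(adj, surpriseOracle)
    expect_lte(got, best + 1e-9)
    if (abs(got - best) < 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("percolation profiles are correct and non-increasing", {
  set.seed(23)
  w <- randomSymWeights(10, 0.2, 0.9)
  offdiag <- w[upper.tri(w)]
  expect_equal(percolationProfile(w, min(offdiag) - 0.01), 1)
  expect_equal(percolationProfile(w, max(offdiag)), 1 / 10)
  taus <- seq(0.1, 0.95, by = 0.05)
  for (rep in 1:5) {
    prof <- percolationProfile(randomSymWeights(10), taus)
    expect_true(all(diff(prof) <= 1e-12))
  }
  expect_error(percolationProfile(w, c(0.5, 0.2)), "sorted")
})

test_that("optimal-threshold selection maximizes mean Surprise", {
  # planted two-module structure: within 0.8, between 0.3; only thresholds in
  # the gap separate the modules
  w <- matrix(0.3, 16, 16)
  w[1:8, 1:8] <- 0.8
  w[9:16, 9:16] <- 0.8
  diag(w) <- 1
  vals <- array(0, dim = c(2, 3, 16, 16))
  for (tr in 1:2) for (wi in 1:3) vals[tr, wi, , ] <- w
  tens <- syntheticTensor(vals, winLen = 100, step = 50)
  sw <- selectOptimalThreshold(list(tens), seed = 1)
  expect_s4_class(sw, "ThresholdSweep")
  expect_length(sw@thresholds, 100)
  expect_equal(sw@thresholds, (1:100) / 101)
  expect_gt(optimalThreshold(sw), 0.3)
  expect_lt(optimalThreshold(sw), 0.8)

  # constant surprise (all-ones matrices): tie broken to the smallest tau
  ones <- array(1, dim = c(1, 2, 6, 6))
  to <- syntheticTensor(ones, winLen = 100, step = 50)
  swt <- selectOptimalThreshold(list(to), seed = 1)
  expect_equal(optimalThreshold(swt), 1 / 101)

  expect_error(selectOptimalThreshold(list()), "parameter error")
})

test_that("threshold selection is invariant to subject and trial order", {
  set.seed(24)
  vals <- array(runif(4 * 2 * 8 * 8, 0.2, 0.9), dim = c(4, 2, 8, 8))
  for (tr in 1:4) for (wi in 1:2) {
    m <- vals[tr, wi, , ]
    m <- (m + t(m)) / 2
    diag(m) <- 1
    vals[tr, wi, , ] <- m
  }
  t1 <- syntheticTensor(vals, winLen = 100, step = 50)
  t2 <- syntheticTensor(vals[c(3, 1, 4, 2), , , , drop = FALSE],
                        winLen = 100, step = 50)
  s12 <- selectOptimalThreshold(list(t1, t2), seed = 1)
  s21 <- selectOptimalThreshold(list(t2, t1), seed = 1)
  expect_equal(s12@meanSurprise, s21@meanSurprise, tolerance = 1e-12)
  expect_equal(optimalThreshold(s12), optimalThreshold(s21))
})
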