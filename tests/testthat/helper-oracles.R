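# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: exact combinatorial sums, literal double-sum
# formulas, and exhaustive partition enumeration at small n.

# all set partitions of n elements as restricted growth strings (0-based)
allPartitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxUsed) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in 0:(maxUsed + 1L)) rec(c(prefix, v), max(maxUsed, v))
  }
  rec(integer(0), -1L)
  res
}

# exact hypergeometric tail Surprise from direct summation of choose() terms
# (all quantities are small integers at n <= 8, so doubles are exact)
surpriseOracle <- function(adj, labels) {
  n <- nrow(adj)
  M <- n * (n - 1) / 2
  m <- sum(adj[upper.tri(adj)])
  if (m == 0) return(0)
  sizes <- table(labels)
  Mint <- sum(sizes * (sizes - 1) / 2)
  same <- outer(labels, labels, "==")
  mint <- sum(adj[same & upper.tri(adj)])
  jmax <- min(m, Mint)
  if (mint <= 0) return(0)
  tail <- sum(sapply(mint:jmax, function(j)
    choose(Mint, j) * choose(M - Mint, m - j))) / choose(M, m)
  max(0, -log10(tail))
}

# literal pairwise double-sum modularity
modularityOracle <- function(adj, labels) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  m <- sum(deg) / 2
  if (m == 0) return(0)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# exhaustive maxima over all partitions
exhaustiveMax <- function(adj, score) {
  best <- -Inf
  for (p in allPartitions(nrow(adj))) {
    v <- score(adj, p)
    if (v > best) best <- v
  }
  best
}

randomAdjacency <- function(n, p) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

randomSymWeights <- function(n, lo = 0, hi = 1) {
  w <- matrix(stats::runif(n * n, lo, hi), n)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  w
}

# adjacency of two disconnected triangles on 6 nodes
twoTriangles <- function() {
  a <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

trianglePlusIsolate <- function() {
  a <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(1, 3), c(2, 3))) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}

# build a CoherenceTensor directly from a stack of weight matrices
# (trials x windows x n x n), bypassing the estimation chain
syntheticTensor <- function(values, band = canonicalBands()$beta,
                            winLen = 256, step = 128, fs = 1000) {
  d <- dim(values)
  epochLen <- (d[2] - 1) * step + winLen
  plan <- planWindows(epochLen, winLen, step, eventSample = epochLen / 2)
  stopifnot(plan@nWindows == d[2])
  new("CoherenceTensor", subjectId = "SYN", band = band, values = values,
      windowPlan = plan)
}

# quick single-subject planted-effect cohort config at the analysis rate
plantedConfig <- function(seed, nTrials = 20, gains = c(0.3, 0.8),
                          nSubjects = 1) {
  cohortConfig(nSubjects = nSubjects, nTrials = nTrials, fsRaw = 1000,
               seed = seed, bandCoupling = list(beta = gains),
               bands = canonicalBands()["beta"])
}

# beta-band feature table from one recording (the short path used by tests)
betaFeaturesFromRecording <- function(rec, seed = 1, tau = NULL) {
  sig <- broadbandFilter(signalMatrix(rec), samplingRate(rec))
  sig <- removeLineNoise(sig, samplingRate(rec))
  bands <- bandDecompose(sig, samplingRate(rec), canonicalBands()["beta"])
  ep <- extractEpochs(rec, bands$beta, samplingRate(rec),
                      band = canonicalBands()$beta)
  plan <- planWindows(dim(epochData(ep))[3], 256, 128,
                      eventSample = 1000)
  tens <- coherenceTensor(ep, plan)
  if (is.null(tau)) {
    tau <- optimalThreshold(selectOptimalThreshold(list(tens), seed = seed))
  }
  suppressWarnings(featuresPerWindow(tens, tau, seed = seed))
}

# synthetic NetFeatureTable with a planted pre/post offset on k_bar
syntheticFeatureTable <- function(nSubjects = 1, nTrials = 60, nWindows = 14,
                                  offset = 0, seed = 1, band = "beta") {
  set.seed(seed)
  rows <- expand.grid(trial = seq_len(nTrials), window = seq_len(nWindows),
                      subject_id = sprintf("S%02d", seq_len(nSubjects)),
                      stringsAsFactors = FALSE)
  rows$band <- band
  rows$condition <- ifelse(rows$window <= nWindows / 2, "pre", "post")
  post <- rows$condition == "post"
  rows$k_bar <- stats::rnorm(nrow(rows), 5 + offset * post, 1)
  rows$Q <- stats::rnorm(nrow(rows), 0.3 - 0.02 * offset * post, 0.05)
  rows
}
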