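test_that("window plans tile epochs and split conditions by midpoint", {
  p <- planWindows(2000, 256, 128, eventSample = 1000)
  expect_equal(p@nWindows, 14)
  expect_equal(sum(windowConditions(p) == "pre"), 7)
  expect_equal(sum(windowConditions(p) == "post"), 7)
  expect_equal(p@starts, seq(0, by = 128, length.out = 14))

  expect_equal(planWindows(256, 256, 128, 128)@nWindows, 1)
  expect_equal(planWindows(1000, 256, 128, 500)@nWindows, 6)
  expect_error(planWindows(100, 256, 128, 50), "parameter error")
})

test_that("DPSS tapers are orthonormal and concentration-ordered", {
  tp <- dpssTapers(256, 3, 5)
  expect_equal(dim(tp), c(256, 5))
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-9)
  # in-band energy concentration decreases with taper order
  conc <- apply(tp, 2, function(h) {
    H <- abs(fft(c(h, rep(0, 768))))^2
    W <- 3 / 256
    inBand <- sum(H[abs((0:1023) / 1024 - 0) <= W | (0:1023) / 1024 >= 1 - W])
    inBand / sum(H)
  })
  expect_true(all(diff(conc) < 0))
  expect_error(dpssTapers(256, 3, 8), "parameter error")
})

test_that("multitaper coherence identities hold", {
  set.seed(10)
  x <- rnorm(256)
  co <- mtmCoherence(x, x, 1000)
  expect_true(all(abs(co$coherence - 1) < 1e-9))

  # scale invariance
  y <- rnorm(256)
  c1 <- mtmCoherence(x, y, 1000)$coherence
  c2 <- mtmCoherence(3.7 * x, 0.2 * y, 1000)$coherence
  expect_lt(max(abs(c1 - c2)), 1e-9)

  expect_warning(z <- mtmCoherence(rep(0, 256), y, 1000), "zero-variance")
  expect_true(all(z$coherence == 0))
})

test_that("independent-signal coherence sits at a bias floor decreasing in k", {
  set.seed(11)
  floorAt <- function(k, reps = 300) {
    mean(replicate(reps, {
      mean(mtmCoherence(rnorm(256), rnorm(256), 1000, nw = 3, k = k)$coherence)
    }))
  }
  floors <- sapply(c(2, 3, 5), floorAt)
  # the floor scales like 1/k: the 5-taper estimate sits in (0.05, 0.45)
  expect_gt(floors[3], 0.05)
  expect_lt(floors[3], 0.45)
  expect_true(all(diff(floors) < 0))
})

test_that("a shared narrowband component produces near-unit coherence", {
  set.seed(12)
  t <- (0:255) / 1000
  s <- sin(2 * pi * 20 * t)
  snr <- 10
  noiseSd <- sqrt(stats::var(s) / snr)
  x <- s + rnorm(256, sd = noiseSd)
  y <- s + rnorm(256, sd = noiseSd)
  co <- mtmCoherence(x, y, 1000)
  bin <- which.min(abs(co$freq - 20))
  expect_gt(co$coherence[bin], 0.9)
})

test_that("band adjacency matrices behave at the extremes", {
  beta <- canonicalBands()$beta
  set.seed(13)
  base <- rnorm(256)
  same <- matrix(rep(base, 4), nrow = 4, byrow = TRUE)
  adjSame <- bandAdjacency(same, 1000, beta)
  expect_true(all(abs(adjSame - 1) < 1e-9))

  indep <- matrix(rnorm(16 * 256), nrow = 16)
  adjInd <- bandAdjacency(indep, 1000, beta)
  expect_true(isSymmetric(adjInd))
  expect_true(all(diag(adjInd) == 1))
  offdiag <- adjInd[upper.tri(adjInd)]
  expect_lt(mean(offdiag), 3 * 0.2)

  # planted coupled pair stands out from the independent background
  shared <- rnorm(256)
  planted <- indep
  planted[1, ] <- shared + rnorm(256, sd = 0.3)
  planted[2, ] <- shared + rnorm(256, sd = 0.3)
  adjP <- bandAdjacency(planted, 1000, beta)
  expect_gt(adjP[1, 2], stats::median(adjP[upper.tri(adjP)]))

  expect_error(bandAdjacency(indep, 1000, bandSpec("narrow", 20, 20.5)),
               "parameter error")
})

test_that("the coherence tensor assembles per-window adjacencies", {
  beta <- canonicalBands()$beta
  set.seed(14)
  data <- array(rnorm(3 * 4 * 512), dim = c(3, 4, 512))
  ep <- new("EpochSet", band = beta, fs = 1000, data = data,
            eventSample = 256, subjectId = "X")
  plan <- planWindows(512, 256, 128, 256)
  tens <- coherenceTensor(ep, plan)
  expect_equal(dim(coherenceValues(tens)), c(3, 3, 4, 4))
  rng <- range(coherenceValues(tens))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  for (tr in 1:3) for (w in 1:3) {
    a <- coherenceValues(tens)[tr, w, , ]
    expect_true(isSymmetric(a))
    expect_true(all(diag(a) == 1))
  }

  # degenerate single window equals bandAdjacency directly
  ep1 <- new("EpochSet", band = beta, fs = 1000,
             data = array(data[1, , 1:256], dim = c(1, 4, 256)),
             eventSample = 128, subjectId = "X")
  plan1 <- planWindows(256, 256, 128, 128)
  t1 <- coherenceTensor(ep1, plan1)
  direct <- bandAdjacency(matrix(data[1, , 1:256], nrow = 4), 1000, beta)
  expect_equal(coherenceValues(t1)[1, 1, , ], direct, tolerance = 1e-12)

  # permuting trials permutes axis 1 identically
  perm <- c(2, 3, 1)
  epP <- new("EpochSet", band = beta, fs = 1000,
             data = data[perm, , , drop = FALSE], eventSample = 256,
             subjectId = "X")
  tensP <- coherenceTensor(epP, plan)
  expect_equal(coherenceValues(tensP), coherenceValues(tens)[perm, , , ,
                                                             drop = FALSE])
})

test_that("global mean coherence reduces the tensor correctly", {
  ones <- array(1, dim = c(2, 3, 4, 4))
  tens <- syntheticTensor(ones, winLen = 100, step = 50)
  expect_equal(globalMeanCoherence(tens), rep(1, 3))

  # with a single channel pair the trace equals that pair's mean
  set.seed(15)
  vals <- array(0, dim = c(5, 3, 2, 2))
  for (tr in 1:5) for (w in 1:3) {
    v <- runif(1)
    vals[tr, w, , ] <- matrix(c(1, v, v, 1), 2)
  }
  t2 <- syntheticTensor(vals, winLen = 100, step = 50)
  expect_equal(globalMeanCoherence(t2),
               apply(vals[, , 1, 2], 2, mean))
})
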