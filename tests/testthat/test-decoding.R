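test_that("feature matrices have the contracted geometry", {
  ft <- syntheticFeatureTable(nSubjects = 1, nTrials = 60, nWindows = 14,
                              offset = 1, seed = 50)
  fmD <- assembleFeatures(ft, "beta", "degree")
  expect_equal(dim(fmD$X), c(120, 7))
  expect_equal(as.vector(table(fmD$y)), c(60, 60))

  fmC <- assembleFeatures(ft, "beta", "combined")
  expect_equal(dim(fmC$X), c(120, 14))
  expect_equal(colnames(fmC$X)[c(1, 8)], c("k_bar_w1", "Q_w1"))

  ft4 <- syntheticFeatureTable(nSubjects = 4, nTrials = 60, nWindows = 14,
                               offset = 1, seed = 51)
  fm4 <- assembleFeatures(ft4, "beta", "combined")
  expect_equal(dim(fm4$X), c(480, 14))
  expect_equal(nrow(fm4$rowMeta), 480)
  expect_setequal(unique(fm4$rowMeta$subject_id),
                  sprintf("S%02d", 1:4))

  # window values appear in temporal order
  sub <- ft[ft$trial == 5 & ft$condition == "pre", ]
  expect_equal(unname(fmD$X[fmD$rowMeta$trial == 5 & fmD$y == "pre", ]),
               sub$k_bar[order(sub$window)])

  expect_error(assembleFeatures(ft, "delta"), "parameter error")
  ragged <- ft[-3, ]
  expect_error(assembleFeatures(ragged, "beta"), "data error")
})

test_that("stratified folds partition rows with balanced classes", {
  ft <- syntheticFeatureTable(nTrials = 60, offset = 0, seed = 52)
  fm <- assembleFeatures(ft, "beta", "degree")
  folds <- nclnet:::stratifiedFolds(fm$y, 10, seed = 7)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 12))
  tab <- table(folds, fm$y)
  expect_true(all(abs(tab - 6) <= 1))
})

test_that("all decoders solve a linearly separable toy problem", {
  ft <- syntheticFeatureTable(nTrials = 30, offset = 10, seed = 53)
  fm <- assembleFeatures(ft, "beta", "degree")
  for (dec in c("margin", "recurrent", "tree")) {
    r <- tenFoldCv(fm, dec, seed = 1)
    expect_equal(meanAccuracy(r), 1.0)
    expect_equal(aucOf(r), 1.0)
  }
  expect_error(tenFoldCv(fm, "perceptron", seed = 1), "registered")
})

test_that("decoders sit at chance on label-free data", {
  accs <- sapply(1:6, function(s) {
    ft <- syntheticFeatureTable(nTrials = 30, offset = 0, seed = 100 + s)
    meanAccuracy(tenFoldCv(assembleFeatures(ft, "beta", "degree"),
                           "margin", seed = s))
  })
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
  # chance is inside the binomial 99% band pooled over folds
  n <- 6 * 60
  expect_gt(stats::binom.test(round(mean(accs) * n), n, 0.5)$p.value, 0.01)

  ft <- syntheticFeatureTable(nTrials = 30, offset = 0, seed = 110)
  for (dec in c("recurrent", "tree")) {
    a <- meanAccuracy(tenFoldCv(assembleFeatures(ft, "beta", "degree"),
                                dec, seed = 3))
    expect_gt(a, 0.3)
    expect_lt(a, 0.7)
  }
})

test_that("ROC curves follow the half-tie trapezoid convention", {
  rc <- rocCurve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(rc$auc, 0.75)
  expect_equal(rc$roc[1, ], c(fpr = 0, tpr = 0))
  expect_equal(rc$roc[nrow(rc$roc), ], c(fpr = 1, tpr = 1))
  expect_true(all(diff(rc$roc[, "fpr"]) >= 0))
  expect_true(all(diff(rc$roc[, "tpr"]) >= 0))

  expect_equal(rocCurve(c(5, 6, 7), c(0, 0, 1))$auc, 1)
  expect_equal(rocCurve(rep(1, 8), rep(c(0, 1), 4))$auc, 0.5)

  # auc equals the pair-counting probability (brute-force oracle)
  set.seed(54)
  for (rep in 1:20) {
    scores <- round(runif(30), 2)          # ties likely
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(rocCurve(scores, labels)$auc, mean(pairs), tolerance = 1e-12)
  }
  # complement identity for tie-free scores
  scores <- sample(seq(0.01, 0.99, length.out = 20))
  labels <- rep(c(0, 1), 10)
  expect_equal(rocCurve(scores, labels)$auc +
                 rocCurve(-scores, labels)$auc, 1, tolerance = 1e-12)
  expect_error(rocCurve(1:5, rep(1, 5)), "both classes")
})

test_that("subject-grouped folds hold out whole subjects", {
  ft <- syntheticFeatureTable(nSubjects = 3, nTrials = 12, offset = 3,
                              seed = 57)
  fm <- assembleFeatures(ft, "beta", "degree")
  r <- tenFoldCv(fm, "margin", seed = 1, groupBySubject = TRUE)
  expect_length(foldAccuracies(r), 3)
  expect_gt(meanAccuracy(r), 0.5)
  fm1 <- assembleFeatures(ft[ft$subject_id == "S01", ], "beta", "degree")
  expect_error(tenFoldCv(fm1, "margin", groupBySubject = TRUE),
               "at least 2 subjects")
})

test_that("cross-validation is deterministic given the seed", {
  ft <- syntheticFeatureTable(nTrials = 20, offset = 1, seed = 55)
  fm <- assembleFeatures(ft, "beta", "combined")
  for (dec in c("margin", "tree", "recurrent")) {
    r1 <- tenFoldCv(fm, dec, seed = 9)
    r2 <- tenFoldCv(fm, dec, seed = 9)
    expect_identical(foldAccuracies(r1), foldAccuracies(r2))
    expect_identical(aucOf(r1), aucOf(r2))
  }
})

test_that("the decoding suite covers all nine combinations", {
  ft <- syntheticFeatureTable(nTrials = 15, offset = 2, seed = 56)
  res <- runDecodingSuite(ft, band = "beta", seed = 2)
  expect_length(res, 9)
  expect_setequal(names(res),
    as.vector(outer(c("margin", "recurrent", "tree"),
                    c("degree", "modularity", "combined"), paste, sep = ".")))
  for (r in res) {
    expect_length(foldAccuracies(r), 10)
    expect_gte(aucOf(r), 0)
    expect_lte(aucOf(r), 1)
  }
  # a strong planted offset should be decodable by every combination
  expect_true(all(sapply(res, meanAccuracy) > 0.5))
})
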