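test_that("cohort generation is deterministic and structurally correct", {
  cfg <- plantedConfig(seed = 11, nTrials = 5, nSubjects = 2)
  r1 <- generateRecording(cfg, 1)
  r2 <- generateRecording(cfg, 1)
  expect_identical(signalMatrix(r1), signalMatrix(r2))
  expect_identical(eventTimes(r1), eventTimes(r2))

  cohort <- generateCohort(cfg)
  expect_length(cohort, 2)
  expect_false(identical(signalMatrix(cohort[[1]]), signalMatrix(cohort[[2]])))

  # study-scale structure at the analysis rate: 4 subjects x 60 events each
  cfgFull <- cohortConfig(nSubjects = 4, nTrials = 60, fsRaw = 1000,
                          bandCoupling = list(beta = c(0.3, 0.8)),
                          bands = canonicalBands()["beta"], seed = 3)
  cohortFull <- generateCohort(cfgFull)
  expect_length(cohortFull, 4)
  for (rec in cohortFull) {
    expect_length(eventTimes(rec), 60)
    expect_equal(nrow(signalMatrix(rec)), 16)
    # epochs never overlap and always fit inside the recording
    expect_true(all(diff(eventTimes(rec)) >= 2))
    dur <- ncol(signalMatrix(rec)) / samplingRate(rec)
    expect_true(all(eventTimes(rec) >= 1 & eventTimes(rec) <= dur - 1))
  }
  # defaults carry the full study conditions
  dflt <- cohortConfig()
  expect_equal(dflt@nSubjects, 4)
  expect_equal(dflt@nTrials, 60)
  expect_equal(dflt@fsRaw, 30000)
  expect_equal(dflt@bandCoupling$beta, c(0.3, 0.8))

  cfg1 <- cohortConfig(nSubjects = 1, fsRaw = 1000,
                       bandCoupling = list(beta = c(0.3, 0.3)),
                       bands = canonicalBands()["beta"], nTrials = 2)
  expect_length(generateCohort(cfg1), 1)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohortConfig(bandCoupling = list(beta = c(0.3, 1.2)),
                            bands = canonicalBands()["beta"], fsRaw = 1000),
               "bandCoupling\\[beta\\]")
  expect_error(cohortConfig(fsRaw = 100), "fsRaw")
  expect_error(cohortConfig(nChannels = 1), "nChannels")
  expect_error(generateRecording(plantedConfig(1, nTrials = 2), 5),
               "subjectIndex")
})

test_that("coupling gains control inter-channel coherence as planted", {
  mkCoh <- function(gains, seed, lineAmp = 1, noiseSd = 1, nTrials = 6) {
    cfg <- cohortConfig(nSubjects = 1, nTrials = nTrials, fsRaw = 1000,
                        seed = seed, bandCoupling = list(beta = gains),
                        bands = canonicalBands()["beta"],
                        lineAmp = lineAmp, noiseSd = noiseSd)
    rec <- generateRecording(cfg, 1)
    ep <- extractEpochs(rec, signalMatrix(rec), 1000,
                        band = canonicalBands()$beta)
    plan <- planWindows(2000, 256, 128, 1000)
    tens <- coherenceTensor(ep, plan)
    tr <- globalMeanCoherence(tens)
    pre <- mean(tr[windowConditions(plan) == "pre"])
    post <- mean(tr[windowConditions(plan) == "post"])
    c(pre = pre, post = post)
  }
  # zero coupling, no line: coherence sits at the multitaper bias floor
  indep <- mkCoh(c(0, 0), seed = 21, lineAmp = 0)
  expect_lt(max(indep), 0.45)
  # full coupling, no noise: coherence ~ 1 in the driven band
  full <- mkCoh(c(1, 1), seed = 22, noiseSd = 0, nTrials = 3)
  expect_gt(min(full), 0.99)
  # planted increase: post exceeds pre for each of 3 seeds
  for (s in 31:33) {
    cc <- mkCoh(c(0.3, 0.8), seed = s)
    expect_gt(cc["post"], cc["pre"])
  }
})

test_that("post-event coherence is monotone in the post gain", {
  gains <- c(0.3, 0.55, 0.8)
  postMeans <- sapply(gains, function(g) {
    mean(sapply(41:43, function(s) {
      cfg <- cohortConfig(nSubjects = 1, nTrials = 6, fsRaw = 1000, seed = s,
                          bandCoupling = list(beta = c(0.3, g)),
                          bands = canonicalBands()["beta"])
      rec <- generateRecording(cfg, 1)
      ep <- extractEpochs(rec, signalMatrix(rec), 1000,
                          band = canonicalBands()$beta)
      plan <- planWindows(2000, 256, 128, 1000)
      tr <- globalMeanCoherence(coherenceTensor(ep, plan))
      mean(tr[windowConditions(plan) == "post"])
    }))
  })
  expect_true(all(diff(postMeans) > 0))
})

test_that("bands with unchanged gains show no pre/post difference", {
  # delta coupling held at 0.3 while beta is planted; delta coherence must
  # not differ pre vs post beyond sampling noise
  diffs <- sapply(51:58, function(s) {
    cfg <- cohortConfig(nSubjects = 1, nTrials = 8, fsRaw = 1000, seed = s,
                        bandCoupling = list(delta = c(0.3, 0.3),
                                            beta = c(0.3, 0.8)),
                        bands = canonicalBands()[c("delta", "beta")])
    rec <- generateRecording(cfg, 1)
    bands <- bandDecompose(signalMatrix(rec), 1000,
                           canonicalBands()["delta"])
    ep <- extractEpochs(rec, bands$delta, 1000,
                        band = canonicalBands()$delta)
    plan <- planWindows(2000, 256, 128, 1000)
    tr <- globalMeanCoherence(coherenceTensor(ep, plan))
    mean(tr[windowConditions(plan) == "post"]) -
      mean(tr[windowConditions(plan) == "pre"])
  })
  expect_gt(stats::t.test(diffs)$p.value, 0.01)
})

test_that("recording serialization round-trips bit-exactly", {
  cfg <- plantedConfig(seed = 61, nTrials = 3)
  rec <- generateRecording(cfg, 1)
  prefix <- file.path(tempdir(), "roundtrip")
  writeRecording(rec, prefix)
  back <- readRecording(prefix)
  expect_identical(signalMatrix(back), unname(signalMatrix(rec)))
  expect_identical(eventTimes(back), eventTimes(rec))
  expect_identical(samplingRate(back), samplingRate(rec))
  expect_identical(subjectId(back), subjectId(rec))
  unlink(paste0(prefix, c(".bin", ".json")))
})
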