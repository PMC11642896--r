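# Synthetic coupled cardiorespiratory generator.

test_that("deterministic breathing produces exactly rate x minutes cycles", {
  p <- groupPreset("Healthy", hrMean = 80, respRateMean = 15,
                   respRateSd = 0, ieRatio = 1)
  x <- generateRespiration(p, durationS = 300, fs = 250, seed = 1)
  expect_length(x, 75000)
  expect_lt(abs(mean(x)), 1e-10)
  br <- detectBreaths(bandpassResp(x, 250), 250)
  expect_true(abs(nrow(br) - 75) <= 1)
})

test_that("symmetric breaths give inspiration:expiration ratio 1", {
  p <- groupPreset("Healthy", hrMean = 80, respRateMean = 15,
                   respRateSd = 0, ieRatio = 1)
  x <- generateRespiration(p, 300, 250, seed = 2)
  br <- detectBreaths(bandpassResp(x, 250), 250)
  f <- respiratoryFeatures(br)
  expect_equal(unname(f["IERatioMean"]), 1, tolerance = 0.02)
})

test_that("generator rejects invalid durations and rates", {
  p <- defaultPresets()$Healthy
  expect_error(generateRespiration(p, durationS = 100), ">= 300")
  expect_error(generateRespiration(p, 300, 250, subjectRate = 45),
               "\\[3, 40\\]")
  bad <- try(groupPreset("X", hrMean = 80, respRateMean = 50), silent = TRUE)
  expect_s3_class(bad, "try-error")
})

test_that("uncoupled RR sequences are independent of respiration", {
  p <- defaultPresets()$Healthy
  p@couplingStrength <- 0
  rec <- generateRecording(p, seed = 21)
  pre <- preprocessRecording(rec)
  rA <- as.numeric(signal::decimate(scale(pre$resp25)[, 1], 5))
  tA <- as.numeric(signal::decimate(scale(pre$tach25)[, 1], 5))
  n <- min(length(rA), length(tA))
  rA <- rA[seq_len(n)]; tA <- tA[seq_len(n)]
  gc0 <- max(linearGC(rA, tA, 5)$gc, 0)
  # permutation null: circularly shift respiration
  null <- vapply(1:19, function(k) {
    shift <- round(n * k / 20)
    rs <- c(rA[(shift + 1):n], rA[1:shift])
    max(linearGC(rs, tA, 5)$gc, 0)
  }, 0)
  expect_lte(gc0, quantile(null, 0.95) + 0.05)
})

test_that("calibration solves the degenerate coupling cases exactly", {
  p <- defaultPresets()$Healthy
  p@couplingStrength <- 0
  cal0 <- calibratePreset(p, nPilot = 100, seed = 3)
  expect_equal(cal0$g, 0)
  expect_gt(cal0$a, 0)
  p@couplingStrength <- 1
  cal1 <- calibratePreset(p, nPilot = 100, seed = 3)
  expect_equal(cal1$a, 0)
  expect_gt(cal1$g, 0)
})

test_that("pilot calibration reaches the Cardiac RMSSD target within 5%", {
  p <- defaultPresets()$Cardiac
  cal <- calibratePreset(p, nPilot = 100, seed = 4)
  expect_true(cal$converged)
  expect_gte(cal$achievedRMSSD, 52.5)
  expect_lte(cal$achievedRMSSD, 58.1)
  expect_lt(abs(cal$achievedShare - p@couplingStrength), 0.05)
})

test_that("identical seeds reproduce identical recordings", {
  p <- defaultPresets()
  c1 <- generateCohort(p, nPerGroup = c(1, 1, 1), seed = 9, nPilot = 100)
  c2 <- generateCohort(p, nPerGroup = c(1, 1, 1), seed = 9, nPilot = 100)
  for (i in 1:3) {
    expect_identical(resp(c1[[i]]), resp(c2[[i]]))
    expect_identical(rri(c1[[i]]), rri(c2[[i]]))
    expect_identical(demographics(c1[[i]]), demographics(c2[[i]]))
  }
})

test_that("cohort counts, labels and demographic invariants hold", {
  coh <- tinyCohort()
  expect_length(coh, 9L)
  man <- cohortManifest(coh)
  expect_equal(unname(table(man$group)[c("Cardiac", "Healthy", "Sport")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_true(all(abs(man$bmi - man$weight_kg / (man$height_cm / 100)^2)
                  < 1e-6))
  # Sport group has no female subjects (male fraction 44/44)
  expect_true(all(man$sex[man$group == "Sport"] == "M"))
  # demographics inside the printed ranges
  h <- man[man$group == "Healthy", ]
  expect_true(all(h$age >= 7 & h$age <= 15))
  expect_true(all(h$height_cm >= 123 & h$height_cm <= 183))
})

test_that("recordings satisfy the container invariants", {
  rec <- healthyRecording()
  expect_s4_class(rec, "CRRecording")
  expect_gte(length(resp(rec)) / samplingRate(rec), 300)
  expect_true(all(rri(rec) > 0))
  expect_error(crRecording(rnorm(1000), c(800, 810), fs = 250),
               "300 s")
  expect_error(crRecording(rnorm(80000), c(800, -10), fs = 250),
               "positive")
})

test_that("group means recover the preset targets at cohort scale", {
  # scaled-down recovery check (n = 60 per group); the acceptance suite
  # re-runs this at n = 500
  p <- defaultPresets()
  coh <- generateCohort(p[c("Healthy", "Sport")], nPerGroup = c(60, 60),
                        seed = 31, nPilot = 100)
  grp <- vapply(seq_len(length(coh)), function(i) groupLabel(coh[[i]]), "")
  hr <- vapply(seq_len(length(coh)),
               function(i) 60000 / mean(rri(coh[[i]])), 0)
  rm <- vapply(seq_len(length(coh)),
               function(i) sqrt(mean(diff(rri(coh[[i]]))^2)), 0)
  expect_lt(abs(mean(hr[grp == "Healthy"]) / 79.4 - 1), 0.05)
  expect_lt(abs(mean(rm[grp == "Sport"]) / 68.2 - 1), 0.05)
})
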