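# HRV feature battery: time, frequency, nonlinear, symbolic domains.

test_that("time-domain features match hand-computed values", {
  v <- hrvTimeFeatures(c(800, 810, 790, 805))
  expect_equal(unname(v["RMSSD"]), sqrt((10^2 + 20^2 + 15^2) / 3),
               tolerance = 1e-9)
  expect_equal(unname(v["MeanNN"]), 801.25)
  expect_equal(unname(v["pNN5"]), 100)
  expect_equal(unname(v["pNN20"]), 0)
  cst <- hrvTimeFeatures(rep(800, 50))
  expect_equal(unname(cst[c("SDNN", "RMSSD", "pNN50")]), c(0, 0, 0))
})

test_that("in-band tones land their power in the right frequency band", {
  t <- seq(0, 300, by = 0.25)
  hfTone <- list(values = 800 + 20 * sin(2 * pi * 0.25 * t), times = t, fs = 4)
  v <- hrvFrequencyFeatures(hfTone)
  expect_gte(unname(v["HF"] / v["TP"]), 0.95)
  lfTone <- list(values = 800 + 20 * sin(2 * pi * 0.1 * t), times = t, fs = 4)
  v2 <- hrvFrequencyFeatures(lfTone)
  expect_gte(unname(v2["LF"] / v2["TP"]), 0.95)
  expect_equal(unname(v2["LFpeak"]), 0.1, tolerance = 0.02)
})

test_that("normalized LF and HF powers always sum to one", {
  withr::with_seed(5, {
    for (i in 1:5) {
      rriSeq <- 800 + rnorm(500, sd = 40)
      v <- hrvFrequencyFeatures(rriSeq)
      expect_equal(unname(v["LFn"] + v["HFn"]), 1, tolerance = 1e-9)
    }
  })
  expect_true(all(is.na(hrvFrequencyFeatures(800 + rnorm(50, sd = 10)))))
})

test_that("Poincare geometry identities hold", {
  withr::with_seed(6, {
    x <- 800 + cumsum(rnorm(300, sd = 15))
    v <- hrvNonlinearFeatures(x)
    rmssd <- sqrt(mean(diff(x)^2))
    expect_equal(unname(v["SD1"]), sd(diff(x)) / sqrt(2), tolerance = 1e-9)
    expect_equal(unname(v["C1d"] + v["C1a"]), 1, tolerance = 1e-9)
    expect_equal(unname(v["C2d"] + v["C2a"]), 1, tolerance = 1e-9)
    # decomposition identity (uncentered convention)
    expect_equal(unname(v["SD1d"]^2 + v["SD1a"]^2),
                 sum(diff(x)^2) / (2 * (length(x) - 1)), tolerance = 1e-9)
  })
})

test_that("entropies separate periodic from irregular series", {
  per <- rep(c(800, 850), 100)
  vp <- hrvNonlinearFeatures(per)
  expect_lt(unname(vp["SampEn"]), 0.05)
  withr::with_seed(7, {
    irr <- 800 + 50 * runif(200)
    vi <- hrvNonlinearFeatures(irr)
    expect_gt(unname(vi["SampEn"]), 1)
  })
})

test_that("DFA exponent of iid series is near 0.5", {
  withr::with_seed(8, {
    a1 <- vapply(1:30, function(i)
      unname(hrvNonlinearFeatures(800 + 50 * runif(300))["DFAalpha1"]), 0)
    expect_lt(abs(mean(a1) - 0.5), 0.1)
  })
})

test_that("symbolic dynamics classify canonical patterns", {
  cst <- symbolicDynamicsFeatures(rep(800, 50))
  expect_equal(unname(cst["Sym0V"]), 100)
  # monotone runs whose steps exceed the bin width are like-variation words;
  # a triangle wave with 5-beat ramps is 2LV-dominant (turns contribute 2UV)
  tri <- symbolicDynamicsFeatures(600 + 50 * rep(c(0:5, 4:1), 6))
  expect_gt(unname(tri["Sym2LV"]),
            max(tri["Sym0V"], tri["Sym1V"], tri["Sym2UV"]))
  # strict alternation spanning bins is all unlike-variation words
  alt <- symbolicDynamicsFeatures(rep(c(700, 900), 25))
  expect_equal(unname(alt["Sym2UV"]), 100)
  withr::with_seed(9, {
    v <- symbolicDynamicsFeatures(800 + rnorm(300, sd = 30))
    expect_equal(unname(sum(v[c("Sym0V", "Sym1V", "Sym2LV", "Sym2UV")])),
                 100, tolerance = 1e-9)
  })
})

test_that("the cardiac battery emits the full named set on a recording", {
  v <- cardiacFeatures(rri(healthyRecording()))
  m <- featureManifest()
  expect_setequal(names(v), m$name[m$domain == "cardiac"])
  expect_length(v, 102L)
  expect_true(all(is.finite(v)))
  pct <- v[c("pNN50", "Sym0V", "Sym1V", "Sym2LV", "Sym2UV", "PIP")]
  expect_true(all(pct >= 0 & pct <= 100))
  expect_true(all(v[c("VLF", "LF", "HF", "TP")] >= 0))
})

test_that("breath detection counts and amplitudes track the truth", {
  fs <- 250
  t <- seq(0, 300, by = 1 / fs)
  x <- sin(2 * pi * 0.25 * t)            # 15 breaths/min
  br <- detectBreaths(x, fs)
  expect_true(abs(nrow(br) - 75) <= 1)
  f <- respiratoryFeatures(br)
  expect_equal(unname(f["RespRateMean"]), 15, tolerance = 0.1)
  # amplitude modulation tracked within 5%
  env <- 1 + 0.3 * sin(2 * pi * t / 300)
  brm <- detectBreaths(env * x, fs)
  expected <- 1 + 0.3 * sin(2 * pi * brm$peak / 300)
  expect_lt(max(abs(brm$amplitude / 2 / expected - 1)), 0.05)
  # flat signal -> empty table with flag
  flat <- detectBreaths(rep(0, 75000), fs)
  expect_equal(nrow(flat), 0)
  expect_equal(attr(flat, "flag"), "no_breaths")
})

test_that("relative tidal volume is median-indexed", {
  pre <- healthyPre()
  br <- detectBreaths(pre$respFiltered, 250)
  relTV <- br$amplitude / median(br$amplitude)
  expect_equal(median(relTV), 1)
  f <- respiratoryFeatures(br)
  m <- featureManifest()
  expect_setequal(names(f), m$name[m$domain == "respiratory"])
  expect_true(all(is.finite(f)))
  expect_true(is.na(respiratoryFeatures(br[1, , drop = FALSE])["RespRateMean"]))
})
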