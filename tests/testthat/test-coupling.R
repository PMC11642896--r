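# Causal/information coupling features.

# independent brute-force linear GC: explicit normal equations, no shared
# code with linearGC
bruteGC <- function(source, target, p) {
  n <- length(target)
  y <- target[(p + 1):n]
  XR <- matrix(1, length(y), 1)
  XF <- matrix(1, length(y), 1)
  for (k in 1:p) {
    XR <- cbind(XR, target[(p + 1 - k):(n - k)])
    XF <- cbind(XF, target[(p + 1 - k):(n - k)])
  }
  for (k in 1:p) XF <- cbind(XF, source[(p + 1 - k):(n - k)])
  bR <- solve(t(XR) %*% XR, t(XR) %*% y)
  bF <- solve(t(XF) %*% XF, t(XF) %*% y)
  s2R <- sum((y - XR %*% bR)^2) / (length(y) - ncol(XR))
  s2F <- sum((y - XF %*% bF)^2) / (length(y) - ncol(XF))
  log(s2R / s2F)
}

test_that("linear GC equals the normal-equations oracle", {
  withr::with_seed(13, {
    for (i in 1:20) {
      p <- sample(1:3, 1)
      x <- as.numeric(arima.sim(list(ar = 0.5), 500))
      y <- as.numeric(stats::filter(0.4 * c(0, head(x, -1)) + rnorm(500),
                                    0.3, method = "recursive"))
      expect_equal(linearGC(x, y, p)$gc, bruteGC(x, y, p),
                   tolerance = 1e-8)
    }
  })
})

test_that("linear GC recovers the analytic one-way coupling value", {
  # y_t = 0.9 x_{t-1} + e, e ~ N(0, 0.1^2), x white N(0,1):
  # restricted residual var = 0.81 + 0.01 = 0.82, full = 0.01
  withr::with_seed(14, {
    gcs <- replicate(5, {
      x <- rnorm(5000)
      y <- 0.9 * c(0, head(x, -1)) + rnorm(5000, sd = 0.1)
      c(fwd = linearGC(x, y, 1)$gc, rev = linearGC(y, x, 1)$gc)
    })
    expect_equal(mean(gcs["fwd", ]), log(82), tolerance = 0.15 / log(82))
    expect_lte(mean(gcs["rev", ]), 0.01)
  })
})

test_that("GC handles degenerate input and respects nesting", {
  g <- linearGC(rnorm(500), rep(5, 500), 3)
  expect_true(g$masked)
  withr::with_seed(15, {
    for (i in 1:10) {
      n <- 300; p <- 2
      g <- linearGC(rnorm(n), rnorm(n), p)
      # the full model nests the restricted one: RSS can only shrink
      nn <- n - p
      rssR <- g$residVarRestricted * (nn - (p + 1))
      rssF <- g$residVarFull * (nn - (2 * p + 1))
      expect_lte(rssF, rssR * (1 + 1e-10))
      # the df-normalized log-ratio may dip slightly below zero on
      # independent data; it must stay within the finite-sample band
      expect_gte(g$gc, -2 * (2 * p + 1) / nn)
    }
  })
})

test_that("order selection finds the true lag structure", {
  withr::with_seed(16, {
    hits <- vapply(1:20, function(i) {
      x <- rnorm(1200)
      y <- numeric(1200)
      for (t in 3:1200) y[t] <- 0.4 * y[t - 1] + 0.8 * x[t - 2] +
        rnorm(1, sd = 0.3)
      selectOrder(x, y, 6) == 2
    }, TRUE)
    expect_gte(mean(hits), 0.9)
    expect_equal(selectOrder(rnorm(500), rnorm(500), 1), 1)
    wn <- vapply(1:10, function(i)
      selectOrder(rnorm(800), rnorm(800), 6), 0L)
    expect_gte(mean(wn == 1), 0.8)      # BIC favors the smallest model
  })
})

test_that("GC ratio distinguishes symmetric from one-way coupling", {
  withr::with_seed(17, {
    # symmetric mutual coupling
    n <- 3000; x <- numeric(n); y <- numeric(n)
    for (t in 2:n) {
      x[t] <- 0.3 * x[t - 1] + 0.5 * y[t - 1] + rnorm(1)
      y[t] <- 0.3 * y[t - 1] + 0.5 * x[t - 1] + rnorm(1)
    }
    r <- gcRatio(x, y, 2)
    expect_gt(r$ratio, 0.5); expect_lt(r$ratio, 2)
    # one-way coupling
    x1 <- rnorm(n)
    y1 <- 0.9 * c(0, head(x1, -1)) + rnorm(n, sd = 0.3)
    r1 <- gcRatio(x1, y1, 2)
    expect_gt(r1$ratio, 10)
    # exactly zero denominator -> masked
    r0 <- gcRatio(rnorm(500), rep(3, 500), 2)
    expect_true(r0$masked)
  })
})

test_that("kernel GC detects nonlinear coupling the linear GC misses", {
  withr::with_seed(18, {
    x <- rnorm(2000)
    yq <- c(0, head(x, -1))^2 + rnorm(2000, sd = 0.3)
    kq <- kernelGC(x, yq, 1)
    lq <- max(linearGC(x, yq, 1)$gc, 0)
    expect_gt(kq, lq)
    # independent pair stays near zero
    expect_lte(kernelGC(rnorm(2000), rnorm(2000), 1), 0.02)
  })
})

test_that("wide-kernel GC approaches linear GC on linear data", {
  withr::with_seed(19, {
    x <- rnorm(3000)
    y <- 0.8 * c(0, head(x, -1)) + 0.3 * rnorm(3000)
    lin <- linearGC(x, y, 1)$gc
    wide <- kernelGC(x, y, 1, kernelWidth = 20, lambda = 1e-7)
    expect_lt(abs(wide - lin) / lin, 0.2)
  })
  expect_error(kernelGC(rnorm(100), rnorm(100), 1, kernelWidth = -1),
               "positive")
})

test_that("lsNGC F-statistic separates coupled from independent pairs", {
  withr::with_seed(20, {
    nulls <- vapply(1:20, function(i)
      lsngc(rnorm(1500), rnorm(1500), 8, 2, seed = i)$fStatistic, 0)
    crit <- qf(0.95, 8, 1500 - 2 - 8 - 1)
    expect_gte(mean(nulls < crit), 0.9)
    hits <- vapply(1:10, function(i) {
      x <- rnorm(1500)
      y <- sin(2 * c(0, head(x, -1))) + rnorm(1500, sd = 0.2)
      lsngc(x, y, 8, 2, seed = i)$fStatistic >
        qf(0.99, 8, 1500 - 2 - 8 - 1)
    }, TRUE)
    expect_gte(mean(hits), 0.9)
    # a single center gives a constant (row-normalized) activation
    x <- rnorm(1500)
    y <- 0.8 * c(0, head(x, -1)) + rnorm(1500, sd = 0.3)
    expect_lt(lsngc(x, y, 1, 2, seed = 1)$fStatistic, 1e-6)
  })
})

test_that("ML GC is near zero for independent pairs and tracks linear truth", {
  withr::with_seed(21, {
    vals <- vapply(1:10, function(i)
      mlGC(rnorm(1200), rnorm(1200), "mlp", 2, seed = i, maxit = 80), 0)
    expect_lte(abs(mean(vals)), 0.05)
    x <- rnorm(2000)
    y <- 0.9 * c(0, head(x, -1)) + rnorm(2000, sd = 0.3)
    lin <- linearGC(x, y, 1)$gc
    mlp <- mlGC(x, y, "mlp", 1, seed = 1)
    expect_lt(abs(mlp - lin) / lin, 0.3)
    expect_identical(mlGC(x, y, "mlp", 1, seed = 7),
                     mlGC(x, y, "mlp", 1, seed = 7))
  })
})

test_that("transfer entropy matches the 1-bit closed form and orderings", {
  withr::with_seed(22, {
    x <- sample(c(-1, 1), 5000, replace = TRUE)
    y <- c(0, head(x, -1))                 # y_{t+1} = x_t exactly
    expect_equal(transferEntropy(x, y, lag = 1, nBins = 4), 1,
                 tolerance = 0.05)
    a <- sample(c(-1, 1), 5000, replace = TRUE)
    b <- sample(c(-1, 1), 5000, replace = TRUE)
    expect_lte(transferEntropy(a, b, lag = 1), 0.02)
    # ordering: true source beats an independent one, across seeds
    for (i in 1:5) {
      z <- rnorm(3000)
      w <- c(0, head(z, -1)) + rnorm(3000, sd = 0.5)
      expect_gte(transferEntropy(z, w, 1, seed = i),
                 transferEntropy(rnorm(3000), w, 1, seed = i))
    }
  })
})

test_that("maximal lagged correlation finds the exact delay and sign", {
  fs <- 20   # 0.5 s is an integer number of samples at 20 Hz
  withr::with_seed(23, {
    x <- as.numeric(stats::filter(rnorm(7500), rep(1 / 10, 10), sides = 1))
    x[is.na(x)] <- 0
    k <- round(0.5 * fs)
    y <- c(rep(0, k), head(x, -k))         # y trails x by 0.5 s
    r <- maxLaggedCorrelation(x, y, fs, 1)
    expect_equal(r$lagAtMax, 0.5)
    expect_gt(r$rMax, 0.99)
    rn <- maxLaggedCorrelation(rnorm(7500), rnorm(7500), fs, 1)
    expect_lte(abs(rn$rMax), 0.08)
    ra <- maxLaggedCorrelation(x, -x, fs, 1)
    expect_equal(ra$lagAtMax, 0)
    expect_lt(ra$rMax, -0.99)              # signed convention
    expect_true(maxLaggedCorrelation(rep(1, 100), rnorm(100), fs)$masked)
  })
})

test_that("the assembled coupling vector is complete and reproducible", {
  pre <- healthyPre()
  ctl <- couplingControl(seed = 3)
  v1 <- assembleCouplingFeatures(pre, ctl)
  v2 <- assembleCouplingFeatures(pre, ctl)
  m <- featureManifest()
  expect_length(v1, 32L)
  expect_setequal(names(v1), m$name[m$domain == "causal_information"])
  expect_identical(as.numeric(v1), as.numeric(v2))
  # non-negativity of clipped causality values
  gcNames <- grep("^(GC|KGC|LsNGC|MLGC|TE)", names(v1), value = TRUE)
  gcNames <- setdiff(gcNames, c("GCRatio", "KGCRatio"))
  expect_true(all(v1[gcNames] >= 0, na.rm = TRUE))
})

test_that("direction specificity: beat-domain GC favors the true direction", {
  p <- defaultPresets()$Healthy   # one-way Resp->RR coupling, share 0.5
  hits <- vapply(1:20, function(s) {
    rec <- generateRecording(p, seed = 400 + s)
    rriSeq <- rri(rec)
    rf <- bandpassResp(resp(rec), 250)
    bt <- cumsum(rriSeq) / 1000
    idx <- pmin(pmax(round(bt * 250) + 1, 1), length(rf))
    rb <- as.numeric(scale(rf[idx])); rrn <- as.numeric(scale(rriSeq))
    linearGC(rb, rrn, 2)$gc > linearGC(rrn, rb, 2)$gc
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
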