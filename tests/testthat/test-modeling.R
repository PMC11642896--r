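# Dataset assembly, SMOTE, metrics, cross-validation, statistical tests.

test_that("dataset specs select the documented column counts", {
  se <- tinySE()
  expect_equal(ncol(assembleDataset(se, datasetSpec("D3"))$X), 157L)
  expect_equal(ncol(assembleDataset(se, datasetSpec("D4"))$X), 152L)
  expect_equal(ncol(assembleDataset(se, datasetSpec("D1"))$X), 107L)
  expect_equal(ncol(assembleDataset(se, datasetSpec("D2"))$X), 125L)
  m <- featureManifest()
  sub <- head(m$name, 35)
  expect_equal(ncol(assembleDataset(se, datasetSpec("D5", sub))$X), 35L)
  expect_error(datasetSpec("D5"), "featureSubset")
  expect_error(assembleDataset(se, datasetSpec("D6", c(sub[-1], "NotAFeature"))),
               "unknown feature")
})

test_that("SMOTE hits the strategy counts with convex synthetic points", {
  withr::with_seed(30, {
    n <- c(Cardiac = 26, Healthy = 56, Sport = 40)
    y <- factor(rep(names(n), n))
    X <- matrix(rnorm(sum(n) * 8), ncol = 8)
    X <- X + as.integer(y)              # group shift
    out <- smoteResample(X, y, c(Cardiac = 200, Healthy = 200, Sport = 200),
                         seed = 1)
    expect_equal(nrow(out$X), 600L)
    expect_equal(unname(table(out$y)), rep(200L, 3), ignore_attr = TRUE)
    expect_identical(out$X[seq_len(sum(n)), ], X)   # originals preserved
    # every synthetic point lies on a segment between two same-class parents
    for (i in sample(which(out$synthetic), 25)) {
      cl <- out$y[i]
      P <- X[y == cl, , drop = FALSE]
      s <- out$X[i, ]
      resid <- min(apply(P, 1, function(a) min(apply(P, 1, function(b) {
        d <- b - a
        if (sum(d^2) < 1e-12) return(sum((s - a)^2))
        u <- sum((s - a) * d) / sum(d^2)
        if (u < -1e-9 || u > 1 + 1e-9) return(Inf)
        sum((s - a - u * d)^2)
      }))))
      expect_lt(resid, 1e-9)
    }
  })
})

test_that("SMOTE with strategy equal to current counts is a no-op", {
  y <- factor(rep(c("A", "B"), c(10, 12)))
  X <- matrix(rnorm(44), ncol = 2)
  out <- smoteResample(X, y, c(A = 10, B = 12), seed = 1)
  expect_identical(out$X, X)
  expect_error(smoteResample(X, y, c(A = 5, B = 12)), "below")
  expect_error(smoteResample(X, y, c(C = 10)), "absent")
})

# independent confusion-table oracle for the metric equations
bruteMetrics <- function(yt, yp, prob = NULL) {
  lev <- levels(yt)
  K <- length(lev); n <- length(yt)
  acc <- mean(yt == yp)
  pr <- re <- f1 <- numeric(K)
  for (k in seq_len(K)) {
    tp <- sum(yt == lev[k] & yp == lev[k])
    fp <- sum(yt != lev[k] & yp == lev[k])
    fn <- sum(yt == lev[k] & yp != lev[k])
    pr[k] <- if (tp + fp) tp / (tp + fp) else 0
    re[k] <- if (tp + fn) tp / (tp + fn) else 0
    f1[k] <- if (2 * tp + fn + fp) 2 * tp / (2 * tp + fn + fp) else 0
  }
  pk <- vapply(lev, function(l) sum(yp == l), 0)
  tk <- vapply(lev, function(l) sum(yt == l), 0)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  mcc <- if (den == 0) 0 else (n * sum(yt == yp) - sum(pk * tk)) / den
  auc <- NA_real_
  if (!is.null(prob)) {
    aucs <- vapply(lev, function(l) {
      pos <- yt == l
      if (!any(pos) || all(pos)) return(NA_real_)
      # brute-force pairwise comparison
      s <- prob[, l]
      cmp <- outer(s[pos], s[!pos], function(a, b)
        (a > b) + 0.5 * (a == b))
      mean(cmp)
    }, 0)
    auc <- mean(aucs, na.rm = TRUE)
  }
  list(accuracy = acc, precision = mean(pr), recall = mean(re),
       f1 = mean(f1), mcc = mcc, auc = auc)
}

test_that("metrics match a brute-force oracle on random multiclass labels", {
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(12:40, 1)
      lev <- c("Cardiac", "Healthy", "Sport")
      yt <- factor(sample(lev, n, replace = TRUE), levels = lev)
      yp <- factor(sample(lev, n, replace = TRUE), levels = lev)
      prob <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, lev))
      prob <- prob / rowSums(prob)
      got <- computeMetrics(yt, yp, prob)
      want <- bruteMetrics(yt, yp, prob)
      for (m in c("accuracy", "precision", "recall", "f1", "mcc", "auc"))
        expect_equal(got[[m]], want[[m]], tolerance = 1e-12, label = m)
    }
  })
})

test_that("one-vs-rest AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(32, {
    y <- factor(sample(c("A", "B", "C"), 60, replace = TRUE))
    prob <- matrix(runif(180), 60, 3, dimnames = list(NULL, c("A", "B", "C")))
    prob <- prob / rowSums(prob)
    got <- computeMetrics(y, y, prob)$auc
    ref <- mean(vapply(c("A", "B", "C"), function(cl)
      as.numeric(pROC::auc(pROC::roc(as.integer(y == cl), prob[, cl],
                                     quiet = TRUE, direction = "<"))), 0))
    expect_equal(got, ref, tolerance = 1e-12)
  })
})

test_that("metric edge cases behave per definition", {
  lev <- c("A", "B", "C")
  yt <- factor(rep(lev, 4), levels = lev)
  perfect <- computeMetrics(yt, yt)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  # constant prediction on balanced truth: zero numerator, guarded denominator
  allA <- factor(rep("A", 12), levels = lev)
  expect_equal(computeMetrics(yt, allA)$mcc, 0)
  # hand-worked example
  got <- computeMetrics(factor(c(0, 0, 1, 1, 2, 2)),
                        factor(c(0, 0, 1, 2, 2, 2), levels = c(0, 1, 2)))
  expect_equal(got$accuracy, 5 / 6)
  expect_error(computeMetrics(yt, yt, matrix(1, 12, 3,
                                             dimnames = list(NULL, lev))),
               "sum to 1")
  expect_error(computeMetrics(yt, yt[1:3]), "mismatch")
})

test_that("cross-validation partitions subjects and never leaks SMOTE rows", {
  d <- separableData(n = 60, seed = 2)
  se <- seFromMatrix(d$X, d$y)
  rep <- runCV(se, list(datasetSpec("D1")), models = "logistic", k = 10,
               seed = 3, smoteStrategy = c(Cardiac = 30, Healthy = 30,
                                           Sport = 30))
  pd <- oofPredictions(rep)
  expect_setequal(pd$subject, rownames(d$X))       # every subject tested once
  expect_equal(nrow(pd), 60L)
  expect_true(all(pd$subject %in% rownames(d$X)))  # no synthetic row escapes
  fm <- foldMetrics(rep)
  expect_equal(sort(unique(fm$fold)), 1:10)
  # a 10-sigma-separated problem is essentially solved
  expect_gte(mean(fm$accuracy), 0.98)
})

test_that("dataset comparison reproduces exact signed-rank p-values", {
  d <- separableData(n = 60, seed = 4)
  se <- seFromMatrix(d$X, d$y)
  rep <- runCV(se, list(datasetSpec("D1"), datasetSpec("D2")),
               models = "tree", k = 10, seed = 5, smoteStrategy = NULL)
  P <- compareDatasets(rep)
  expect_equal(dim(P), c(2L, 2L))
  expect_equal(diag(P), c(D1 = 1, D2 = 1))
  expect_equal(P, t(P))                     # symmetric
  # D1 and D2 only differ by respiratory columns (all NA -> imputed
  # constants), so the tree metrics tie fold by fold
  expect_true(attr(P, "ties")["D1", "D2"])
  # exact null: one-signed differences across 10 folds give p = 2/2^10
  a <- seq(0.5, 0.95, length.out = 10)
  b <- a - seq(0.05, 0.15, length.out = 10)
  expect_equal(wilcox.test(a, b, paired = TRUE)$p.value, 2 / 1024,
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis demographic screen calibrates and detects", {
  withr::with_seed(33, {
    mkcoh <- function(shift) data.frame(
      group = rep(c("Cardiac", "Healthy", "Sport"), each = 30),
      age = rnorm(90) + rep(c(0, 0, shift), each = 30),
      weight_kg = rnorm(90, 50, 10), height_cm = rnorm(90, 160, 10),
      bmi = rnorm(90, 19, 2))
    nullP <- vapply(1:200, function(i)
      demographicTests(mkcoh(0))$p[1], 0)
    expect_gt(mean(nullP < 0.05), 0.01)
    expect_lt(mean(nullP < 0.05), 0.12)     # ~5% rejections under the null
    expect_lt(demographicTests(mkcoh(5))$p[1], 1e-6)
    two <- data.frame(group = rep(c("A", "B"), 10), age = rnorm(20),
                      weight_kg = rnorm(20), height_cm = rnorm(20),
                      bmi = rnorm(20))
    expect_error(demographicTests(two), "3 groups")
  })
})

test_that("the full model zoo runs on a small separable problem", {
  d <- separableData(n = 45, seed = 6)
  se <- seFromMatrix(d$X, d$y)
  rep <- runCV(se, list(datasetSpec("D1")),
               models = c("logistic", "ridge", "lasso", "tree", "svm",
                          "randomForest", "gradientBoosting", "naiveBayes",
                          "knn", "adaBoost", "xgboost", "mlp"),
               k = 5, seed = 7,
               smoteStrategy = c(Cardiac = 20, Healthy = 20, Sport = 20))
  fm <- foldMetrics(rep)
  expect_false(any(fm$failed))
  acc <- tapply(fm$accuracy, fm$model, mean)
  expect_true(all(acc > 0.8))
  expect_true(bestModel(rep)[["D1"]] %in% names(acc))
  expect_true(all(fm$auc >= 0 & fm$auc <= 1))
  expect_true(all(fm$mcc >= -1 & fm$mcc <= 1))
})
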