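# Shapley attributions, permutation importance, feature selection.

test_that("Shapley values of a linear model match the closed form", {
  withr::with_seed(40, {
    w <- c(2, -1, 0.5, 0)
    bg <- matrix(rnorm(400), 100, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
    X <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
    f <- function(M) {
      s <- as.matrix(M) %*% w
      cbind(pos = as.numeric(s), neg = -as.numeric(s))
    }
    sh <- shapleyAttributions(f, X, bg, nSamples = 10, seed = 1)
    # the full-background walk is exact for additive models
    want <- sweep(X, 2, colMeans(bg)) * rep(w, each = nrow(X))
    expect_lt(max(abs(sh$phi[, , "pos"] - want)), 1e-8)
    # zero-weight feature gets zero attribution
    expect_lt(max(abs(sh$phi[, 4, "pos"])), 1e-10)
    # local additivity: sum_j phi_j + baseline = f(x)
    add <- rowSums(sh$phi[, , "pos"]) + sh$baseline[, 1]
    expect_lt(max(abs(add - sh$fx[, "pos"])), 1e-9)
    # determinism
    sh2 <- shapleyAttributions(f, X, bg, nSamples = 10, seed = 1)
    expect_identical(sh$phi, sh2$phi)
  })
})

test_that("additivity holds for a nonlinear model on many samples", {
  withr::with_seed(41, {
    bg <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
    X <- matrix(rnorm(300), 50, 6, dimnames = list(NULL, paste0("f", 1:6)))
    f <- function(M) {
      M <- as.matrix(M)
      s <- tanh(M[, 1] * M[, 2]) + M[, 3]^2
      p <- 1 / (1 + exp(-s))
      cbind(a = p, b = 1 - p)
    }
    sh <- shapleyAttributions(f, X, bg, nSamples = 40, seed = 2)
    add <- rowSums(sh$phi[, , "a"]) + sh$baseline[, 1]
    expect_lt(max(abs(add - sh$fx[, "a"])), 1e-9)
  })
})

test_that("permutation importance isolates the informative feature", {
  withr::with_seed(42, {
    n <- 150
    y <- factor(rep(c("A", "B"), length.out = n))
    X <- cbind(sig = ifelse(y == "A", -2, 2) + rnorm(n),
               junk1 = rnorm(n), junk2 = rnorm(n))
    fit <- rpart::rpart(y ~ sig, data.frame(X, y = y), method = "class")
    f <- function(M) predict(fit, data.frame(as.matrix(M)), type = "prob")
    imp <- permutationImportance(f, X, y, rounds = 30, seed = 1)
    expect_equal(dim(imp$mean), c(3L, 2L))
    # features the stump never uses have ~zero importance
    expect_lt(max(abs(imp$mean[c("junk1", "junk2"), ])), 0.01)
    expect_gt(min(imp$mean["sig", ]), 0.2)
    expect_true(all(imp$sd >= 0))
    imp2 <- permutationImportance(f, X, y, rounds = 30, seed = 1)
    expect_identical(imp$mean, imp2$mean)
  })
})

test_that("the sole informative feature ranks first across seeds", {
  withr::with_seed(43, {
    hits <- vapply(1:10, function(s) {
      n <- 120
      y <- factor(rep(c("A", "B"), length.out = n))
      X <- cbind(sig = ifelse(y == "A", -2, 2) + rnorm(n),
                 matrix(rnorm(n * 5), n,
                        dimnames = list(NULL, paste0("j", 1:5))))
      fit <- suppressWarnings(
        nnet::multinom(y ~ ., data.frame(X, y = y), trace = FALSE))
      f <- function(M) {
        p <- predict(fit, data.frame(as.matrix(M)), type = "probs")
        cbind(A = 1 - p, B = p)
      }
      imp <- permutationImportance(f, X, y, rounds = 10, seed = s)
      all(rowMeans(imp$mean)["sig"] >= max(rowMeans(imp$mean)))
    }, TRUE)
    expect_gte(mean(hits), 0.95)
  })
})

test_that("top-k selection ranks planted signals and is deterministic", {
  withr::with_seed(44, {
    n <- 200; pInf <- 5; pAll <- 20
    nm <- c(paste0("inf", 1:pInf), paste0("noise", 1:(pAll - pInf)))
    X <- matrix(rnorm(n * pAll), n, pAll, dimnames = list(NULL, nm))
    w <- c(runif(pInf, 1, 2), rep(0, pAll - pInf))
    f <- function(M) {
      s <- as.matrix(M) %*% w
      cbind(a = as.numeric(s), b = -as.numeric(s))
    }
    sh <- shapleyAttributions(f, X[1:40, ], X, nSamples = 25, seed = 1)
    top10 <- selectTopFeatures(sh, k = 10)
    expect_true(all(paste0("inf", 1:pInf) %in% top10))
    # identity selection at k = feature count
    expect_setequal(selectTopFeatures(sh, k = pAll), nm)
    expect_error(selectTopFeatures(sh, k = 50), "exceeds")
    # stability across estimator seeds: Jaccard of top-10 sets
    sh2 <- shapleyAttributions(f, X[1:40, ], X, nSamples = 25, seed = 99)
    t1 <- selectTopFeatures(sh, 10); t2 <- selectTopFeatures(sh2, 10)
    jac <- length(intersect(t1, t2)) / length(union(t1, t2))
    expect_gte(jac, 0.6)
  })
})

test_that("cross-validated Shapley pools folds and selects 35 names", {
  d <- separableData(n = 50, seed = 8)
  se <- seFromMatrix(d$X, d$y)
  sh <- cvShapley(se, datasetSpec("D1"), "randomForest", k = 5, seed = 3,
                  nSamples = 8, smoteStrategy = NULL)
  expect_length(sh, 5L)
  top <- selectTopFeatures(sh, k = 35)
  expect_length(top, 35L)
  # separableData's two informative columns land in the first two manifest
  # slots (MeanNN, SDNN) inside the test container
  expect_true(all(c("MeanNN", "SDNN") %in% top[1:5]))
})
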