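## Dataset assembly (D1-D6), SMOTE, stratified 10-fold cross-validated
## model comparison, classification metrics, and statistical comparisons.

#' Dataset specification (D1-D6)
#'
#' D1 = demographic + cardiac features; D2 = D1 + respiratory; D3 = D2 +
#' causal/information; D4 = D3 minus demographic; D5/D6 = explicit 35-name
#' subsets of the D3/D4 feature spaces selected by Shapley attribution.
#'
#' @param id one of "D1".."D6".
#' @param featureSubset explicit feature-name vector (required for D5/D6).
#' @return list(id, domains, featureSubset).
#' @export
datasetSpec <- function(id, featureSubset = NULL) {
  domains <- switch(id,
    D1 = c("demographic", "cardiac"),
    D2 = c("demographic", "cardiac", "respiratory"),
    D3 = c("demographic", "cardiac", "respiratory", "causal_information"),
    D4 = c("cardiac", "respiratory", "causal_information"),
    D5 = c("demographic", "cardiac", "respiratory", "causal_information"),
    D6 = c("cardiac", "respiratory", "causal_information"),
    stop("unknown dataset id: ", id))
  if (id %in% c("D5", "D6") && is.null(featureSubset))
    stop(id, " requires an explicit featureSubset (the selected top features)")
  list(id = id, domains = domains, featureSubset = featureSubset)
}

#' Assemble a dataset matrix from the feature table
#'
#' Selects the manifest columns belonging to the spec's domains (or the
#' explicit subset for D5/D6). No imputation happens here: missing values
#' are imputed within training folds only, inside [runCV()].
#'
#' @param se feature SummarizedExperiment from [extractFeatures()].
#' @param spec a [datasetSpec()].
#' @return list(X = subjects x features matrix, y = factor labels).
#' @export
assembleDataset <- function(se, spec) {
  dom <- rowData(se)$domain
  keep <- dom %in% spec$domains
  X <- t(assay(se, "features")[keep, , drop = FALSE])
  if (!is.null(spec$featureSubset)) {
    missing <- setdiff(spec$featureSubset, colnames(X))
    if (length(missing))
      stop("unknown feature name(s) in subset: ",
           paste(missing, collapse = ", "))
    X <- X[, spec$featureSubset, drop = FALSE]
  }
  y <- factor(colData(se)$group)
  list(X = X, y = y)
}

#' SMOTE oversampling
#'
#' Synthetic minority oversampling: each synthetic point is a convex
#' combination (uniform coefficient) of a class member and one of its k
#' nearest same-class neighbors. Original rows are preserved; class counts
#' afterwards equal the strategy exactly.
#'
#' @param X numeric matrix (rows = samples).
#' @param y factor labels.
#' @param strategy named integer vector of target per-class counts (each >=
#'   the existing count); classes absent from \code{strategy} are left
#'   unchanged.
#' @param kNeighbors neighbors considered (default 5; reduced with a
#'   warning when a class is too small).
#' @param seed integer seed.
#' @return list(X, y, synthetic = logical marker of generated rows).
#' @export
smoteResample <- function(X, y, strategy, kNeighbors = 5, seed = 1) {
  y <- factor(y)
  stopifnot(!is.null(names(strategy)))
  counts <- table(y)
  for (cl in names(strategy)) {
    if (!cl %in% names(counts) || counts[[cl]] == 0)
      stop("class absent from training data: ", cl)
    if (strategy[[cl]] < counts[[cl]])
      stop("strategy for ", cl, " below the existing count")
  }
  withSeed(seed, {
    newX <- list(); newY <- character()
    for (cl in names(strategy)) {
      nNeed <- strategy[[cl]] - counts[[cl]]
      if (nNeed == 0) next
      Xc <- X[y == cl, , drop = FALSE]
      k <- min(kNeighbors, nrow(Xc) - 1)
      if (k < 1) stop("class ", cl, " has a single member; cannot SMOTE")
      if (k < kNeighbors)
        message("smote: class ", cl, ": kNeighbors reduced to ", k)
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      nb <- apply(D, 1, function(d) order(d)[seq_len(k)])
      if (is.null(dim(nb))) nb <- matrix(nb, nrow = k)
      base <- sample(nrow(Xc), nNeed, replace = TRUE)
      pick <- vapply(base, function(b)
        nb[sample.int(k, 1), b], 0)
      u <- runif(nNeed)
      S <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      newX[[cl]] <- S
      newY <- c(newY, rep(cl, nNeed))
    }
    if (length(newX)) {
      Xout <- rbind(X, do.call(rbind, newX))
      yout <- factor(c(as.character(y), newY), levels = levels(y))
      syn <- c(rep(FALSE, nrow(X)), rep(TRUE, length(newY)))
    } else {
      Xout <- X; yout <- y; syn <- rep(FALSE, nrow(X))
    }
    list(X = Xout, y = yout, synthetic = syn)
  })
}

#' Classification metrics
#'
#' Accuracy = fraction of agreeing labels; precision, recall and F1
#' (2TP/(2TP+FN+FP)) computed per class from the confusion table and
#' macro-averaged; multiclass Matthews correlation coefficient
#' \deqn{MCC = \frac{n c - \sum_k p_k t_k}{\sqrt{(n^2-\sum_k p_k^2)(n^2-\sum_k t_k^2)}}}
#' (0 when a denominator factor vanishes); AUC is the one-vs-rest macro
#' average (rank-based, ties at 1/2).
#'
#' @param yTrue,yPred factors with identical level sets.
#' @param yProb matrix of class probabilities (columns named by level;
#'   rows sum to 1 within 1e-6). NULL skips AUC.
#' @return list(accuracy, precision, recall, f1, mcc, auc, confusion).
#' @export
computeMetrics <- function(yTrue, yPred, yProb = NULL) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  lev <- levels(factor(yTrue))
  yTrue <- factor(yTrue, levels = lev); yPred <- factor(yPred, levels = lev)
  n <- length(yTrue)
  conf <- table(truth = yTrue, pred = yPred)
  acc <- sum(diag(conf)) / n
  prec <- rec <- f1 <- numeric(length(lev))
  for (i in seq_along(lev)) {
    tp <- conf[i, i]; fp <- sum(conf[-i, i]); fn <- sum(conf[i, -i])
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (2 * tp + fn + fp > 0) 2 * tp / (2 * tp + fn + fp) else 0
  }
  pk <- colSums(conf); tk <- rowSums(conf)
  num <- n * sum(diag(conf)) - sum(pk * tk)
  den <- sqrt(n^2 - sum(pk^2)) * sqrt(n^2 - sum(tk^2))
  mcc <- if (den == 0) 0 else num / den
  auc <- NA_real_
  if (!is.null(yProb)) {
    if (any(abs(rowSums(yProb) - 1) > 1e-6))
      stop("probability rows must sum to 1")
    auc <- mean(vapply(lev, function(cl) {
      pos <- yTrue == cl
      if (!any(pos) || all(pos)) return(NA_real_)
      ovrAUC(yProb[, cl], pos)
    }, 0), na.rm = TRUE)
  }
  list(accuracy = acc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), mcc = mcc, auc = auc, confusion = conf)
}

## rank-based AUC (equivalent to the Mann-Whitney statistic)
ovrAUC <- function(score, positive) {
  r <- rank(score)
  nPos <- sum(positive); nNeg <- sum(!positive)
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## ---- model zoo -----------------------------------------------------------

## Each entry: fit(X, y) -> model; prob(model, X) -> matrix with one column
## per class level.
modelZoo <- function(hidden = 16) {
  probOf <- function(p, lev) {
    p <- as.matrix(p)
    if (ncol(p) == 1) { # binary degenerate guard
      p <- cbind(1 - p, p)
    }
    p[, lev, drop = FALSE]
  }
  list(
    logistic = list(
      fit = function(X, y) nnet::multinom(y ~ ., data = data.frame(X, y = y),
                                          trace = FALSE, MaxNWts = 5000),
      prob = function(m, X) {
        p <- predict(m, data.frame(X), type = "probs")
        if (is.null(dim(p))) p <- rbind(p)
        p
      }),
    ridge = glmnetEntry(alpha = 0),
    lasso = glmnetEntry(alpha = 1),
    tree = list(
      fit = function(X, y) rpart::rpart(y ~ ., data.frame(X, y = y),
                                        method = "class"),
      prob = function(m, X) predict(m, data.frame(X), type = "prob")),
    svm = list(
      fit = function(X, y) e1071::svm(X, y, probability = TRUE, kernel = "radial"),
      prob = function(m, X)
        attr(predict(m, X, probability = TRUE), "probabilities")),
    randomForest = list(
      fit = function(X, y) randomForest::randomForest(X, y, ntree = 300),
      prob = function(m, X) predict(m, X, type = "prob")),
    gradientBoosting = list(
      fit = function(X, y) xgbFit(X, y, eta = 0.1, max_depth = 3, nrounds = 120),
      prob = function(m, X) xgbProb(m, X)),
    naiveBayes = list(
      fit = function(X, y) e1071::naiveBayes(X, y),
      prob = function(m, X) predict(m, X, type = "raw")),
    knn = list(
      fit = function(X, y) caret::knn3(X, y, k = 5),
      prob = function(m, X) predict(m, X, type = "prob")),
    adaBoost = list(
      fit = function(X, y) adaboostFit(X, y, nRounds = 50),
      prob = function(m, X) adaboostProb(m, X)),
    xgboost = list(
      fit = function(X, y) xgbFit(X, y, eta = 0.3, max_depth = 6,
                                  nrounds = 80, lambda = 1),
      prob = function(m, X) xgbProb(m, X)),
    mlp = list(
      fit = function(X, y) nnet::nnet(X, nnet::class.ind(y), size = hidden,
                                      decay = 0.1, maxit = 200,
                                      softmax = TRUE, trace = FALSE,
                                      MaxNWts = 20000),
      prob = function(m, X) predict(m, X))
  )
}

glmnetEntry <- function(alpha) list(
  fit = function(X, y) {
    m <- glmnet::glmnet(X, y, family = "multinomial", alpha = alpha,
                        lambda = 0.01)
    attr(m, "lev") <- levels(y)
    m
  },
  prob = function(m, X) {
    p <- predict(m, X, type = "response")[, , 1]
    if (is.null(dim(p))) p <- rbind(p)
    p
  })

xgbFit <- function(X, y, eta, max_depth, nrounds, lambda = 0) {
  lev <- levels(y)
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1, nthread = 1)
  m <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(lev),
                  eta = eta, max_depth = max_depth, lambda = lambda,
                  nthread = 1),
    data = dtrain, nrounds = nrounds, verbose = 0)
  attr(m, "lev") <- lev
  m
}
xgbProb <- function(m, X) {
  lev <- attr(m, "lev")
  p <- predict(m, xgboost::xgb.DMatrix(X, nthread = 1))
  if (!is.matrix(p)) p <- matrix(p, ncol = length(lev), byrow = TRUE)
  colnames(p) <- lev
  p
}

## SAMME AdaBoost over depth-1 rpart stumps.
adaboostFit <- function(X, y, nRounds = 50) {
  lev <- levels(y); K <- length(lev)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  df <- data.frame(X, y = y)
  for (r in seq_len(nRounds)) {
    st <- rpart::rpart(y ~ ., df, weights = w, method = "class",
                       control = rpart::rpart.control(maxdepth = 1,
                                                      cp = 0, xval = 0))
    pred <- predict(st, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K || err <= 0) {
      if (err <= 0) { stumps[[r]] <- st; alphas[r] <- 10; }
      break
    }
    a <- log((1 - err) / err) + log(K - 1)
    stumps[[r]] <- st; alphas[r] <- a
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, alphas = alphas, lev = lev),
            class = "adaboostSAMME")
}
adaboostProb <- function(m, X) {
  df <- data.frame(X)
  K <- length(m$lev)
  score <- matrix(0, nrow(df), K, dimnames = list(NULL, m$lev))
  for (r in seq_along(m$stumps)) {
    pred <- predict(m$stumps[[r]], df, type = "class")
    score[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      score[cbind(seq_len(nrow(df)), as.integer(pred))] + m$alphas[r]
  }
  p <- exp(score - apply(score, 1, max))
  p / rowSums(p)
}

## ---- cross-validation ----------------------------------------------------

stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))[
        sample.int(length(idx))]
    }
    fold
  })
}

#' SMOTE + stratified k-fold cross-validated model comparison
#'
#' For every dataset spec and model: stratified folds; within each fold the
#' training part is median-imputed, SMOTE-upsampled to the strategy counts
#' and standardized (imputer, sampler and scaler all fit on the training
#' part only — synthetic rows never reach a test fold); the model is fit
#' and evaluated on the untouched test fold; metrics are averaged over
#' folds. The best model per dataset is the one with the highest mean
#' accuracy.
#'
#' @param se feature SummarizedExperiment.
#' @param specs list of [datasetSpec()].
#' @param models character subset of the zoo (default all:
#'   logistic, ridge, lasso, tree, svm, randomForest, gradientBoosting,
#'   naiveBayes, knn, adaBoost, xgboost, mlp).
#' @param k folds (default 10).
#' @param seed integer seed (folds, SMOTE, model initializations).
#' @param smoteStrategy named per-class target counts (default
#'   c(Cardiac=200, Healthy=200, Sport=200)); NULL disables upsampling;
#'   counts are raised to the fold's class count when lower.
#' @return a \linkS4class{CVReport}.
#' @export
runCV <- function(se, specs, models = names(modelZoo()), k = 10, seed = 1,
                  smoteStrategy = c(Cardiac = 200, Healthy = 200,
                                    Sport = 200)) {
  zoo <- modelZoo()[models]
  rows <- list(); preds <- list()
  best <- character(); confL <- list()
  for (spec in specs) {
    ds <- assembleDataset(se, spec)
    X <- ds$X; y <- ds$y
    if (nrow(X) < k) stop("need at least k subjects")
    fold <- stratifiedFolds(y, k, seed)
    for (mn in names(zoo)) {
      entry <- zoo[[mn]]
      for (f in seq_len(k)) {
        tr <- fold != f; te <- fold == f
        Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
        Xte <- X[te, , drop = FALSE]; yte <- y[te]
        med <- apply(Xtr, 2, median, na.rm = TRUE)
        med[!is.finite(med)] <- 0
        for (j in seq_len(ncol(Xtr))) {
          Xtr[is.na(Xtr[, j]), j] <- med[j]
          Xte[is.na(Xte[, j]), j] <- med[j]
        }
        if (!is.null(smoteStrategy)) {
          strat <- smoteStrategy[levels(ytr)]
          names(strat) <- levels(ytr)
          cnt <- table(ytr)
          strat <- pmax(strat, as.integer(cnt[names(strat)]))
          sm <- smoteResample(Xtr, ytr, strat, seed = seed * 1000 + f)
          Xtr <- sm$X; ytr <- sm$y
        }
        mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd)
        keepCols <- which(is.finite(sg) & sg > 1e-12)
        if (!length(keepCols)) keepCols <- 1L
        Xtr <- Xtr[, keepCols, drop = FALSE]
        Xte <- Xte[, keepCols, drop = FALSE]
        mu <- mu[keepCols]; sg <- sg[keepCols]
        Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
        Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
        res <- tryCatch(withSeed(seed * 100 + f, {
          mod <- entry$fit(Xtr, ytr)
          p <- entry$prob(mod, Xte)
          p <- p[, levels(y), drop = FALSE]
          p <- p / rowSums(p)
          pred <- factor(levels(y)[max.col(p)], levels = levels(y))
          list(p = p, pred = pred)
        }), error = function(e) NULL)
        if (is.null(res)) {
          rows[[length(rows) + 1L]] <- data.frame(
            dataset = spec$id, model = mn, fold = f, accuracy = NA,
            precision = NA, recall = NA, f1 = NA, mcc = NA, auc = NA,
            failed = TRUE)
          next
        }
        met <- computeMetrics(yte, res$pred, res$p)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = spec$id, model = mn, fold = f,
          accuracy = met$accuracy, precision = met$precision,
          recall = met$recall, f1 = met$f1, mcc = met$mcc, auc = met$auc,
          failed = FALSE)
        preds[[length(preds) + 1L]] <- data.frame(
          dataset = spec$id, model = mn, fold = f,
          subject = rownames(X)[te], truth = as.character(yte),
          pred = as.character(res$pred), res$p, check.names = FALSE)
      }
    }
    fm <- do.call(rbind, rows)
    fm <- fm[fm$dataset == spec$id & !fm$failed, ]
    accByModel <- tapply(fm$accuracy, fm$model, mean)
    best[spec$id] <- names(which.max(accByModel))
    pd <- do.call(rbind, preds)
    pd <- pd[pd$dataset == spec$id & pd$model == best[spec$id], ]
    confL[[spec$id]] <- table(truth = factor(pd$truth, levels(y)),
                              pred = factor(pd$pred, levels(y)))
  }
  new("CVReport", foldMetrics = do.call(rbind, rows),
      predictions = do.call(rbind, preds), bestModel = best,
      confusion = confL, seeds = as.integer(seed))
}

#' Pairwise Wilcoxon comparison of datasets
#'
#' Two-sided Wilcoxon signed-rank tests on the per-fold metric values of
#' each dataset pair (paired by fold), for the chosen metric and each
#' dataset's best model. All-zero difference vectors give p = 1 with a tie
#' flag. No multiplicity correction is applied.
#'
#' @param report a \linkS4class{CVReport}.
#' @param metric metric column (default "accuracy").
#' @param models optional named character (dataset -> model); defaults to
#'   the report's best models.
#' @return symmetric matrix of p-values (diagonal 1), attribute
#'   \code{"ties"} marks degenerate pairs.
#' @export
compareDatasets <- function(report, metric = "accuracy", models = NULL) {
  fm <- foldMetrics(report)
  ds <- unique(fm$dataset)
  if (is.null(models)) models <- bestModel(report)
  P <- matrix(1, length(ds), length(ds), dimnames = list(ds, ds))
  ties <- matrix(FALSE, length(ds), length(ds), dimnames = list(ds, ds))
  for (i in seq_along(ds)) for (j in seq_along(ds)) {
    if (j <= i) next
    a <- fm[fm$dataset == ds[i] & fm$model == models[[ds[i]]], ]
    b <- fm[fm$dataset == ds[j] & fm$model == models[[ds[j]]], ]
    a <- a[order(a$fold), metric]; b <- b[order(b$fold), metric]
    d <- a - b
    if (all(d == 0)) { p <- 1; ties[i, j] <- ties[j, i] <- TRUE }
    else p <- suppressWarnings(
      wilcox.test(a, b, paired = TRUE, exact = NULL)$p.value)
    P[i, j] <- P[j, i] <- p
  }
  attr(P, "ties") <- ties
  P
}

#' Kruskal-Wallis comparison of demographics across groups
#'
#' @param cohort a \linkS4class{CRCohort}, or the colData data.frame of a
#'   feature SummarizedExperiment.
#' @param variables demographic columns to test.
#' @return data.frame(variable, H, p).
#' @export
demographicTests <- function(cohort,
                             variables = c("age", "weight_kg", "height_cm",
                                           "bmi")) {
  df <- if (is(cohort, "CRCohort")) cohortManifest(cohort)
        else as.data.frame(cohort)
  g <- factor(df$group)
  if (nlevels(g) < 3) stop("need 3 groups")
  if (any(table(g) < 2)) stop("each group needs at least 2 subjects")
  out <- lapply(variables, function(v) {
    kt <- kruskal.test(df[[v]], g)
    data.frame(variable = v, H = unname(kt$statistic),
               p = kt$p.value)
  })
  do.call(rbind, out)
}
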