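## Explainability: Monte-Carlo permutation-sampling Shapley attributions,
## permutation variable importance with a 1-AUC dropout loss, and the
## top-k feature selection that defines the reduced datasets.

#' Monte-Carlo Shapley attributions
#'
#' Permutation-sampling estimator: for each explained row, random feature
#' orderings are walked from the background toward the explained row,
#' attributing each output change to the feature just switched in. Every
#' sampled ordering is evaluated against the whole (capped) background set,
#' so the estimator is exact for additive models and each path telescopes:
#' local additivity \eqn{\sum_j \phi_j(x) + baseline = f(x)} holds to
#' numerical precision.
#'
#' @param probFun function(matrix) -> class-probability matrix (rows sum
#'   to 1). Models without probability output can be wrapped to return
#'   decision scores; attributions are then in score units.
#' @param X rows to explain (matrix, named columns).
#' @param background background rows (matrix; at most \code{maxBackground}
#'   rows are kept).
#' @param nSamples sampled feature orderings per explained row (default 30).
#' @param seed integer seed; fixed seed gives identical output.
#' @param maxBackground background cap (default 100).
#' @return list with \code{phi} (array samples x features x classes),
#'   \code{baseline} (per-sample per-class baseline matrix), \code{fx}
#'   (model output at the explained rows).
#' @export
shapleyAttributions <- function(probFun, X, background, nSamples = 30,
                                seed = 1, maxBackground = 100) {
  X <- as.matrix(X); background <- as.matrix(background)
  if (!nrow(background)) stop("background set must be non-empty")
  withSeed(seed, {
    if (nrow(background) > maxBackground)
      background <- background[sample(nrow(background), maxBackground), ,
                               drop = FALSE]
    p <- ncol(X); nBg <- nrow(background)
    fx <- probFun(X)
    K <- ncol(fx)
    phi <- array(0, dim = c(nrow(X), p, K),
                 dimnames = list(rownames(X), colnames(X), colnames(fx)))
    baseline <- matrix(0, nrow(X), K)
    step <- rep(0:p, times = nBg)       # replacement depth within each block
    blockBase <- background[rep(seq_len(nBg), each = p + 1), , drop = FALSE]
    colnames(blockBase) <- colnames(X)
    idxAfter <- which(step > 0)
    for (i in seq_len(nrow(X))) {
      acc <- matrix(0, p, K)
      bacc <- numeric(K)
      for (s in seq_len(nSamples)) {
        perm <- sample.int(p)
        W <- blockBase
        for (r in seq_len(p))
          W[step >= r, perm[r]] <- X[i, perm[r]]
        out <- probFun(W)
        d <- out[idxAfter, , drop = FALSE] - out[idxAfter - 1, , drop = FALSE]
        dsum <- rowsum(d, group = step[idxAfter], reorder = TRUE)
        acc[perm, ] <- acc[perm, ] + dsum / nBg
        bacc <- bacc + colSums(out[step == 0, , drop = FALSE]) / nBg
      }
      phi[i, , ] <- acc / nSamples
      baseline[i, ] <- bacc / nSamples
    }
    list(phi = phi, baseline = baseline, fx = fx)
  })
}

#' Permutation variable importance (1 - AUC dropout loss)
#'
#' For each feature and class: the one-vs-rest 1-AUC loss after permuting
#' that feature's column, minus the unpermuted baseline loss, averaged over
#' permutation rounds (30 by default). Positive values mean the model
#' leans on the feature for that class.
#'
#' @param probFun function(matrix) -> class-probability matrix.
#' @param X test matrix.
#' @param y true labels (factor over the probability columns' classes).
#' @param rounds permutation rounds (default 30).
#' @param seed integer seed.
#' @return list(mean, sd): feature x class matrices of importance means
#'   and SDs; classes with undefined AUC are NA-masked.
#' @export
permutationImportance <- function(probFun, X, y, rounds = 30, seed = 1) {
  X <- as.matrix(X); y <- factor(y)
  p0 <- probFun(X)
  lev <- colnames(p0)
  lossOf <- function(pm) vapply(lev, function(cl) {
    pos <- y == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    1 - ovrAUC(pm[, cl], pos)
  }, 0)
  base <- lossOf(p0)
  withSeed(seed, {
    res <- array(NA_real_, c(ncol(X), length(lev), rounds),
                 dimnames = list(colnames(X), lev, NULL))
    for (r in seq_len(rounds)) {
      ord <- sample.int(nrow(X))           # one shuffle order per round
      for (j in seq_len(ncol(X))) {
        Xp <- X
        Xp[, j] <- X[ord, j]
        res[j, , r] <- lossOf(probFun(Xp)) - base
      }
    }
    list(mean = apply(res, c(1, 2), mean), sd = apply(res, c(1, 2), sd),
         baselineLoss = base, rounds = rounds)
  })
}

#' Select the most influential features by pooled |Shapley|
#'
#' Ranks features by the mean absolute Shapley value pooled over explained
#' samples, cross-validation folds and classes, and returns the top k
#' names (ties broken alphabetically for determinism).
#'
#' @param attributions one attribution list from [shapleyAttributions()],
#'   or a list of them (one per CV fold).
#' @param k number of features to keep (default 35).
#' @return character vector of k feature names, most influential first.
#' @export
selectTopFeatures <- function(attributions, k = 35) {
  if (!is.null(attributions$phi)) attributions <- list(attributions)
  pooled <- NULL
  for (a in attributions) {
    m <- apply(abs(a$phi), 2, sum)     # sum over samples & classes
    n <- dim(a$phi)[1] * dim(a$phi)[3]
    contrib <- cbind(total = m, n = n)
    if (is.null(pooled)) pooled <- contrib
    else {
      stopifnot(identical(rownames(pooled), rownames(contrib)))
      pooled[, "total"] <- pooled[, "total"] + contrib[, "total"]
      pooled[, "n"] <- pooled[, "n"] + contrib[, "n"]
    }
  }
  score <- pooled[, "total"] / pooled[, "n"]
  if (k > length(score)) stop("k exceeds the number of features")
  ord <- order(-score, names(score))
  names(score)[ord][seq_len(k)]
}

#' Cross-validated Shapley attributions for a dataset
#'
#' Replays the stratified folds of [runCV()] (same seed), refits the given
#' model per fold with the same impute/SMOTE/standardize pipeline, and
#' explains each test fold against a background of (up to 100) training
#' rows. The pooled result feeds [selectTopFeatures()], defining the
#' reduced feature sets.
#'
#' @param se feature SummarizedExperiment.
#' @param spec source [datasetSpec()] (the full feature space).
#' @param model model name from the zoo.
#' @param k folds.
#' @param seed integer seed (must match the [runCV()] seed to reproduce
#'   its folds).
#' @param nSamples Shapley Monte-Carlo paths per row.
#' @param smoteStrategy as in [runCV()].
#' @return list of per-fold attribution lists.
#' @export
cvShapley <- function(se, spec, model, k = 10, seed = 1, nSamples = 20,
                      smoteStrategy = c(Cardiac = 200, Healthy = 200,
                                        Sport = 200)) {
  zoo <- modelZoo()
  entry <- zoo[[model]]
  ds <- assembleDataset(se, spec)
  X <- ds$X; y <- ds$y
  fold <- stratifiedFolds(y, k, seed)
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    Xte <- X[te, , drop = FALSE]
    med <- apply(Xtr, 2, median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in seq_len(ncol(Xtr))) {
      Xtr[is.na(Xtr[, j]), j] <- med[j]
      Xte[is.na(Xte[, j]), j] <- med[j]
    }
    XtrRaw <- Xtr
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
    XtrRaw <- XtrRaw[, keepCols, drop = FALSE]
    mu <- mu[keepCols]; sg <- sg[keepCols]
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(Xte, 2, mu), 2, sg, "/")
    bg <- sweep(sweep(XtrRaw, 2, mu), 2, sg, "/")
    mod <- withSeed(seed * 100 + f, entry$fit(Xtr, ytr))
    probFun <- function(M) {
      p <- entry$prob(mod, M)
      p[, levels(y), drop = FALSE]
    }
    sh <- shapleyAttributions(probFun, Xte, bg, nSamples = nSamples,
                              seed = seed + f)
    # re-embed over the full column set (dropped constant columns get 0)
    full <- array(0, dim = c(nrow(Xte), ncol(X), dim(sh$phi)[3]),
                  dimnames = list(rownames(Xte), colnames(X),
                                  dimnames(sh$phi)[[3]]))
    full[, colnames(Xte), ] <- sh$phi
    sh$phi <- full
    out[[f]] <- sh
  }
  out
}
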