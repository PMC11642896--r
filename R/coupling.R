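## Causal- and information-domain cardiorespiratory coupling features.
##
## Directional coupling between the respiration signal and the tachogram is
## quantified by linear Granger causality (log ratio of restricted vs full
## autoregression residual variances), a kernel (Gaussian-RBF) variant, a
## large-scale nonlinear variant (clustered delay embeddings with RBF
## activations and an F-statistic), ML-based variants (MLP and polynomial
## predictors, held-out MSE ratio), transfer entropy, lagged mutual
## information and the maximal lagged Pearson correlation.

## lag-embedding: column k holds x_{t-k} aligned with x_t at row t - p.
lagMatrix <- function(x, p) {
  n <- length(x)
  out <- matrix(0, n - p, p)
  for (k in seq_len(p)) out[, k] <- x[(p - k + 1):(n - k)]
  out
}

#' Select the autoregressive model order
#'
#' Chooses the lag order minimizing the BIC of the full bivariate linear
#' model (target regressed on its own and the source's lags), evaluated on
#' a common sample (first \code{pMax} rows dropped for every candidate).
#'
#' @param source,target numeric series of equal length.
#' @param pMax maximum order (default 25 samples = 1 s at 25 Hz).
#' @return the selected order (integer).
#' @export
selectOrder <- function(source, target, pMax = 25) {
  if (pMax < 1) stop("pMax must be >= 1")
  n <- length(target)
  if (n <= 10 * pMax) pMax <- max(1L, floor((n - 1) / 10))
  y <- target[(pMax + 1):n]
  nn <- length(y)
  Xt <- lagMatrix(target, pMax); Xs <- lagMatrix(source, pMax)
  bic <- vapply(seq_len(pMax), function(p) {
    off <- pMax - p
    X <- cbind(1, Xt[, seq_len(p), drop = FALSE],
               Xs[, seq_len(p), drop = FALSE])
    fit <- .lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    nn * log(rss / nn) + (2 * p + 1) * log(nn)
  }, 0)
  which.min(bic)
}

#' Linear Granger causality
#'
#' Fits by OLS the restricted autoregression of the target on its own p
#' lags and the full bivariate model adding the source's p lags; the
#' causality measure is \eqn{GC = \ln(\sigma^2_{\epsilon 1} /
#' \sigma^2_{\epsilon 2})}, the log ratio of the residual variances
#' (1/(n-k) normalization). The full model nests the restricted one, so GC
#' is non-negative up to OLS tolerance.
#'
#' @param source,target numeric series of equal length, length > 10 p.
#' @param p lag order.
#' @return object of class \code{"GCResult"}: list with \code{gc},
#'   \code{p}, \code{residVarRestricted}, \code{residVarFull},
#'   \code{restrictedCoeffs}, \code{fullCoeffs}, \code{masked},
#'   \code{flag}.
#' @export
linearGC <- function(source, target, p) {
  n <- length(target)
  stopifnot(length(source) == n)
  out <- list(gc = NA_real_, p = p, residVarRestricted = NA_real_,
              residVarFull = NA_real_, restrictedCoeffs = NULL,
              fullCoeffs = NULL, masked = TRUE, flag = NULL)
  class(out) <- "GCResult"
  if (!all(is.finite(source)) || !all(is.finite(target)) ||
      sd(target) == 0 || sd(source) == 0) {
    out$flag <- "degenerate_input"
    return(out)
  }
  y <- target[(p + 1):n]
  Xt <- lagMatrix(target, p); Xs <- lagMatrix(source, p)
  nn <- length(y)
  fitR <- .lm.fit(cbind(1, Xt), y)
  fitF <- .lm.fit(cbind(1, Xt, Xs), y)
  kR <- p + 1; kF <- 2 * p + 1
  s2R <- sum(fitR$residuals^2) / (nn - kR)
  s2F <- sum(fitF$residuals^2) / (nn - kF)
  if (!is.finite(s2R) || !is.finite(s2F) || s2F <= 0) {
    out$flag <- "rank_deficient"
    return(out)
  }
  out$gc <- log(s2R / s2F)
  out$residVarRestricted <- s2R
  out$residVarFull <- s2F
  out$restrictedCoeffs <- fitR$coefficients
  out$fullCoeffs <- fitF$coefficients
  out$masked <- FALSE
  out
}

#' @export
print.GCResult <- function(x, ...) {
  cat(sprintf("GCResult: gc = %.4f (p = %d, sigma2 %.4g -> %.4g)%s\n",
              x$gc, x$p, x$residVarRestricted, x$residVarFull,
              if (x$masked) " [masked]" else ""))
  invisible(x)
}

#' Directional Granger-causality ratio
#'
#' GC(Resp->RR) / GC(RR->Resp); masked when the denominator is at or below
#' 1e-8 (after clipping negative finite-sample estimates to 0).
#'
#' @param respSeries,rrSeries the 25 Hz respiration and tachogram series.
#' @param p lag order.
#' @return list(ratio, gcRespToRR, gcRRToResp, masked).
#' @export
gcRatio <- function(respSeries, rrSeries, p) {
  g1 <- linearGC(respSeries, rrSeries, p)
  g2 <- linearGC(rrSeries, respSeries, p)
  num <- max(g1$gc, 0); den <- max(g2$gc, 0)
  masked <- g1$masked || g2$masked || !is.finite(den) || den <= 1e-8
  list(ratio = if (masked) NA_real_ else num / den,
       gcRespToRR = g1$gc, gcRRToResp = g2$gc, masked = masked)
}

## RBF activation matrix of rows of Z against centers C, bandwidth sigma.
rbfActivations <- function(Z, C, sigma) {
  zz <- rowSums(Z^2); cc <- rowSums(C^2)
  d2 <- outer(zz, cc, "+") - 2 * Z %*% t(C)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

ridgeFit <- function(X, y, lambda) {
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  G <- crossprod(Xs) + diag(lambda, ncol(Xs))
  b <- solve(G, crossprod(Xs, y - mean(y)))
  res <- (y - mean(y)) - Xs %*% b
  sum(res^2)
}

#' Kernel Granger causality
#'
#' Ridge-regularized regression in a Gaussian-RBF feature space: the
#' restricted embedding holds the target's lags, the full embedding both
#' signals' lags; each embedding contributes its raw (linear) lag terms
#' plus RBF activations against \code{nCenters} deterministically chosen
#' (evenly spaced) embedding rows with bandwidth \code{kernelWidth} x the
#' median pairwise center distance. Keeping the linear span inside the
#' feature space makes the estimator nest linear GC (it agrees with it on
#' linear data for any width) while the RBF part adds sensitivity to
#' nonlinear coupling. The causality index is the log residual-variance
#' ratio, clipped at 0.
#'
#' @param source,target standardized numeric series.
#' @param p lag order.
#' @param kernelWidth bandwidth multiplier (> 0, default 1).
#' @param nCenters number of RBF centers (default 100).
#' @param lambda ridge penalty (default 1e-4 per row).
#' @return causality index (dimensionless, >= 0).
#' @export
kernelGC <- function(source, target, p, kernelWidth = 1, nCenters = 100,
                     lambda = 1e-4) {
  if (kernelWidth <= 0) stop("kernelWidth must be positive")
  n <- length(target)
  source <- as.numeric(scale(source)); target <- as.numeric(scale(target))
  y <- target[(p + 1):n]
  Zr <- lagMatrix(target, p)
  Zf <- cbind(Zr, lagMatrix(source, p))
  m <- min(nCenters, nrow(Zf))
  idx <- unique(round(seq(1, nrow(Zf), length.out = m)))
  fitOne <- function(Z) {
    C <- Z[idx, , drop = FALSE]
    dC <- dist(C)
    sigma <- kernelWidth * median(dC[dC > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    A <- cbind(Z, rbfActivations(Z, C, sigma))
    ridgeFit(A, y, lambda * length(y))
  }
  rssR <- fitOne(Zr); rssF <- fitOne(Zf)
  if (!is.finite(rssR) || !is.finite(rssF) || rssF <= 0) return(NA_real_)
  max(log(rssR / rssF), 0)
}

#' Large-scale nonlinear Granger causality
#'
#' Time-delay embeds the source, clusters the embedded points by k-means,
#' converts distances to cluster centers into row-normalized Gaussian-RBF
#' activations, and appends them to the target's autoregression. The
#' F-statistic compares full and restricted residual sums of squares with
#' (nCenters, n - p - nCenters - 1) degrees of freedom; the affinity is the
#' share of restricted RSS removed by the activations.
#'
#' @param source,target numeric series.
#' @param nCenters number of k-means clusters (default 8).
#' @param p embedding/autoregression order.
#' @param seed seed for k-means initialization.
#' @return list(fStatistic, affinity, df1, df2, flag).
#' @export
lsngc <- function(source, target, nCenters = 8, p = 3, seed = 1) {
  n <- length(target)
  if (n <= 10 * (nCenters + p)) stop("series too short for the embedding")
  source <- as.numeric(scale(source)); target <- as.numeric(scale(target))
  y <- target[(p + 1):n]
  Xt <- lagMatrix(target, p)
  S <- lagMatrix(source, p)
  km <- NULL; flag <- NULL
  for (attempt in 1:2) {
    km <- tryCatch(
      withSeed(seed + attempt - 1L,
               kmeans(S, centers = nCenters, nstart = 1, iter.max = 30)),
      error = function(e) NULL)
    if (!is.null(km) && !anyDuplicated(km$centers)) break
    flag <- "kmeans_reseeded"
  }
  if (is.null(km))
    return(list(fStatistic = NA_real_, affinity = NA_real_,
                df1 = nCenters, df2 = NA_real_, flag = "kmeans_failed"))
  sigma <- sqrt(mean(km$withinss / pmax(km$size, 1)))
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  A <- rbfActivations(S, km$centers, sigma)
  A <- A / pmax(rowSums(A), .Machine$double.eps)   # row-normalized
  nn <- length(y)
  fitR <- .lm.fit(cbind(1, Xt), y)
  fitF <- .lm.fit(cbind(1, Xt, A), y)
  rssR <- sum(fitR$residuals^2); rssF <- sum(fitF$residuals^2)
  df1 <- nCenters; df2 <- nn - p - nCenters - 1
  f <- ((rssR - rssF) / df1) / (rssF / df2)
  list(fStatistic = max(f, 0), affinity = max((rssR - rssF) / rssR, 0),
       df1 = df1, df2 = df2, flag = flag)
}

## degree-2 polynomial expansion: linear terms plus squares.
polyExpand <- function(X) cbind(X, X^2)

#' ML-model Granger causality
#'
#' Fits two nonlinear predictors of identical kind and capacity — a
#' single-hidden-layer perceptron or a degree-2 polynomial regression —
#' of the target from its own lags plus the source's lags, on the first
#' 70% of the series, and compares held-out (30% tail) mean squared
#' errors. The restricted reference feeds the same architecture a
#' circularly time-shifted surrogate of the source (temporal alignment
#' destroyed, marginal and autocorrelation preserved), so model-capacity
#' and optimizer effects cancel instead of biasing the log MSE ratio
#' negative; a naive target-lags-only restricted model systematically
#' favors itself by the capacity spent on useless source inputs. The
#' causality value is ln(MSE_surrogate / MSE_true), ~0 for independent
#' series.
#'
#' @param source,target numeric series.
#' @param modelKind "mlp" or "polynomial".
#' @param p lag order.
#' @param seed seed (MLP weight initialization; both fits share it);
#'   fixed seed gives identical values.
#' @param hidden hidden-layer size for the MLP (default 16).
#' @param maxit training iterations (default 150).
#' @return causality value (dimensionless; ~0 for independent series).
#' @export
mlGC <- function(source, target, modelKind = c("mlp", "polynomial"), p,
                 seed = 1, hidden = 16, maxit = 150) {
  modelKind <- match.arg(modelKind)
  n <- length(target)
  source <- as.numeric(scale(source)); target <- as.numeric(scale(target))
  y <- target[(p + 1):n]
  Xt <- lagMatrix(target, p)
  shift <- floor(n / 2)
  surrogate <- c(source[(shift + 1):n], source[1:shift])
  Xf <- cbind(Xt, lagMatrix(source, p))
  Xs <- cbind(Xt, lagMatrix(surrogate, p))
  nn <- length(y)
  nTr <- floor(0.7 * nn)
  tr <- seq_len(nTr); te <- (nTr + 1):nn
  heldOutMSE <- function(X) {
    if (modelKind == "polynomial") {
      Xp <- polyExpand(X)
      fit <- .lm.fit(cbind(1, Xp[tr, , drop = FALSE]), y[tr])
      pred <- cbind(1, Xp[te, , drop = FALSE]) %*% fit$coefficients
    } else {
      fit <- withSeed(seed, tryCatch(
        nnet::nnet(X[tr, , drop = FALSE], y[tr], size = hidden,
                   linout = TRUE, decay = 0.01, maxit = maxit,
                   trace = FALSE, MaxNWts = 5000),
        error = function(e) NULL))
      if (is.null(fit)) return(NA_real_)
      pred <- predict(fit, X[te, , drop = FALSE])
    }
    mean((y[te] - pred)^2)
  }
  mseS <- heldOutMSE(Xs); mseF <- heldOutMSE(Xf)
  if (!is.finite(mseS) || !is.finite(mseF) || mseF <= 0) return(NA_real_)
  log(mseS / mseF)
}

## equal-frequency discretization into at most nBins symbols
equalFreqBins <- function(x, nBins) {
  u <- unique(x)
  if (length(u) <= nBins) return(match(x, sort(u)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 3) return(NULL)
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

discreteEntropy <- function(...) {
  tab <- table(...)
  p <- tab / sum(tab); p <- p[p > 0]
  -sum(p * log2(p))
}

#' Transfer entropy
#'
#' \deqn{TE_{X \to Y} = H(Y_{t+1} | Y_t) - H(Y_{t+1} | Y_t, X_{t-lag+1})}
#' estimated by plug-in on equal-frequency binned series, minus a
#' shuffle-baseline correction (source shuffled \code{nShuffle} times under
#' a fixed seed), floored at 0.
#'
#' @param source,target numeric series (>= 1000 samples recommended).
#' @param lag source lag in samples (default 1: the source value at time t).
#' @param nBins number of equal-frequency bins (default 4).
#' @param nShuffle shuffle-baseline repetitions (default 20).
#' @param seed seed for the shuffles.
#' @return transfer entropy in bits (masked NA when binning degenerates).
#' @export
transferEntropy <- function(source, target, lag = 1, nBins = 4,
                            nShuffle = 20, seed = 1) {
  n <- min(length(source), length(target))
  xs <- equalFreqBins(source[seq_len(n)], nBins)
  ys <- equalFreqBins(target[seq_len(n)], nBins)
  if (is.null(xs) || is.null(ys)) return(NA_real_)
  idx <- seq(lag, n - 1)          # t ranges so that t - lag + 1 >= 1
  yNext <- ys[idx + 1]; yNow <- ys[idx]; xLag <- xs[idx - lag + 1]
  teOf <- function(xv) {
    (discreteEntropy(yNext, yNow) - discreteEntropy(yNow)) -
      (discreteEntropy(yNext, yNow, xv) - discreteEntropy(yNow, xv))
  }
  te <- teOf(xLag)
  base <- withSeed(seed, mean(vapply(seq_len(nShuffle), function(i)
    teOf(sample(xLag)), 0)))
  max(te - base, 0)
}

#' Lagged mutual information
#'
#' Plug-in mutual information of equal-frequency binned series at a given
#' lag (positive lag: the second series is delayed), with a shuffle
#' baseline subtracted.
#'
#' @param x,y numeric series.
#' @param lag lag in samples applied to \code{y}.
#' @param nBins equal-frequency bins.
#' @param nShuffle,seed shuffle-baseline settings.
#' @return mutual information in bits.
#' @export
mutualInformation <- function(x, y, lag = 0, nBins = 4, nShuffle = 20,
                              seed = 1) {
  n <- min(length(x), length(y))
  if (lag >= 0) { xv <- x[1:(n - lag)]; yv <- y[(1 + lag):n] }
  else { xv <- x[(1 - lag):n]; yv <- y[1:(n + lag)] }
  xb <- equalFreqBins(xv, nBins); yb <- equalFreqBins(yv, nBins)
  if (is.null(xb) || is.null(yb)) return(NA_real_)
  miOf <- function(a) discreteEntropy(a) + discreteEntropy(yb) -
    discreteEntropy(a, yb)
  mi <- miOf(xb)
  base <- withSeed(seed, mean(vapply(seq_len(nShuffle), function(i)
    miOf(sample(xb)), 0)))
  max(mi - base, 0)
}

#' Maximal lagged Pearson correlation
#'
#' The signed Pearson correlation of greatest absolute value between the
#' two series over integer-sample lags within +/- \code{maxLagS} seconds
#' (overlap-only windows, no padding), and the lag at which it occurs;
#' ties are broken toward the lag closest to 0. A positive lag means the
#' second series trails the first.
#'
#' @param respSeries,rrSeries numeric series (respiration, tachogram).
#' @param fs sampling rate, Hz.
#' @param maxLagS lag window half-width, s (default 1).
#' @return list(rMax, lagAtMax, masked).
#' @export
maxLaggedCorrelation <- function(respSeries, rrSeries, fs, maxLagS = 1) {
  n <- min(length(respSeries), length(rrSeries))
  x <- respSeries[seq_len(n)]; y <- rrSeries[seq_len(n)]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rMax = NA_real_, lagAtMax = NA_real_, masked = TRUE))
  maxK <- round(maxLagS * fs)
  lags <- -maxK:maxK
  rs <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(x[1:(n - k)], y[(1 + k):n])
    else stats::cor(x[(1 - k):n], y[1:(n + k)])
  }, 0)
  best <- which(abs(rs) == max(abs(rs)))
  best <- best[which.min(abs(lags[best]))]
  list(rMax = rs[best], lagAtMax = lags[best] / fs, masked = FALSE)
}

#' Coupling-feature control parameters
#'
#' The causality family (linear/kernel/lsNGC/ML GC and transfer entropy)
#' is estimated on a further-decimated analysis grid (default 5 Hz): on
#' the heavily oversampled cubic-interpolated tachogram at 25 Hz the
#' restricted autoregression residual variance collapses toward numerical
#' noise and the GC log-ratio becomes spurious (it stays far above zero
#' even for uncoupled pairs), while at 5 Hz with a 1 s lag window the
#' estimators show textbook behavior (near-zero for uncoupled pairs,
#' monotone in coupling strength). Correlation, mutual-information and
#' entropy features stay on the 25 Hz grid.
#'
#' @param pMax maximum lag order for BIC selection (default 5 analysis
#'   samples = 1 s at the 5 Hz analysis grid).
#' @param p fixed lag order; NULL (default) selects by BIC.
#' @param fsAnalysis analysis grid for the causality family, Hz (default
#'   5; must divide the downsampled rate).
#' @param nCentersKGC,kernelWidth kernel-GC settings.
#' @param nCentersLsngc lsNGC cluster count.
#' @param teBins,teShuffles transfer-entropy binning and baseline settings.
#' @param mlHidden,mlMaxit ML-GC MLP capacity and training length.
#' @param seed base seed for the stochastic estimators.
#' @return named list.
#' @export
couplingControl <- function(pMax = 5, p = NULL, fsAnalysis = 5,
                            nCentersKGC = 100, kernelWidth = 1,
                            nCentersLsngc = 8, teBins = 4,
                            teShuffles = 20, mlHidden = 16, mlMaxit = 150,
                            seed = 1) {
  list(pMax = pMax, p = p, fsAnalysis = fsAnalysis,
       nCentersKGC = nCentersKGC, kernelWidth = kernelWidth,
       nCentersLsngc = nCentersLsngc, teBins = teBins,
       teShuffles = teShuffles, mlHidden = mlHidden, mlMaxit = mlMaxit,
       seed = seed)
}

#' Assemble the 32 causal/information features
#'
#' Evaluates the manifest's causal/information block on the preprocessed
#' signal pair: both directions for linear GC (on the decimated analysis
#' grid and on the beat-aligned pair), kernel GC, lsNGC (F-statistic and
#' affinity), ML GC (MLP and polynomial), and transfer entropy (lags 1 and
#' 2); plus the GC ratios, mutual information at lag 0 and its lagged
#' maximum, Pearson correlations, signal/joint/conditional entropies and
#' cross sample/approximate entropies. Negative finite-sample causality
#' estimates are clipped at 0 for output (raw values are kept in the
#' attached log).
#'
#' @param pre output of [preprocessRecording()] (or a list with
#'   \code{resp25}, \code{tach25}, \code{respFiltered}, \code{tachogram},
#'   \code{fs}, \code{fsDown}).
#' @param control settings from [couplingControl()].
#' @return named numeric vector of 32 features, with attribute
#'   \code{"log"} (order used, raw GC values, flags).
#' @export
assembleCouplingFeatures <- function(pre, control = couplingControl()) {
  r25 <- as.numeric(scale(pre$resp25)); t25 <- as.numeric(scale(pre$tach25))
  fsD <- pre$fsDown %||% 25
  dec <- max(1L, round(fsD / control$fsAnalysis))
  rA <- if (dec > 1) as.numeric(signal::decimate(r25, dec)) else r25
  tA <- if (dec > 1) as.numeric(signal::decimate(t25, dec)) else t25
  m <- featureManifest()
  nm <- m$name[m$domain == "causal_information"]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  logL <- list(flags = character())
  p <- control$p %||% selectOrder(rA, tA, control$pMax)
  logL$p <- p
  clip0 <- function(v) if (is.finite(v)) max(v, 0) else NA_real_
  g1 <- linearGC(rA, tA, p); g2 <- linearGC(tA, rA, p)
  logL$gcRaw <- c(RespToRR = g1$gc, RRToResp = g2$gc)
  out["GC_RespToRR"] <- clip0(g1$gc); out["GC_RRToResp"] <- clip0(g2$gc)
  gr <- gcRatio(rA, tA, p)
  out["GCRatio"] <- gr$ratio
  rriSrc <- pre$tachogram$sourceRRI
  if (!is.null(rriSrc) && !is.null(pre$respFiltered)) {
    bt <- cumsum(rriSrc) / 1000
    rf <- pre$respFiltered
    idx <- pmin(pmax(round(bt * pre$fs) + 1, 1), length(rf))
    rb <- as.numeric(scale(rf[idx])); rrn <- as.numeric(scale(rriSrc))
    pb <- selectOrder(rb, rrn, 3)   # ~2-3 beats back, within the +/-1 s window
    gb1 <- linearGC(rb, rrn, pb); gb2 <- linearGC(rrn, rb, pb)
    logL$gcBeatRaw <- c(RespToRR = gb1$gc, RRToResp = gb2$gc)
    logL$pBeat <- pb
    out["GCbeat_RespToRR"] <- clip0(gb1$gc)
    out["GCbeat_RRToResp"] <- clip0(gb2$gc)
  }
  k1 <- kernelGC(rA, tA, p, control$kernelWidth, control$nCentersKGC)
  k2 <- kernelGC(tA, rA, p, control$kernelWidth, control$nCentersKGC)
  out["KGC_RespToRR"] <- k1; out["KGC_RRToResp"] <- k2
  out["KGCRatio"] <- if (is.finite(k2) && k2 > 1e-8) k1 / k2 else NA_real_
  l1 <- lsngc(rA, tA, control$nCentersLsngc, p, seed = control$seed)
  l2 <- lsngc(tA, rA, control$nCentersLsngc, p, seed = control$seed)
  out["LsNGC_F_RespToRR"] <- l1$fStatistic
  out["LsNGC_F_RRToResp"] <- l2$fStatistic
  out["LsNGC_Aff_RespToRR"] <- l1$affinity
  out["LsNGC_Aff_RRToResp"] <- l2$affinity
  mlRaw <- c(
    mlpF = mlGC(rA, tA, "mlp", p, seed = control$seed,
                hidden = control$mlHidden, maxit = control$mlMaxit),
    mlpR = mlGC(tA, rA, "mlp", p, seed = control$seed,
                hidden = control$mlHidden, maxit = control$mlMaxit),
    polyF = mlGC(rA, tA, "polynomial", p),
    polyR = mlGC(tA, rA, "polynomial", p))
  logL$mlRaw <- mlRaw
  out["MLGCmlp_RespToRR"] <- clip0(mlRaw["mlpF"])
  out["MLGCmlp_RRToResp"] <- clip0(mlRaw["mlpR"])
  out["MLGCpoly_RespToRR"] <- clip0(mlRaw["polyF"])
  out["MLGCpoly_RRToResp"] <- clip0(mlRaw["polyR"])
  out["TE_RespToRR"] <- transferEntropy(rA, tA, lag = 1, control$teBins,
                                        control$teShuffles, control$seed)
  out["TE_RRToResp"] <- transferEntropy(tA, rA, lag = 1, control$teBins,
                                        control$teShuffles, control$seed)
  out["TE2_RespToRR"] <- transferEntropy(rA, tA, lag = 2, control$teBins,
                                         control$teShuffles, control$seed)
  out["TE2_RRToResp"] <- transferEntropy(tA, rA, lag = 2, control$teBins,
                                         control$teShuffles, control$seed)
  out["MI0"] <- mutualInformation(r25, t25, 0, control$teBins,
                                  control$teShuffles, control$seed)
  fsD <- pre$fsDown %||% 25
  maxK <- round(fsD)
  miLags <- seq(-maxK, maxK, by = max(1, round(fsD / 5)))
  mis <- vapply(miLags, function(l) mutualInformation(
    r25, t25, l, control$teBins, 5, control$seed), 0)
  out["MImax"] <- max(mis, na.rm = TRUE)
  out["Corr0"] <- stats::cor(r25, t25)
  mc <- maxLaggedCorrelation(r25, t25, fsD, 1)
  out["CorrCoefMax"] <- mc$rMax; out["CorrCoefLag"] <- mc$lagAtMax
  rb <- equalFreqBins(r25, control$teBins)
  tb <- equalFreqBins(t25, control$teBins)
  if (!is.null(rb) && !is.null(tb)) {
    hR <- discreteEntropy(tb); hResp <- discreteEntropy(rb)
    hJ <- discreteEntropy(rb, tb)
    out["EnRR"] <- hR; out["EnResp"] <- hResp; out["JointEn"] <- hJ
    out["CondEnRRGivenResp"] <- hJ - hResp
    out["CondEnRespGivenRR"] <- hJ - hR
  }
  out["CrossSampEn"] <- cpp_cross_sampen(r25, t25, 2L, 0.2)
  out["CrossApEn"] <- cpp_cross_apen(r25, t25, 2L, 0.2)
  logL$flags <- c(l1$flag, l2$flag)
  attr(out, "log") <- logL
  out
}
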