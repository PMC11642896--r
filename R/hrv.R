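## Heart-rate-variability feature battery: time, frequency, Poincare /
## asymmetry / fragmentation, complexity and symbolic-dynamics domains,
## all computed from the beat-wise RR sequence (ms).

#' @useDynLib crcoupling, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

skewness_ <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}
kurtosis_ <- function(x) {
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^4) / s^4 - 3
}

## HRV triangular index and TINN on the standard 1/128 s (7.8125 ms) grid.
triangularMeasures <- function(x) {
  binw <- 1000 / 128
  breaks <- seq(floor(min(x) / binw) * binw, max(x) + binw, by = binw)
  h <- hist(x, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  hti <- length(x) / max(cnt)
  # TINN: least-squares triangular interpolation of the histogram
  peak <- which.max(cnt)
  mids <- h$mids
  best <- Inf; nBest <- mids[1]; mBest <- mids[length(mids)]
  for (i in seq_len(peak)) {
    for (j in seq(peak, length(mids))) {
      tri <- numeric(length(mids))
      if (peak > i)
        tri[i:peak] <- cnt[peak] * (mids[i:peak] - mids[i]) / (mids[peak] - mids[i])
      if (j > peak)
        tri[peak:j] <- cnt[peak] * (mids[j] - mids[peak:j]) / (mids[j] - mids[peak])
      tri[peak] <- cnt[peak]
      err <- sum((cnt - tri)^2)
      if (err < best) { best <- err; nBest <- mids[i]; mBest <- mids[j] }
    }
  }
  c(HTI = hti, TINN = mBest - nBest)
}

#' Time-domain HRV features
#'
#' Standard beat-wise statistics of the RR sequence; RMSSD is the root
#' mean square of successive differences, pNNx the percentage of
#' successive differences exceeding x ms.
#'
#' @param rriSeq RR intervals, ms.
#' @return named numeric vector (36 values); short inputs yield NA entries
#'   rather than errors.
#' @examples
#' hrvTimeFeatures(c(800, 810, 790, 805))[c("MeanNN", "RMSSD")]
#' @export
hrvTimeFeatures <- function(rriSeq) {
  x <- as.numeric(rriSeq)
  nm <- featureManifest()
  nm <- nm$name[nm$category == "time"]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (length(x) < 1) return(out)
  hr <- 60000 / x
  out["MeanNN"] <- mean(x)
  out["MedianNN"] <- median(x)
  out["MinNN"] <- min(x); out["MaxNN"] <- max(x)
  out["RangeNN"] <- max(x) - min(x)
  out["MeanHR"] <- mean(hr); out["MinHR"] <- min(hr); out["MaxHR"] <- max(hr)
  if (length(x) < 2) return(out)
  d <- diff(x)
  out["SDNN"] <- sd(x)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["SDSD"] <- sd(d)
  out["CVNN"] <- out["SDNN"] / out["MeanNN"]
  out["CVSD"] <- out["RMSSD"] / out["MeanNN"]
  out["MadNN"] <- mad(x)
  out["MCVNN"] <- out["MadNN"] / out["MedianNN"]
  out["IQRNN"] <- IQR(x)
  q <- quantile(x, c(.05, .20, .80, .95), names = FALSE)
  out[c("Prc5NN", "Prc20NN", "Prc80NN", "Prc95NN")] <- q
  for (th in c(5, 10, 20, 30, 40, 50))
    out[paste0("pNN", th)] <- 100 * mean(abs(d) > th)
  out["SEMNN"] <- sd(x) / sqrt(length(x))
  out["SDHR"] <- sd(hr)
  out["SDRMSSD"] <- if (out["RMSSD"] > 0) out["SDNN"] / out["RMSSD"] else NA_real_
  out["SkewNN"] <- skewness_(x)
  out["KurtNN"] <- kurtosis_(x)
  out["MeanAbsDiff"] <- mean(abs(d))
  out["MedianAbsDiff"] <- median(abs(d))
  out["IQRDiff"] <- IQR(d)
  if (length(x) >= 20 && sd(x) > 0) {
    tm <- triangularMeasures(x)
    out["HTI"] <- tm["HTI"]; out["TINN"] <- tm["TINN"]
  } else if (sd(x) == 0) {
    out["HTI"] <- 1; out["TINN"] <- 0
  }
  out
}

## Welch power spectral density: Hann-windowed overlapping segments.
welchPSD <- function(x, fs, segS = 120, overlap = 0.5) {
  x <- as.numeric(x) - mean(x)
  nseg <- min(round(segS * fs), length(x))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  U <- sum(w^2)
  nf <- floor(nseg / 2)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)
    p <- (Mod(X[2:(nf + 1)])^2) / (U * fs)
    acc <- acc + 2 * p
  }
  list(freq = seq_len(nf) * fs / nseg, psd = acc / length(starts))
}

bandPower <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (!any(sel)) return(0)
  sum(psd[sel]) * (freq[2] - freq[1])
}

#' Frequency-domain HRV features
#'
#' Welch periodogram (120 s Hann segments, 50% overlap) of the tachogram
#' resampled onto a 4 Hz working grid; band powers are VLF 0.0033-0.04,
#' LF 0.04-0.15, HF 0.15-0.4, VHF 0.4-0.5 Hz. Normalized powers satisfy
#' LFn + HFn = 1.
#'
#' @param tachogram output of [tachogramFromRRI()], or a numeric RR series
#'   (ms) from which a 4 Hz tachogram is built.
#' @param workingFs internal analysis grid, Hz (default 4).
#' @return named numeric vector (14 values); inputs shorter than 120 s are
#'   fully masked.
#' @export
hrvFrequencyFeatures <- function(tachogram, workingFs = 4) {
  nm <- featureManifest()
  nm <- nm$name[nm$category == "frequency"]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (is.numeric(tachogram)) {
    if (length(tachogram) < 4) return(out)
    tachogram <- tachogramFromRRI(tachogram, fsTarget = workingFs)
  }
  dur <- (length(tachogram$values) - 1) / tachogram$fs
  if (dur < 120) return(out)
  vals <- tachogram$values
  if (tachogram$fs != workingFs) {
    grid <- seq(tachogram$times[1], tachogram$times[length(tachogram$times)],
                by = 1 / workingFs)
    vals <- approx(tachogram$times, vals, xout = grid)$y
  }
  ps <- welchPSD(vals, workingFs, segS = 120, overlap = 0.5)
  vlf <- bandPower(ps$freq, ps$psd, 0.0033, 0.04)
  lf <- bandPower(ps$freq, ps$psd, 0.04, 0.15)
  hf <- bandPower(ps$freq, ps$psd, 0.15, 0.4)
  vhf <- bandPower(ps$freq, ps$psd, 0.4, 0.5)
  tp <- bandPower(ps$freq, ps$psd, 0.0033, 0.5)
  out["VLF"] <- vlf; out["LF"] <- lf; out["HF"] <- hf; out["VHF"] <- vhf
  out["TP"] <- tp
  out["LFn"] <- if (lf + hf > 0) lf / (lf + hf) else NA_real_
  out["HFn"] <- if (lf + hf > 0) hf / (lf + hf) else NA_real_
  out["LFHF"] <- if (hf > 0) lf / hf else NA_real_
  out["LnHF"] <- if (hf > 0) log(hf) else NA_real_
  out["VLFrel"] <- if (tp > 0) vlf / tp else NA_real_
  out["LFrel"] <- if (tp > 0) lf / tp else NA_real_
  out["HFrel"] <- if (tp > 0) hf / tp else NA_real_
  selLF <- ps$freq >= 0.04 & ps$freq < 0.15
  selHF <- ps$freq >= 0.15 & ps$freq < 0.4
  out["LFpeak"] <- ps$freq[selLF][which.max(ps$psd[selLF])]
  out["HFpeak"] <- ps$freq[selHF][which.max(ps$psd[selHF])]
  out
}

## Poincare-plot asymmetry (Guzik/Porta family) and fragmentation indices.
poincareFeatures <- function(x) {
  nm <- featureManifest()
  nm <- nm$name[nm$category == "poincare"]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  n <- length(x)
  if (n < 3) return(out)
  d <- diff(x)
  sd1 <- sqrt(var(d) / 2)
  sd2sq <- 2 * var(x) - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  out["SD1"] <- sd1; out["SD2"] <- sd2
  out["SD1SD2"] <- if (sd2 > 0) sd1 / sd2 else NA_real_
  out["EllipseArea"] <- pi * sd1 * sd2
  out["CSI"] <- if (sd1 > 0) sd2 / sd1 else NA_real_
  out["CVI"] <- if (sd1 * sd2 > 0) log10(16 * sd1 * sd2) else NA_real_
  out["CSIMod"] <- if (sd1 > 0) (4 * sd2)^2 / sd1 else NA_real_
  # asymmetry: points (x_i, x_{i+1}); decelerations have x_{i+1} > x_i
  x1 <- x[-n]; x2 <- x[-1]
  dperp <- (x2 - x1) / sqrt(2)          # distance to identity line, signed
  dec <- dperp > 0; acc <- dperp < 0
  if (any(dperp != 0)) {
    out["GI"] <- 100 * sum(abs(dperp[dec])) / sum(abs(dperp))
    th <- atan2(x2, x1) - pi / 4
    out["SI"] <- 100 * sum(abs(th[dec])) / max(sum(abs(th)), .Machine$double.eps)
    r2 <- x1^2 + x2^2
    ar <- 0.5 * r2 * abs(th)
    out["AI"] <- 100 * sum(ar[dec]) / max(sum(ar), .Machine$double.eps)
    out["PI"] <- 100 * sum(acc) / sum(dperp != 0)
    nn <- n - 1
    sd1d <- sqrt(sum(dperp[dec]^2) / nn); sd1a <- sqrt(sum(dperp[acc]^2) / nn)
    dpar <- (x1 + x2 - 2 * mean(x)) / sqrt(2)
    sd2d <- sqrt(sum(dpar[dec]^2) / nn + sum(dpar[dperp == 0]^2) / (2 * nn))
    sd2a <- sqrt(sum(dpar[acc]^2) / nn + sum(dpar[dperp == 0]^2) / (2 * nn))
    out["SD1d"] <- sd1d; out["SD1a"] <- sd1a
    out["SD2d"] <- sd2d; out["SD2a"] <- sd2a
    s1sq <- sd1d^2 + sd1a^2; s2sq <- sd2d^2 + sd2a^2
    out["C1d"] <- if (s1sq > 0) sd1d^2 / s1sq else NA_real_
    out["C1a"] <- if (s1sq > 0) sd1a^2 / s1sq else NA_real_
    out["C2d"] <- if (s2sq > 0) sd2d^2 / s2sq else NA_real_
    out["C2a"] <- if (s2sq > 0) sd2a^2 / s2sq else NA_real_
    sdnnd <- sqrt((sd1d^2 + sd2d^2) / 2); sdnna <- sqrt((sd1a^2 + sd2a^2) / 2)
    out["SDNNd"] <- sdnnd; out["SDNNa"] <- sdnna
    tot <- sdnnd^2 + sdnna^2
    out["Cd"] <- if (tot > 0) sdnnd^2 / tot else NA_real_
    out["Ca"] <- if (tot > 0) sdnna^2 / tot else NA_real_
  }
  # fragmentation (sign structure of successive differences)
  s <- sign(d)
  if (length(s) >= 3) {
    infl <- sum(s[-1] != s[-length(s)] & s[-1] != 0)
    out["PIP"] <- 100 * infl / length(d)
    runs <- rle(s[s != 0])
    if (length(runs$lengths)) {
      out["IALS"] <- 1 / mean(runs$lengths)
      out["PSS"] <- 100 * sum(runs$lengths[runs$lengths < 3]) / sum(runs$lengths)
      alt <- runs$lengths == 1
      ar <- rle(alt)
      altBeats <- sum(ar$lengths[ar$values & ar$lengths >= 4])
      out["PAS"] <- 100 * altBeats / sum(runs$lengths)
    }
  }
  out
}

histEntropy <- function(x, bins = 10, renyiAlpha = NULL) {
  if (sd(x) == 0) return(0)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = bins + 1),
            plot = FALSE)
  p <- h$counts / sum(h$counts); p <- p[p > 0]
  if (is.null(renyiAlpha)) -sum(p * log2(p))
  else log2(sum(p^renyiAlpha)) / (1 - renyiAlpha)
}

permutationEntropy <- function(x, order = 3, weighted = FALSE) {
  n <- length(x) - order + 1
  if (n < 10) return(NA_real_)
  emb <- sapply(seq_len(order), function(k) x[k:(k + n - 1)])
  pat <- apply(emb, 1, function(r) paste(order(r), collapse = ""))
  if (!weighted) {
    p <- table(pat) / n
  } else {
    w <- apply(emb, 1, var)
    if (sum(w) == 0) return(0)
    p <- tapply(w, pat, sum) / sum(w)
  }
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(factorial(order))
}

dfaExponent <- function(x, scales) {
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    nseg <- floor(length(y) / s)
    if (nseg < 2) return(NA_real_)
    f <- vapply(seq_len(nseg), function(k) {
      seg <- y[((k - 1) * s + 1):(k * s)]
      t <- seq_len(s)
      res <- lm.fit(cbind(1, t), seg)$residuals
      mean(res^2)
    }, 0)
    sqrt(mean(f))
  }, 0)
  ok <- is.finite(fl) & fl > 0
  if (sum(ok) < 2) return(NA_real_)
  unname(coef(lm(log(fl[ok]) ~ log(scales[ok])))[2])
}

lempelZiv <- function(bits) {
  n <- length(bits)
  if (n < 10) return(NA_real_)
  s <- paste(bits, collapse = "")
  i <- 1; c <- 0; dict <- new.env(hash = TRUE)
  while (i <= n) {
    j <- i
    repeat {
      sub <- substr(s, i, j)
      if (is.null(dict[[sub]]) || j >= n) {
        dict[[sub]] <- TRUE; c <- c + 1; i <- j + 1; break
      }
      j <- j + 1
    }
  }
  c * log2(n) / n
}

katzFD <- function(x) {
  n <- length(x) - 1
  if (n < 2) return(NA_real_)
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  if (L == 0 || d == 0) return(NA_real_)
  log10(n) / (log10(n) + log10(d / L))
}

## Phase-rectified signal averaging: acceleration/deceleration capacity.
prsaCapacity <- function(x, decelerate = TRUE) {
  n <- length(x)
  if (n < 6) return(NA_real_)
  idx <- which(if (decelerate) x[-1] > x[-n] else x[-1] < x[-n]) + 1L
  idx <- idx[idx >= 3 & idx <= n - 1]
  if (!length(idx)) return(NA_real_)
  mean(vapply(idx, function(i) (x[i] + x[i + 1] - x[i - 1] - x[i - 2]) / 4, 0))
}

#' Nonlinear HRV features
#'
#' Poincare geometry (SD1 = RMSSD/sqrt(2), SD2), heart-rate asymmetry,
#' fragmentation, entropies (approximate, sample, fuzzy, permutation,
#' histogram Shannon/Renyi, multiscale), detrended fluctuation exponents,
#' Lempel-Ziv complexity, Katz fractal dimension and phase-rectified
#' acceleration/deceleration capacity.
#'
#' @param rriSeq RR intervals, ms.
#' @param minBeatsEntropy entropy/DFA features are masked below this length
#'   (default 100 beats).
#' @return named numeric vector (46 values: 27 Poincare + 19 complexity).
#' @export
hrvNonlinearFeatures <- function(rriSeq, minBeatsEntropy = 100) {
  x <- as.numeric(rriSeq)
  m <- featureManifest()
  cnm <- m$name[m$category == "complexity"]
  out <- c(poincareFeatures(x), setNames(rep(NA_real_, length(cnm)), cnm))
  if (length(x) >= minBeatsEntropy && sd(x) > 0) {
    r <- 0.2 * sd(x)
    out["ApEn"] <- cpp_apen(x, 2L, r)
    out["SampEn"] <- cpp_sampen(x, 2L, r)
    out["FuzzyEn"] <- cpp_fuzzyen(x, 2L, r)
    out["ShanEn"] <- histEntropy(x, 10)
    out["RenyiEn"] <- histEntropy(x, 10, renyiAlpha = 2)
    out["PermEn"] <- permutationEntropy(x, 3)
    out["WPermEn"] <- permutationEntropy(x, 3, weighted = TRUE)
    for (sc in 1:6) {
      xs <- if (sc == 1) x else {
        nseg <- floor(length(x) / sc)
        colMeans(matrix(x[seq_len(nseg * sc)], nrow = sc))
      }
      out[paste0("MSE", sc)] <- if (length(xs) >= 30)
        cpp_sampen(xs, 2L, r) else NA_real_
    }
    out["DFAalpha1"] <- dfaExponent(x, 4:16)
    out["DFAalpha2"] <- if (length(x) >= 150)
      dfaExponent(x, seq(16, 64, by = 4)) else NA_real_
    out["LZC"] <- lempelZiv(as.integer(diff(x) > 0))
    out["KFD"] <- katzFD(x)
    out["AC"] <- prsaCapacity(x, decelerate = FALSE)
    out["DC"] <- prsaCapacity(x, decelerate = TRUE)
  } else if (sd(x) == 0 && length(x) >= 10) {
    out[c("ShanEn", "RenyiEn", "PermEn", "WPermEn")] <- 0
  }
  out
}

#' Symbolic-dynamics HRV features
#'
#' RR intervals are quantized into 6 equal-width bins spanning mean +/- 2
#' SD (values outside are clamped into the edge bins); consecutive
#' 3-symbol words are classified by their number and pattern of
#' variations: 0V (no variation), 1V (one variation), 2LV (two like
#' variations, monotone), 2UV (two unlike variations). Percentages sum to
#' 100; word-distribution Shannon and Renyi entropies are appended.
#'
#' @param rriSeq RR intervals, ms (>= 10 beats).
#' @return named numeric vector (6 values).
#' @export
symbolicDynamicsFeatures <- function(rriSeq) {
  x <- as.numeric(rriSeq)
  nmv <- c("Sym0V", "Sym1V", "Sym2LV", "Sym2UV", "SymShanEn", "SymRenyiEn")
  out <- setNames(rep(NA_real_, 6), nmv)
  if (length(x) < 10) return(out)
  mu <- mean(x); s <- sd(x)
  if (s == 0) {
    out[] <- c(100, 0, 0, 0, 0, 0)
    return(out)
  }
  br <- seq(mu - 2 * s, mu + 2 * s, length.out = 7)
  sym <- findInterval(x, br, all.inside = TRUE) - 1L  # 0..5
  n <- length(sym) - 2L
  w1 <- sym[1:n]; w2 <- sym[2:(n + 1)]; w3 <- sym[3:(n + 2)]
  d1 <- w2 - w1; d2 <- w3 - w2
  cls <- ifelse(d1 == 0 & d2 == 0, "0V",
         ifelse(d1 == 0 | d2 == 0, "1V",
         ifelse(sign(d1) == sign(d2), "2LV", "2UV")))
  tab <- table(factor(cls, levels = c("0V", "1V", "2LV", "2UV")))
  out[1:4] <- 100 * as.numeric(tab) / n
  words <- paste(w1, w2, w3)
  p <- table(words) / n
  out["SymShanEn"] <- -sum(p * log2(p))
  out["SymRenyiEn"] <- -log2(sum(p^2))
  out
}

#' All 102 cardiac features from an RR sequence
#'
#' @param rriSeq RR intervals, ms.
#' @return named numeric vector of the manifest's 102 cardiac features.
#' @export
cardiacFeatures <- function(rriSeq) {
  c(hrvTimeFeatures(rriSeq),
    hrvFrequencyFeatures(as.numeric(rriSeq)),
    hrvNonlinearFeatures(rriSeq),
    symbolicDynamicsFeatures(rriSeq))
}
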