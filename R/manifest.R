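#' The normative 157-feature manifest
#'
#' Returns the pinned list of all features the extractor computes: 5
#' demographic, 102 cardiac (time, frequency, Poincare/asymmetry/
#' fragmentation, complexity, symbolic-dynamics HRV), 18 respiratory and 32
#' causal/information-domain features. Each entry records which input
#' variant it consumes: the beat-wise RR sequence (\code{rri}), the 250 Hz
#' or 25 Hz interpolated tachogram, the 250/25 Hz filtered respiration, or
#' the signal \code{pair}.
#'
#' @return data.frame with columns \code{name}, \code{domain}
#'   (demographic | cardiac | respiratory | causal_information),
#'   \code{category}, \code{variant}, \code{description}.
#' @examples
#' m <- featureManifest()
#' table(m$domain)
#' @export
featureManifest <- function() {
  e <- function(name, domain, category, variant, description)
    data.frame(name = name, domain = domain, category = category,
               variant = variant, description = description,
               stringsAsFactors = FALSE)
  rows <- list(
    e("Age",    "demographic", "demographic", "meta", "age, years"),
    e("Sex",    "demographic", "demographic", "meta", "sex, 1 = male, 0 = female"),
    e("Height", "demographic", "demographic", "meta", "height, cm"),
    e("Weight", "demographic", "demographic", "meta", "body mass, kg"),
    e("BMI",    "demographic", "demographic", "meta", "body mass index, kg/m^2")
  )
  tfeat <- c(
    MeanNN = "mean RR interval, ms", SDNN = "SD of RR intervals, ms",
    RMSSD = "root mean square of successive differences, ms",
    SDSD = "SD of successive differences, ms",
    CVNN = "SDNN/MeanNN", CVSD = "RMSSD/MeanNN",
    MedianNN = "median RR, ms", MadNN = "median absolute deviation of RR, ms",
    MCVNN = "MadNN/MedianNN", IQRNN = "interquartile range of RR, ms",
    Prc5NN = "5th percentile of RR, ms", Prc20NN = "20th percentile of RR, ms",
    Prc80NN = "80th percentile of RR, ms", Prc95NN = "95th percentile of RR, ms",
    pNN5 = "% successive differences > 5 ms", pNN10 = "% > 10 ms",
    pNN20 = "% > 20 ms", pNN30 = "% > 30 ms", pNN40 = "% > 40 ms",
    pNN50 = "% > 50 ms",
    MinNN = "minimum RR, ms", MaxNN = "maximum RR, ms",
    RangeNN = "RR range, ms", SEMNN = "standard error of mean RR, ms",
    HTI = "HRV triangular index (n / modal bin count, 7.8125 ms bins)",
    TINN = "triangular interpolation of the NN histogram, ms",
    MeanHR = "mean heart rate, beats/min", SDHR = "SD of heart rate, beats/min",
    MinHR = "minimum heart rate", MaxHR = "maximum heart rate",
    SDRMSSD = "SDNN/RMSSD", SkewNN = "skewness of RR",
    KurtNN = "excess kurtosis of RR",
    MeanAbsDiff = "mean |successive difference|, ms",
    MedianAbsDiff = "median |successive difference|, ms",
    IQRDiff = "IQR of successive differences, ms")
  for (n in names(tfeat))
    rows[[length(rows) + 1L]] <- e(n, "cardiac", "time", "rri", tfeat[[n]])
  ffeat <- c(
    VLF = "very-low-frequency power 0.0033-0.04 Hz, ms^2",
    LF = "low-frequency power 0.04-0.15 Hz, ms^2",
    HF = "high-frequency power 0.15-0.4 Hz, ms^2",
    VHF = "very-high-frequency power 0.4-0.5 Hz, ms^2",
    TP = "total power 0.0033-0.5 Hz, ms^2",
    LFn = "LF/(LF+HF)", HFn = "HF/(LF+HF)", LFHF = "LF/HF ratio",
    LnHF = "log HF power", VLFrel = "VLF/TP", LFrel = "LF/TP",
    HFrel = "HF/TP", LFpeak = "peak frequency in LF band, Hz",
    HFpeak = "peak frequency in HF band, Hz")
  for (n in names(ffeat))
    rows[[length(rows) + 1L]] <- e(n, "cardiac", "frequency", "rri", ffeat[[n]])
  pfeat <- c(
    SD1 = "Poincare short-axis SD, ms", SD2 = "Poincare long-axis SD, ms",
    SD1SD2 = "SD1/SD2", EllipseArea = "pi*SD1*SD2, ms^2",
    CSI = "cardiac sympathetic index SD2/SD1",
    CVI = "cardiac vagal index log10(16*SD1*SD2)",
    CSIMod = "modified CSI (4*SD2)^2/SD1",
    GI = "Guzik asymmetry index, %", SI = "slope asymmetry index, %",
    AI = "area asymmetry index, %", PI = "Porta asymmetry index, %",
    C1d = "short-term decelerating contribution", C1a = "short-term accelerating contribution",
    SD1d = "short-term SD of decelerations, ms", SD1a = "short-term SD of accelerations, ms",
    C2d = "long-term decelerating contribution", C2a = "long-term accelerating contribution",
    SD2d = "long-term SD of decelerations, ms", SD2a = "long-term SD of accelerations, ms",
    Cd = "total decelerating contribution", Ca = "total accelerating contribution",
    SDNNd = "total variability of decelerations, ms", SDNNa = "total variability of accelerations, ms",
    PIP = "% inflection points", IALS = "inverse average acceleration/deceleration segment length",
    PSS = "% short (<3 beat) monotone segments", PAS = "% beats in alternation segments >= 4")
  for (n in names(pfeat))
    rows[[length(rows) + 1L]] <- e(n, "cardiac", "poincare", "rri", pfeat[[n]])
  cfeat <- c(
    ApEn = "approximate entropy, m=2, r=0.2*SDNN",
    SampEn = "sample entropy, m=2, r=0.2*SDNN",
    FuzzyEn = "fuzzy entropy, m=2, r=0.2*SDNN",
    ShanEn = "Shannon entropy of the RR histogram (10 bins), bits",
    PermEn = "permutation entropy, order 3, normalized",
    WPermEn = "weighted permutation entropy, order 3, normalized",
    RenyiEn = "Renyi entropy (alpha=2) of the RR histogram, bits",
    MSE1 = "multiscale sample entropy, scale 1", MSE2 = "scale 2",
    MSE3 = "scale 3", MSE4 = "scale 4", MSE5 = "scale 5", MSE6 = "scale 6",
    DFAalpha1 = "detrended fluctuation short-range exponent (4-16 beats)",
    DFAalpha2 = "detrended fluctuation long-range exponent (16-64 beats)",
    LZC = "Lempel-Ziv complexity of the binarized difference series",
    KFD = "Katz fractal dimension",
    AC = "acceleration capacity (PRSA), ms", DC = "deceleration capacity (PRSA), ms")
  for (n in names(cfeat))
    rows[[length(rows) + 1L]] <- e(n, "cardiac", "complexity", "rri", cfeat[[n]])
  sfeat <- c(
    Sym0V = "% 3-beat words with no variation", Sym1V = "% words with one variation",
    Sym2LV = "% words with two like variations", Sym2UV = "% words with two unlike variations",
    SymShanEn = "Shannon entropy of the word distribution, bits",
    SymRenyiEn = "Renyi entropy (alpha=2) of the word distribution, bits")
  for (n in names(sfeat))
    rows[[length(rows) + 1L]] <- e(n, "cardiac", "symbolic", "rri", sfeat[[n]])
  rfeat <- c(
    RespRateMean = "breaths per minute (60/mean breath duration)",
    RespRateSD = "SD of per-breath instantaneous rate, breaths/min",
    RespRateCV = "CV of per-breath instantaneous rate",
    BreathDurMean = "mean breath duration, s", BreathDurSD = "SD, s",
    BreathDurCV = "CV of breath duration", BreathDurMedian = "median, s",
    BreathDurIQR = "IQR, s",
    InspDurMean = "mean inspiration duration, s", InspDurSD = "SD, s",
    ExpDurMean = "mean expiration duration, s", ExpDurSD = "SD, s",
    IERatioMean = "mean inspiration:expiration ratio", IERatioSD = "SD",
    IERatioMedian = "median inspiration:expiration ratio",
    RelTVMean = "mean relative tidal volume (amplitude / median amplitude)",
    RelTVSD = "SD of relative tidal volume",
    RelTVCV = "CV of relative tidal volume")
  for (n in names(rfeat))
    rows[[length(rows) + 1L]] <- e(n, "respiratory", "respiratory", "resp250", rfeat[[n]])
  ci <- function(name, variant, description)
    e(name, "causal_information", "causal_information", variant, description)
  rows <- c(rows, list(
    ci("GC_RespToRR", "pair25", "linear Granger causality Resp->RR, ln residual-variance ratio"),
    ci("GC_RRToResp", "pair25", "linear Granger causality RR->Resp"),
    ci("GCbeat_RespToRR", "beat", "linear GC Resp->RR on the beat-aligned pair (RR_n vs respiration at beat times)"),
    ci("GCbeat_RRToResp", "beat", "linear GC RR->Resp on the beat-aligned pair"),
    ci("GCRatio", "pair25", "GC(Resp->RR)/GC(RR->Resp)"),
    ci("KGC_RespToRR", "pair25", "kernel (Gaussian RBF) Granger causality Resp->RR"),
    ci("KGC_RRToResp", "pair25", "kernel Granger causality RR->Resp"),
    ci("KGCRatio", "pair25", "KGC(Resp->RR)/KGC(RR->Resp)"),
    ci("LsNGC_F_RespToRR", "pair25", "large-scale nonlinear GC F-statistic Resp->RR"),
    ci("LsNGC_F_RRToResp", "pair25", "lsNGC F-statistic RR->Resp"),
    ci("LsNGC_Aff_RespToRR", "pair25", "lsNGC affinity (RSS reduction share) Resp->RR"),
    ci("LsNGC_Aff_RRToResp", "pair25", "lsNGC affinity RR->Resp"),
    ci("MLGCmlp_RespToRR", "pair25", "ML Granger causality (MLP), ln held-out MSE ratio, Resp->RR"),
    ci("MLGCmlp_RRToResp", "pair25", "ML Granger causality (MLP), RR->Resp"),
    ci("MLGCpoly_RespToRR", "pair25", "ML Granger causality (degree-2 polynomial), Resp->RR"),
    ci("MLGCpoly_RRToResp", "pair25", "ML Granger causality (polynomial), RR->Resp"),
    ci("TE_RespToRR", "pair25", "transfer entropy Resp->RR, lag 1 analysis sample, bits"),
    ci("TE_RRToResp", "pair25", "transfer entropy RR->Resp, lag 1, bits"),
    ci("TE2_RespToRR", "pair25", "transfer entropy Resp->RR, lag 2 analysis samples, bits"),
    ci("TE2_RRToResp", "pair25", "transfer entropy RR->Resp, lag 2, bits"),
    ci("MI0", "pair25", "mutual information at lag 0, bits"),
    ci("MImax", "pair25", "maximum lagged mutual information within +/-1 s, bits"),
    ci("Corr0", "pair25", "Pearson correlation at lag 0"),
    ci("CorrCoefMax", "pair25", "signed Pearson correlation of largest |r| over lags in [-1, 1] s"),
    ci("CorrCoefLag", "pair25", "lag (s) of the maximal |r|"),
    ci("EnRR", "pair25", "Shannon entropy of the binned tachogram, bits"),
    ci("EnResp", "pair25", "Shannon entropy of the binned respiration, bits"),
    ci("JointEn", "pair25", "joint entropy of the binned pair, bits"),
    ci("CondEnRRGivenResp", "pair25", "conditional entropy H(RR|Resp), bits"),
    ci("CondEnRespGivenRR", "pair25", "conditional entropy H(Resp|RR), bits"),
    ci("CrossSampEn", "pair25", "cross-sample entropy, m=2, r=0.2 (standardized)"),
    ci("CrossApEn", "pair25", "cross-approximate entropy, m=2, r=0.2 (standardized)")
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$name), nrow(out) == 157L)
  out
}

#' Feature-manifest domain counts
#'
#' Convenience summary used in validity checks: the extractor must emit 5
#' demographic, 102 cardiac, 18 respiratory and 32 causal/information
#' features.
#' @return named integer vector.
#' @export
manifestCounts <- function() {
  m <- featureManifest()
  counts <- table(factor(m$domain, levels = c(
    "demographic", "cardiac", "respiratory", "causal_information")))
  setNames(as.integer(counts), names(counts))
}
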