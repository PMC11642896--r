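## Signal preprocessing: respiration band-pass, RR stationarity check,
## cubic tachogram interpolation, anti-aliased downsampling.

#' Band-pass filter a respiration waveform
#'
#' Zero-phase (forward-backward) Butterworth band-pass with passband
#' 0.05-0.67 Hz, the frequency equivalents of 3 and 40 breaths per minute.
#' The band-pass is realized as a cascade of a 2nd-order high-pass and a
#' 4th-order low-pass: a direct transfer-function band-pass with a 0.05 Hz
#' corner at 250 Hz sampling is numerically unstable, while the cascade is
#' well conditioned. Zero-phase filtering protects the lag-sensitive
#' coupling features downstream.
#'
#' @param raw numeric waveform.
#' @param fs sampling frequency, Hz; must exceed twice the upper cutoff.
#' @param band passband in Hz (default \code{c(0.05, 0.67)}).
#' @param order low-pass Butterworth order (default 4; the high-pass stage
#'   uses order/2).
#' @return filtered zero-mean waveform.
#' @export
bandpassResp <- function(raw, fs, band = c(0.05, 0.67), order = 4) {
  if (fs <= 2 * band[2]) stop("fs must exceed twice the upper cutoff")
  if (length(raw) < 60 * fs)
    stop("signal shorter than 60 s: too short for a stable filter output")
  hp <- signal::butter(max(order %/% 2, 1), band[1] * 2 / fs, type = "high")
  lp <- signal::butter(order, band[2] * 2 / fs, type = "low")
  y <- signal::filtfilt(hp, as.numeric(raw))
  as.numeric(signal::filtfilt(lp, y))
}

#' Phillips-Perron stationarity check for an RR series
#'
#' Runs the Phillips-Perron unit-root test; rejection (p < alpha) is taken
#' as evidence of stationarity. The result is advisory (logged, not fatal).
#' A constant series is reported stationary with a degenerate-input flag.
#'
#' @param rriSeq RR intervals, ms (>= 50 beats).
#' @param alpha significance level (default 0.05).
#' @param lshort logical, passed to [stats::PP.test()] lag truncation.
#' @return list(statistic, p_value, is_stationary, degenerate).
#' @export
checkStationarity <- function(rriSeq, alpha = 0.05, lshort = TRUE) {
  if (length(rriSeq) < 50) stop("need at least 50 beats")
  if (sd(rriSeq) == 0 || !is.finite(sd(rriSeq)))
    return(list(statistic = NA_real_, p_value = 0, is_stationary = TRUE,
                degenerate = TRUE))
  pp <- PP.test(as.numeric(rriSeq), lshort = lshort)
  list(statistic = unname(pp$statistic), p_value = unname(pp$p.value),
       is_stationary = pp$p.value < alpha, degenerate = FALSE)
}

#' Cubic-interpolated tachogram from RR intervals
#'
#' Interpolates the (beat time, RR) pairs with a cubic spline onto a
#' uniform grid at \code{fsTarget} Hz spanning first to last beat time (no
#' extrapolation), yielding a tachogram with the same sampling as the
#' respiration signal.
#'
#' @param rriSeq RR intervals in ms (>= 4 beats, all positive).
#' @param fsTarget output grid frequency, Hz.
#' @return list(values, times, fs, sourceRRI).
#' @export
tachogramFromRRI <- function(rriSeq, fsTarget = 250) {
  rriSeq <- as.numeric(rriSeq)
  if (length(rriSeq) < 4) stop("cubic interpolation needs at least 4 beats")
  if (any(rriSeq <= 0)) stop("RR intervals must be positive")
  beatT <- cumsum(rriSeq) / 1000
  grid <- seq(beatT[1], beatT[length(beatT)], by = 1 / fsTarget)
  vals <- spline(beatT, rriSeq, xout = grid, method = "fmm")$y
  list(values = vals, times = grid, fs = fsTarget, sourceRRI = rriSeq)
}

#' Anti-aliased downsampling
#'
#' Low-pass (8th-order Chebyshev via [signal::decimate()]) then decimate,
#' reducing e.g. 250 Hz signals to 25 Hz for the causal/information
#' features.
#'
#' @param x waveform.
#' @param factor integer decimation factor (default 10).
#' @return waveform of \code{ceiling(length(x)/factor)} samples.
#' @export
downsampleSignal <- function(x, factor = 10) {
  x <- as.numeric(x)
  if (length(x) < factor) stop("signal shorter than the decimation factor")
  m <- mean(x)   # remove the mean so DC passes through exactly
  as.numeric(signal::decimate(x - m, factor, ftype = "iir")) + m
}

#' Preprocess a recording into analysis-ready signals
#'
#' Applies the full preprocessing chain: respiration band-pass (0.05-0.67
#' Hz), Phillips-Perron stationarity check on the RR series, cubic
#' tachogram interpolation at the respiration sampling rate, and 25 Hz
#' downsampled variants of both signals for the causal/information
#' features. The 250 Hz pair is truncated to the common overlap of the
#' tachogram support and the respiration record.
#'
#' @param rec a \linkS4class{CRRecording}.
#' @param fsDown downsampled rate, Hz (default 25).
#' @return list(respFiltered, tachogram, resp25, tach25, fs, fsDown,
#'   stationarity).
#' @export
preprocessRecording <- function(rec, fsDown = 25) {
  fs <- samplingRate(rec)
  respF <- bandpassResp(resp(rec), fs)
  st <- checkStationarity(rri(rec))
  tg <- tachogramFromRRI(rri(rec), fsTarget = fs)
  i0 <- floor(tg$times[1] * fs) + 1L
  nCommon <- min(length(tg$values), length(respF) - i0 + 1L)
  respAligned <- respF[seq(i0, length.out = nCommon)]
  tach <- tg$values[seq_len(nCommon)]
  factor <- round(fs / fsDown)
  list(respFiltered = respF, tachogram = tg,
       respAligned = respAligned, tachAligned = tach,
       resp25 = downsampleSignal(respAligned, factor),
       tach25 = downsampleSignal(tach, factor),
       fs = fs, fsDown = fsDown, stationarity = st)
}
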