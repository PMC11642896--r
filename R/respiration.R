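## Respiration waveform analysis: breath segmentation and the 18
## respiratory features (rate, timing, relative tidal volume).

#' Detect breaths in a band-passed respiration waveform
#'
#' Alternating trough-peak-trough segmentation. Local extrema are found on
#' a lightly smoothed copy of the signal, forced to alternate (of two
#' consecutive same-type extrema the more extreme one is kept), and breaths
#' shorter than the duration floor (default 60/40 s, the upper edge of the
#' respiration band) or smaller than \code{ampFrac} x the median amplitude
#' are merged away.
#'
#' @param respF band-pass filtered waveform.
#' @param fs sampling frequency, Hz.
#' @param minDurationS minimum breath duration, s (default 1.5 = 60/40).
#' @param ampFrac amplitude threshold as a fraction of the median breath
#'   amplitude (default 0.1).
#' @param smoothS moving-average smoothing window for extremum detection, s.
#' @return data.frame with columns \code{onset}, \code{peak}, \code{end}
#'   (times, s), \code{inspDur}, \code{expDur}, \code{duration} (s),
#'   \code{amplitude}; zero rows (with attribute \code{flag = "no_breaths"})
#'   when nothing is detected.
#' @export
detectBreaths <- function(respF, fs, minDurationS = 60 / 40, ampFrac = 0.1,
                          smoothS = 0.2) {
  x <- as.numeric(respF)
  n <- length(x)
  emptyTab <- function() {
    tab <- data.frame(onset = numeric(0), peak = numeric(0),
                      end = numeric(0), inspDur = numeric(0),
                      expDur = numeric(0), duration = numeric(0),
                      amplitude = numeric(0))
    attr(tab, "flag") <- "no_breaths"
    tab
  }
  if (n < fs * 4 || sd(x) == 0) return(emptyTab())
  w <- max(1L, as.integer(round(smoothS * fs)))
  xs <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  dd <- sign(diff(xs))
  dd[dd == 0] <- 1
  turns <- which(dd[-1] != dd[-length(dd)]) + 1L
  if (length(turns) < 3) return(emptyTab())
  kind <- ifelse(dd[turns] == -1, "peak", "trough")  # slope after the turn
  # refine each extremum on the raw signal within the smoothing window
  loc <- vapply(seq_along(turns), function(i) {
    a <- max(1L, turns[i] - w); b <- min(n, turns[i] + w)
    if (kind[i] == "peak") a - 1L + which.max(x[a:b]) else a - 1L + which.min(x[a:b])
  }, integer(1))
  # enforce alternation
  keep <- rep(TRUE, length(loc))
  last <- 1L
  for (i in seq_along(loc)[-1]) {
    if (kind[i] == kind[last]) {
      better <- if (kind[i] == "peak") x[loc[i]] > x[loc[last]]
                else x[loc[i]] < x[loc[last]]
      if (better) { keep[last] <- FALSE; last <- i } else keep[i] <- FALSE
    } else last <- i
  }
  loc <- loc[keep]; kind <- kind[keep]
  tr <- which(kind == "trough")
  rows <- list()
  for (k in seq_len(length(tr) - 1)) {
    i1 <- tr[k]; i2 <- tr[k + 1]
    if (i2 != i1 + 2L) next              # must be trough-peak-trough
    pk <- i1 + 1L
    onset <- (loc[i1] - 1) / fs; pkT <- (loc[pk] - 1) / fs
    endT <- (loc[i2] - 1) / fs
    amp <- x[loc[pk]] - (x[loc[i1]] + x[loc[i2]]) / 2
    rows[[length(rows) + 1L]] <- data.frame(
      onset = onset, peak = pkT, end = endT, inspDur = pkT - onset,
      expDur = endT - pkT, duration = endT - onset, amplitude = amp)
  }
  if (!length(rows)) return(emptyTab())
  tab <- do.call(rbind, rows)
  medAmp <- median(tab$amplitude)
  tab <- tab[tab$duration >= minDurationS & tab$amplitude >= ampFrac * medAmp, ,
             drop = FALSE]
  rownames(tab) <- NULL
  if (!nrow(tab)) return(emptyTab())
  tab
}

#' Respiratory features from a breath table
#'
#' The 18 respiratory features: respiratory rate (60 / mean breath
#' duration) and per-breath rate spread, breath/inspiration/expiration
#' duration statistics, inspiration:expiration ratio statistics, and
#' relative tidal volume (each breath's amplitude indexed by the median
#' amplitude, so the median relative TV is 1 by construction).
#'
#' @param breaths breath table from [detectBreaths()].
#' @return named numeric vector (18 values); fewer than 2 breaths gives a
#'   fully masked vector.
#' @export
respiratoryFeatures <- function(breaths) {
  m <- featureManifest()
  nm <- m$name[m$domain == "respiratory"]
  out <- setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(breaths) || nrow(breaths) < 2) return(out)
  dur <- breaths$duration
  rate <- 60 / dur
  relTV <- breaths$amplitude / median(breaths$amplitude)
  ie <- breaths$inspDur / breaths$expDur
  out["RespRateMean"] <- 60 / mean(dur)
  out["RespRateSD"] <- sd(rate)
  out["RespRateCV"] <- sd(rate) / mean(rate)
  out["BreathDurMean"] <- mean(dur)
  out["BreathDurSD"] <- sd(dur)
  out["BreathDurCV"] <- sd(dur) / mean(dur)
  out["BreathDurMedian"] <- median(dur)
  out["BreathDurIQR"] <- IQR(dur)
  out["InspDurMean"] <- mean(breaths$inspDur)
  out["InspDurSD"] <- sd(breaths$inspDur)
  out["ExpDurMean"] <- mean(breaths$expDur)
  out["ExpDurSD"] <- sd(breaths$expDur)
  out["IERatioMean"] <- mean(ie)
  out["IERatioSD"] <- sd(ie)
  out["IERatioMedian"] <- median(ie)
  out["RelTVMean"] <- mean(relTV)
  out["RelTVSD"] <- sd(relTV)
  out["RelTVCV"] <- sd(relTV) / mean(relTV)
  out
}
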