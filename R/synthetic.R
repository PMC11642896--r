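## Synthetic coupled cardiorespiratory cohort generator.
##
## The generator emulates >= 5-minute supine recordings: a quasi-periodic
## respiration waveform (relative tidal volume, arbitrary units) and an RR
## interval sequence whose variability is split between an intrinsic AR(1)
## component and a lagged respiratory component (respiratory sinus
## arrhythmia), with the respiratory variance share — the coupling strength
## — a controllable parameter.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    set.seed(seed)
  }
  force(expr)
}

## Truncated-normal sampler whose *truncated* mean equals targetMean:
## the pre-truncation location is solved so that asymmetric ranges do not
## bias cohort means away from the printed targets. Subject-level draws
## use randomized stratified (inverse-CDF) sampling: the marginal stays the
## truncated normal, but the cohort mean concentrates at the target with
## O(1/n) instead of O(1/sqrt(n)) error, so group descriptive statistics
## are recovered reliably at cohort sizes.
rtruncnormCalibrated <- function(n, targetMean, sd, range,
                                 stratified = TRUE) {
  lo <- range[1]; hi <- range[2]
  if (sd <= 0) return(rep(targetMean, n))
  truncMean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    mu + sd * (dnorm(a) - dnorm(b)) / z
  }
  mu <- tryCatch(
    uniroot(function(m) truncMean(m) - targetMean,
            lower = lo, upper = hi, extendInt = "yes", tol = 1e-8)$root,
    error = function(e) targetMean)
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  u <- if (stratified) (sample.int(n) - runif(n)) / n else runif(n)
  u <- pnorm(a) + u * (pnorm(b) - pnorm(a))
  mu + sd * qnorm(u)
}

#' Generate a synthetic respiration waveform
#'
#' Builds a quasi-periodic zero-mean relative tidal-volume signal, breath by
#' breath: each breath's instantaneous rate is drawn from a truncated normal
#' (3-40 breaths/min, inside the 0.05-0.67 Hz respiration passband), its
#' amplitude is jittered, and inspiration/expiration durations follow the
#' preset inspiration:expiration ratio. Each breath rises from a trough to
#' its peak along a half-cosine and falls to the next trough likewise.
#'
#' The preset's respiratory-rate SD describes the spread *across* subjects
#' (it comes from group descriptive statistics); the breath-to-breath
#' jitter within a recording is \code{breathJitterFrac} of it (default 0.6,
#' about a 12% within-recording CV at the default presets; resting
#' breath-to-breath variability is typically 10-25% CV). Drawing per-breath
#' rates at the full between-subject SD would both overdisperse the
#' waveform and bias the detected rate (60 / mean breath duration is a
#' harmonic-type mean) several percent below the target.
#'
#' @param preset a \linkS4class{GroupPreset}.
#' @param durationS recording length in seconds (>= 300).
#' @param fs sampling frequency, Hz.
#' @param seed integer seed (reproducible output).
#' @param amplitudeJitter SD of the multiplicative per-breath amplitude
#'   jitter (default 0.15).
#' @param subjectRate this subject's mean rate, breaths/min (default: the
#'   preset mean; [generateCohort()] draws it per subject).
#' @param breathJitterFrac within-recording per-breath rate SD as a
#'   fraction of the preset SD (default 0.6).
#' @return numeric waveform of \code{durationS * fs} samples with attribute
#'   \code{"breathOnsets"} (trough times, s).
#' @export
generateRespiration <- function(preset, durationS = 300, fs = 250,
                                seed = NULL, amplitudeJitter = 0.15,
                                subjectRate = preset@respRateMean,
                                breathJitterFrac = 0.6) {
  if (durationS < 300) stop("durationS must be >= 300 s")
  if (fs <= 2 * subjectRate / 60) stop("fs too low for the requested rate")
  if (subjectRate < 3 || subjectRate > 40)
    stop("respiratory rate outside [3, 40] breaths/min")
  withSeed(seed, {
    nMax <- ceiling(durationS / (60 / subjectRate) * 2) + 20
    rate <- rnorm(nMax, subjectRate, breathJitterFrac * preset@respRateSd)
    rate <- pmin(pmax(rate, 3), 40)
    dur <- 60 / rate
    onsets <- cumsum(c(0, dur))
    nBr <- which(onsets >= durationS)[1] - 1L
    if (is.na(nBr)) nBr <- nMax
    dur <- dur[seq_len(nBr)]
    amp <- pmax(1 + amplitudeJitter * rnorm(nBr), 0.2)
    ie <- preset@ieRatio
    insp <- dur * ie / (1 + ie)
    expn <- dur - insp
    n <- round(durationS * fs)
    tOn <- cumsum(c(0, dur))[seq_len(nBr)]
    x <- numeric(n)
    ampNext <- c(amp[-1], amp[nBr])
    for (i in seq_len(nBr)) {
      i0 <- floor(tOn[i] * fs) + 1L
      iPk <- min(floor((tOn[i] + insp[i]) * fs), n)
      i1 <- min(floor((tOn[i] + dur[i]) * fs), n)
      if (i0 > n) break
      if (iPk >= i0) {
        tt <- (seq(i0, iPk) - 1) / fs - tOn[i]
        x[i0:iPk] <- -amp[i] + amp[i] * (1 - cos(pi * tt / insp[i]))
      }
      if (i1 > iPk) {
        tt <- (seq(iPk + 1L, i1) - 1) / fs - (tOn[i] + insp[i])
        x[(iPk + 1L):i1] <- -ampNext[i] +
          (amp[i] + ampNext[i]) * (1 + cos(pi * tt / expn[i])) / 2
      }
    }
    x <- x - mean(x)
    attr(x, "breathOnsets") <- tOn
    x
  })
}

#' Calibrate RR-generator scales for a preset
#'
#' The RR model is \eqn{RR_n = \mu + a v_n + g r(t_n - lag)} with \eqn{v}
#' a unit-variance AR(1) process and \eqn{r} the unit-variance respiration
#' value at the (lagged) beat time. Writing \eqn{c} for the coupling
#' strength (respiratory variance share) and \eqn{T} for the total RR
#' variance, \eqn{g^2 = cT} and \eqn{a^2 = (1-c)T}; \eqn{T} follows from
#' the RMSSD target via
#' \deqn{RMSSD^2 = 2T[(1-c)(1-\phi) + c(1-\rho)]}
#' where \eqn{\rho} is the respiration autocorrelation at one mean RR
#' interval, estimated from pilot waveforms. A pilot Monte-Carlo run then
#' multiplies both scales by a single correction factor so the realized
#' mean RMSSD matches the target.
#'
#' @param preset a \linkS4class{GroupPreset}.
#' @param nPilot number of pilot recordings (>= 100).
#' @param seed integer seed.
#' @param durationS pilot recording length, s.
#' @return list with \code{a}, \code{g}, \code{rho}, \code{correction},
#'   \code{achievedRMSSD}, \code{achievedShare}, \code{converged}.
#' @export
calibratePreset <- function(preset, nPilot = 100, seed = 1, durationS = 300) {
  if (nPilot < 100) stop("nPilot must be >= 100")
  withSeed(seed, {
    rho0 <- NULL; aRep <- gRep <- NA_real_
    pil <- replicate(nPilot, {
      resp <- generateRespiration(preset, durationS, 250,
                                  seed = sample.int(1e9, 1))
      rho <- respAutocorAtRR(resp, 250, preset@hrMean)
      if (is.null(rho0)) rho0 <<- rho
      sc <- analyticScales(preset@rmssdTarget, preset@couplingStrength,
                           preset@arPhi, rho)
      if (is.na(aRep)) { aRep <<- sc$a; gRep <<- sc$g }
      r <- simulateRRI(resp, 250, 60000 / preset@hrMean, sc$a, sc$g,
                       preset@arPhi, preset@couplingLag, durationS,
                       seed = sample.int(1e9, 1))
      c(rmssd = sqrt(mean(diff(r$rri)^2)), shareNum = sc$g^2 * r$varR,
        shareDen = sc$a^2 * r$varV + sc$g^2 * r$varR)
    })
    achieved <- mean(pil["rmssd", ])
    corr <- if (achieved > 0) preset@rmssdTarget / achieved else 1
    share <- mean(pil["shareNum", ] / pmax(pil["shareDen", ], 1e-12))
    converged <- abs(achieved * corr / preset@rmssdTarget - 1) < 0.05 &&
      abs(share - preset@couplingStrength) < 0.05
    if (!converged)
      warning(sprintf(
        "calibration did not converge: achieved RMSSD %.2f (target %.2f), share %.3f (target %.3f)",
        achieved * corr, preset@rmssdTarget, share, preset@couplingStrength))
    list(a = aRep * corr, g = gRep * corr, rho = rho0, correction = corr,
         achievedRMSSD = achieved * corr, achievedShare = share,
         converged = converged)
  })
}

## rho: respiration autocorrelation at a lag of one mean RR interval.
respAutocorAtRR <- function(resp, fs, hrMean) {
  k <- max(1L, round(60 / hrMean * fs))
  n <- length(resp)
  stats::cor(resp[1:(n - k)], resp[(k + 1):n])
}

## Solve (a, g) from RMSSD target, coupling share c, AR(1) phi and resp
## autocorrelation rho. v has unit variance so share = g^2/(a^2 + g^2).
analyticScales <- function(rmssd, c, phi, rho) {
  denom <- 2 * ((1 - c) * (1 - phi) + c * (1 - rho))
  if (denom <= 0) stop("calibration failed: non-positive variance budget")
  total <- rmssd^2 / denom
  list(a = sqrt((1 - c) * total), g = sqrt(c * total))
}

## Core RR simulator. Returns rri (ms), beat times (s) and the realized
## component variances (for share audits).
simulateRRI <- function(resp, fs, muRR, a, g, phi, lag, durationS,
                        seed = NULL, minRR = 200) {
  withSeed(seed, {
    r <- as.numeric(resp)
    r <- (r - mean(r)) / sd(r)
    nMax <- ceiling(durationS / (muRR / 1000)) + 60L
    innov <- rnorm(nMax) * sqrt(1 - phi^2)
    v <- as.numeric(stats::filter(innov, phi, method = "recursive"))
    n <- length(r)
    rri <- numeric(nMax); rv <- numeric(nMax)
    t <- 0; i <- 0L
    while (t <= durationS && i < nMax) {
      i <- i + 1L
      tl <- max(t - lag, 0)
      idx <- tl * fs + 1
      i0 <- floor(idx); w <- idx - i0
      i0 <- min(max(i0, 1L), n - 1L)
      rv[i] <- (1 - w) * r[i0] + w * r[i0 + 1L]
      rri[i] <- max(muRR + a * v[i] + g * rv[i], minRR)
      t <- t + rri[i] / 1000
    }
    list(rri = rri[seq_len(i)], beatTimes = cumsum(rri[seq_len(i)]) / 1000,
         varV = var(v[seq_len(i)]), varR = var(rv[seq_len(i)]))
  })
}

#' Generate an RR-interval sequence coupled to a respiration waveform
#'
#' Respiratory sinus arrhythmia mechanism: each RR interval is the sum of a
#' mean interval (60000/heart rate), an intrinsic AR(1) fluctuation, and a
#' lagged respiration term whose variance share equals the preset's
#' coupling strength. With coupling 0 the RR sequence is independent of
#' respiration.
#'
#' @param preset a \linkS4class{GroupPreset}.
#' @param resp respiration waveform (from [generateRespiration()]).
#' @param fs sampling rate of \code{resp}, Hz.
#' @param seed integer seed.
#' @param calibration optional output of [calibratePreset()]; if missing,
#'   analytic scales (no pilot correction) are used.
#' @param hrMean,rmssdTarget optional per-subject overrides of the preset
#'   targets (used by [generateCohort()]).
#' @return numeric RR intervals (ms) with attribute \code{"beatTimes"} (s).
#' @export
generateRRI <- function(preset, resp, fs = 250, seed = NULL,
                        calibration = NULL, hrMean = NULL,
                        rmssdTarget = NULL) {
  if (!length(resp)) stop("resp must be non-empty")
  hr <- hrMean %||% preset@hrMean
  rmssd <- rmssdTarget %||% preset@rmssdTarget
  corr <- if (!is.null(calibration)) calibration$correction else 1
  rho <- respAutocorAtRR(resp, fs, hr)   # subject-specific autocorrelation
  sc <- analyticScales(rmssd, preset@couplingStrength, preset@arPhi, rho)
  if (sc$a < 0 || sc$g < 0)
    stop("calibration cannot reach the RMSSD target with non-negative scales")
  durationS <- length(resp) / fs
  out <- simulateRRI(resp, fs, 60000 / hr, sc$a * corr, sc$g * corr,
                     preset@arPhi, preset@couplingLag, durationS, seed = seed)
  structure(out$rri, beatTimes = out$beatTimes)
}

#' Default group presets (descriptive-statistics calibrated)
#'
#' Heart rate, RMSSD and respiratory-rate targets (mean, SD, range) per
#' group follow the study population's descriptive statistics; the
#' coupling strengths (Cardiac 0.2, Healthy 0.5, Sport 0.7) are synthesis
#' knobs that make the groups separable through their cardiorespiratory
#' coupling alone, not estimates of physiology.
#'
#' @param couplingStrengths named or positional numeric(3) overriding the
#'   default Cardiac/Healthy/Sport coupling strengths.
#' @return named list of three \linkS4class{GroupPreset} objects.
#' @export
defaultPresets <- function(couplingStrengths = c(Cardiac = 0.2,
                                                 Healthy = 0.5,
                                                 Sport = 0.7)) {
  cs <- couplingStrengths
  if (is.null(names(cs))) names(cs) <- c("Cardiac", "Healthy", "Sport")
  list(
    Cardiac = groupPreset("Cardiac",
      hrMean = 72.8, hrSd = 13.3, hrRange = c(56.0, 100.5),
      rmssdTarget = 55.3, rmssdSd = 36.8, rmssdRange = c(9.4, 140.7),
      respRateMean = 18.5, respRateSd = 4.6, respRateRange = c(7.9, 25.4),
      couplingStrength = unname(cs["Cardiac"]),
      demographics = list(maleProb = 20 / 29,
        age = list(mean = 13.1, sd = 3.5, range = c(6, 17)),
        weight = list(mean = 57.1, sd = 21.0, range = c(23.0, 95.0)),
        height = list(mean = 160.4, sd = 17.2, range = c(123, 184)))),
    Healthy = groupPreset("Healthy",
      hrMean = 79.4, hrSd = 10.2, hrRange = c(60.7, 100.5),
      rmssdTarget = 61.8, rmssdSd = 34.4, rmssdRange = c(13.0, 162.3),
      respRateMean = 18.8, respRateSd = 3.5, respRateRange = c(10.7, 28.5),
      couplingStrength = unname(cs["Healthy"]),
      demographics = list(maleProb = 33 / 62,
        age = list(mean = 11.0, sd = 2.2, range = c(7, 15)),
        weight = list(mean = 43.5, sd = 12.1, range = c(21.4, 75.6)),
        height = list(mean = 151.2, sd = 13.1, range = c(123, 183)))),
    Sport = groupPreset("Sport",
      hrMean = 76.9, hrSd = 15.0, hrRange = c(46.7, 121.4),
      rmssdTarget = 68.2, rmssdSd = 46.7, rmssdRange = c(5.6, 178.9),
      respRateMean = 17.1, respRateSd = 3.5, respRateRange = c(10.2, 25.8),
      couplingStrength = unname(cs["Sport"]),
      demographics = list(maleProb = 1.0,
        age = list(mean = 13.3, sd = 1.4, range = c(10, 15)),
        weight = list(mean = 57.2, sd = 13.6, range = c(30.0, 81.8)),
        height = list(mean = 169.4, sd = 12.7, range = c(135, 190))))
  )
}

#' Generate one labeled synthetic recording
#'
#' @param preset a \linkS4class{GroupPreset}.
#' @param durationS recording length, s.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @param calibration optional [calibratePreset()] output.
#' @param subjectTargets optional list(hrMean, rmssdTarget, demographics)
#'   for cohort-level between-subject variation.
#' @return a \linkS4class{CRRecording}.
#' @export
generateRecording <- function(preset, durationS = 300, fs = 250, seed = NULL,
                              calibration = NULL, subjectTargets = NULL) {
  if (!is.null(subjectTargets$arPhi)) {
    preset@arPhi <- subjectTargets$arPhi
    validObject(preset)
  }
  withSeed(seed, {
    resp <- generateRespiration(
      preset, durationS, fs, seed = sample.int(1e9, 1),
      subjectRate = subjectTargets$respRate %||% preset@respRateMean)
    hr <- subjectTargets$hrMean %||% preset@hrMean
    rmssd <- subjectTargets$rmssdTarget %||% preset@rmssdTarget
    rriSeq <- generateRRI(preset, resp, fs, seed = sample.int(1e9, 1),
                          calibration = calibration, hrMean = hr,
                          rmssdTarget = rmssd)
    demo <- subjectTargets$demographics %||% list()
    crRecording(as.numeric(resp), as.numeric(rriSeq), fs = fs,
                demographics = demo, groupLabel = preset@groupLabel,
                meta = list(hrMean = hr, rmssdTarget = rmssd,
                            couplingStrength = preset@couplingStrength,
                            couplingLag = preset@couplingLag,
                            arPhi = preset@arPhi, seed = seed))
  })
}

#' Generate a group-conditioned synthetic cohort
#'
#' Subject-level heart rate, RMSSD and demographics (age, mass, height) are
#' drawn from mean-calibrated truncated normals matched to the group
#' descriptive statistics; sex is Bernoulli with the group's male fraction;
#' BMI is computed from mass and height. Each subject's RR generator is
#' calibrated to the subject's own targets via the preset-level pilot
#' correction.
#'
#' @param presets named list of \linkS4class{GroupPreset} (see
#'   [defaultPresets()]).
#' @param nPerGroup integer vector, one count per preset.
#' @param durationS recording length, s.
#' @param fs sampling rate, Hz.
#' @param seed integer master seed; identical seeds give identical cohorts.
#' @param calibrations optional named list of [calibratePreset()] outputs
#'   (computed if missing; pass precomputed ones to amortize pilots).
#' @param nPilot pilot size for preset calibration.
#' @param arPhiRange optional length-2 range: per-subject intrinsic AR(1)
#'   coefficients are drawn uniformly from it (heterogeneous autonomic
#'   dynamics) instead of using the preset value. NULL keeps the preset
#'   coefficient for every subject.
#' @return a \linkS4class{CRCohort}.
#' @export
generateCohort <- function(presets = defaultPresets(),
                           nPerGroup = c(29, 62, 44),
                           durationS = 300, fs = 250, seed = 1,
                           calibrations = NULL, nPilot = 100,
                           arPhiRange = NULL) {
  stopifnot(length(nPerGroup) == length(presets), all(nPerGroup >= 1))
  if (is.null(calibrations)) {
    calibrations <- lapply(seq_along(presets), function(i)
      calibratePreset(presets[[i]], nPilot = nPilot, seed = seed + i,
                      durationS = durationS))
    names(calibrations) <- names(presets)
  }
  withSeed(seed, {
    recs <- list(); k <- 0L
    for (gi in seq_along(presets)) {
      p <- presets[[gi]]; cal <- calibrations[[gi]]
      n <- nPerGroup[gi]
      hrs <- rtruncnormCalibrated(n, p@hrMean, p@hrSd, p@hrRange)
      rms <- rtruncnormCalibrated(n, p@rmssdTarget, p@rmssdSd, p@rmssdRange)
      rrs <- rtruncnormCalibrated(n, p@respRateMean, p@respRateSd,
                                  p@respRateRange)
      dg <- p@demographics
      ages <- rtruncnormCalibrated(n, dg$age$mean, dg$age$sd, dg$age$range)
      wts <- rtruncnormCalibrated(n, dg$weight$mean, dg$weight$sd, dg$weight$range)
      hts <- rtruncnormCalibrated(n, dg$height$mean, dg$height$sd, dg$height$range)
      male <- rbinom(n, 1, dg$maleProb %||% 0.5)
      phis <- if (is.null(arPhiRange)) rep(p@arPhi, n)
              else runif(n, arPhiRange[1], arPhiRange[2])
      for (j in seq_len(n)) {
        k <- k + 1L
        demo <- list(age = ages[j], sex = if (male[j] == 1) "M" else "F",
                     height_cm = hts[j], weight_kg = wts[j],
                     bmi = wts[j] / (hts[j] / 100)^2)
        recs[[k]] <- generateRecording(
          p, durationS, fs, seed = sample.int(1e9, 1), calibration = cal,
          subjectTargets = list(hrMean = hrs[j], rmssdTarget = rms[j],
                                respRate = rrs[j], arPhi = phis[j],
                                demographics = demo))
      }
    }
    crCohort(recs)
  })
}
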