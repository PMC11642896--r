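#' @import methods
#' @importFrom stats sd median quantile var fft approx spline rnorm runif
#'   rbinom predict coef lm kmeans wilcox.test kruskal.test mad IQR uniroot
#'   dnorm pnorm qnorm optimize setNames aggregate complete.cases PP.test
#'   dist lm.fit .lm.fit
#' @importFrom graphics hist
#' @importFrom utils head tail read.csv write.csv
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Group-conditioned generator preset
#'
#' A \code{GroupPreset} bundles the physiological targets a synthetic
#' recording of one study group has to meet: heart rate, short-term heart
#' rate variability (RMSSD), respiratory rate, inspiration/expiration shape,
#' and the strength and lag of the respiration-to-heart coupling
#' (respiratory sinus arrhythmia). Between-subject demographic
#' distributions (age, body mass, height, sex ratio) ride along in
#' \code{demographics}.
#'
#' @slot groupLabel one of \code{"Cardiac"}, \code{"Healthy"}, \code{"Sport"}.
#' @slot hrMean,hrSd mean/SD of heart rate across subjects, beats/min.
#' @slot hrRange length-2 truncation range for subject heart rate.
#' @slot rmssdTarget target RMSSD (ms); \code{rmssdSd}/\code{rmssdRange}
#'   give the between-subject spread and truncation range.
#' @slot respRateMean,respRateSd per-breath respiratory-rate distribution,
#'   breaths/min; \code{respRateRange} the between-subject truncation range.
#' @slot ieRatio inspiration:expiration duration ratio (dimensionless).
#' @slot couplingStrength fraction of RR-interval variance driven by
#'   respiration, in [0, 1].
#' @slot couplingLag lag (s) between respiration and its effect on RR.
#' @slot arPhi AR(1) coefficient of the intrinsic (non-respiratory) RR
#'   variability.
#' @slot demographics list with \code{maleProb}, and \code{mean}, \code{sd},
#'   \code{range} for \code{age} (years), \code{weight} (kg), \code{height}
#'   (cm).
#' @seealso [defaultPresets()], [generateCohort()]
#' @export
setClass("GroupPreset",
  representation(
    groupLabel = "character",
    hrMean = "numeric", hrSd = "numeric", hrRange = "numeric",
    rmssdTarget = "numeric", rmssdSd = "numeric", rmssdRange = "numeric",
    respRateMean = "numeric", respRateSd = "numeric", respRateRange = "numeric",
    ieRatio = "numeric",
    couplingStrength = "numeric",
    couplingLag = "numeric",
    arPhi = "numeric",
    demographics = "list"
  )
)

setValidity("GroupPreset", function(object) {
  msg <- character()
  if (object@hrMean <= 0) msg <- c(msg, "hrMean must be > 0")
  if (object@rmssdTarget <= 0) msg <- c(msg, "rmssdTarget must be > 0")
  if (object@respRateMean < 3 || object@respRateMean > 40)
    msg <- c(msg, "respRateMean must lie in [3, 40] breaths/min (the respiration passband)")
  if (object@couplingStrength < 0 || object@couplingStrength > 1)
    msg <- c(msg, "couplingStrength must lie in [0, 1]")
  if (object@ieRatio <= 0) msg <- c(msg, "ieRatio must be > 0")
  if (abs(object@arPhi) >= 1) msg <- c(msg, "arPhi must satisfy |arPhi| < 1")
  if (length(msg)) msg else TRUE
})

#' Construct a generator preset
#'
#' @param groupLabel group name ("Cardiac", "Healthy" or "Sport").
#' @param hrMean,hrSd,hrRange heart-rate distribution (beats/min).
#' @param rmssdTarget,rmssdSd,rmssdRange RMSSD distribution (ms).
#' @param respRateMean,respRateSd,respRateRange respiratory rate
#'   (breaths/min).
#' @param ieRatio inspiration:expiration duration ratio.
#' @param couplingStrength fraction of RR variance of respiratory origin,
#'   in [0, 1].
#' @param couplingLag respiration-to-RR lag in seconds.
#' @param arPhi AR(1) coefficient of intrinsic RR variability.
#' @param demographics list(maleProb, age=list(mean, sd, range),
#'   weight=..., height=...).
#' @return a validated \linkS4class{GroupPreset}.
#' @export
groupPreset <- function(groupLabel, hrMean, hrSd = 0, hrRange = c(40, 130),
                        rmssdTarget = 60, rmssdSd = 0,
                        rmssdRange = c(5, 200),
                        respRateMean = 18, respRateSd = 3,
                        respRateRange = c(8, 30),
                        ieRatio = 0.8, couplingStrength = 0.5,
                        couplingLag = 0.4, arPhi = 0.9,
                        demographics = list()) {
  new("GroupPreset",
    groupLabel = groupLabel, hrMean = hrMean, hrSd = hrSd,
    hrRange = hrRange, rmssdTarget = rmssdTarget, rmssdSd = rmssdSd,
    rmssdRange = rmssdRange, respRateMean = respRateMean,
    respRateSd = respRateSd, respRateRange = respRateRange,
    ieRatio = ieRatio, couplingStrength = couplingStrength,
    couplingLag = couplingLag, arPhi = arPhi,
    demographics = demographics)
}

setMethod("show", "GroupPreset", function(object) {
  cat(sprintf(
    "GroupPreset '%s': HR %.1f+/-%.1f bpm, RMSSD %.1f ms, RespRate %.1f+/-%.1f /min, coupling %.2f (lag %.2f s)\n",
    object@groupLabel, object@hrMean, object@hrSd, object@rmssdTarget,
    object@respRateMean, object@respRateSd, object@couplingStrength,
    object@couplingLag))
})

#' A single subject's cardiorespiratory recording
#'
#' Pairs a respiration waveform (relative tidal volume, arbitrary units,
#' sampled at \code{fs} Hz) with the subject's RR-interval sequence (ms),
#' demographic metadata and the 3-class health-status label. Synthetic
#' recordings also carry the generator parameters actually used in
#' \code{meta} so calibration can be audited.
#'
#' @slot resp numeric respiration waveform.
#' @slot rri numeric RR intervals in milliseconds.
#' @slot fs sampling frequency of \code{resp}, Hz (250 by default).
#' @slot demographics list with age (years), sex ("M"/"F"), height_cm,
#'   weight_kg, bmi.
#' @slot groupLabel character group label (may be NA for unlabeled data).
#' @slot meta list of provenance/generator parameters.
#' @export
setClass("CRRecording",
  representation(
    resp = "numeric", rri = "numeric", fs = "numeric",
    demographics = "list", groupLabel = "character", meta = "listOrNULL"
  ),
  prototype(fs = 250, demographics = list(), groupLabel = NA_character_,
            meta = NULL)
)

setValidity("CRRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(object@resp) / object@fs < 300)
    msg <- c(msg, "recording must be at least 300 s long")
  if (any(!is.finite(object@rri)) || any(object@rri <= 0))
    msg <- c(msg, "all RR intervals must be finite and positive")
  d <- object@demographics
  if (!is.null(d$bmi) && !is.null(d$height_cm) && !is.null(d$weight_kg)) {
    if (abs(d$bmi - d$weight_kg / (d$height_cm / 100)^2) > 1e-6)
      msg <- c(msg, "bmi inconsistent with weight/(height/100)^2")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CRRecording-class
#' @param resp,rri,fs,demographics,groupLabel,meta see slots.
#' @export
crRecording <- function(resp, rri, fs = 250, demographics = list(),
                        groupLabel = NA_character_, meta = NULL) {
  new("CRRecording", resp = as.numeric(resp), rri = as.numeric(rri),
      fs = fs, demographics = demographics,
      groupLabel = as.character(groupLabel), meta = meta)
}

#' @export
setGeneric("resp", function(x) standardGeneric("resp"))
#' @export
setGeneric("rri", function(x) standardGeneric("rri"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @export
setGeneric("demographics", function(x) standardGeneric("demographics"))
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))

#' Accessors for CRRecording
#' @param x a \linkS4class{CRRecording}.
#' @name CRRecording-accessors
#' @aliases resp rri samplingRate groupLabel demographics recordingMeta
NULL

#' @rdname CRRecording-accessors
#' @export
setMethod("resp", "CRRecording", function(x) x@resp)
#' @rdname CRRecording-accessors
#' @export
setMethod("rri", "CRRecording", function(x) x@rri)
#' @rdname CRRecording-accessors
#' @export
setMethod("samplingRate", "CRRecording", function(x) x@fs)
#' @rdname CRRecording-accessors
#' @export
setMethod("groupLabel", "CRRecording", function(x) x@groupLabel)
#' @rdname CRRecording-accessors
#' @export
setMethod("demographics", "CRRecording", function(x) x@demographics)
#' @rdname CRRecording-accessors
#' @export
setMethod("recordingMeta", "CRRecording", function(x) x@meta)

setMethod("show", "CRRecording", function(object) {
  cat(sprintf(
    "CRRecording (%s): %.0f s respiration @ %g Hz, %d RR intervals (mean %.0f ms)\n",
    object@groupLabel, length(object@resp) / object@fs, object@fs,
    length(object@rri), mean(object@rri)))
})

#' A cohort of recordings
#'
#' Thin container over a list of \linkS4class{CRRecording}, with subject
#' identifiers and a manifest accessor used by the file writers.
#'
#' @slot recordings list of \linkS4class{CRRecording}.
#' @slot subjectIds character vector, same length.
#' @export
setClass("CRCohort",
  representation(recordings = "list", subjectIds = "character"))

setValidity("CRCohort", function(object) {
  if (length(object@recordings) != length(object@subjectIds))
    return("subjectIds and recordings lengths differ")
  if (!all(vapply(object@recordings, is, TRUE, class2 = "CRRecording")))
    return("all elements must be CRRecording")
  if (anyDuplicated(object@subjectIds))
    return("subjectIds must be unique")
  TRUE
})

#' @rdname CRCohort-class
#' @param recordings list of recordings.
#' @param subjectIds optional ids (default S001, S002, ...).
#' @export
crCohort <- function(recordings, subjectIds = NULL) {
  if (is.null(subjectIds))
    subjectIds <- sprintf("S%03d", seq_along(recordings))
  new("CRCohort", recordings = recordings, subjectIds = subjectIds)
}

#' @export
setMethod("length", "CRCohort", function(x) length(x@recordings))

#' @export
setMethod("[[", "CRCohort", function(x, i) x@recordings[[i]])

#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname CRCohort-class
#' @param x a CRCohort.
#' @export
setMethod("subjectIds", "CRCohort", function(x) x@subjectIds)

#' @rdname CRCohort-class
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))

#' @rdname CRCohort-class
#' @export
setMethod("cohortManifest", "CRCohort", function(x) {
  do.call(rbind, lapply(seq_along(x@recordings), function(i) {
    r <- x@recordings[[i]]
    d <- r@demographics
    data.frame(subject_id = x@subjectIds[i], group = r@groupLabel,
               age = d$age %||% NA, sex = d$sex %||% NA,
               height_cm = d$height_cm %||% NA,
               weight_kg = d$weight_kg %||% NA, bmi = d$bmi %||% NA,
               stringsAsFactors = FALSE)
  }))
})

setMethod("show", "CRCohort", function(object) {
  tab <- table(vapply(object@recordings, function(r) r@groupLabel, ""))
  cat(sprintf("CRCohort with %d recordings: %s\n", length(object@recordings),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validation report
#'
#' Holds per-fold metrics for every (dataset, model) pair, pooled
#' out-of-fold predictions and class probabilities, the pooled confusion
#' matrix per dataset for the best model, and the seeds used.
#'
#' @slot foldMetrics data.frame: dataset, model, fold, accuracy, precision,
#'   recall, f1, mcc, auc.
#' @slot predictions data.frame of pooled out-of-fold predictions
#'   (dataset, model, fold, subject, truth, pred, one probability column
#'   per class).
#' @slot bestModel named character: best model per dataset (highest mean
#'   accuracy).
#' @slot confusion named list of pooled K x K confusion matrices for the
#'   best model of each dataset.
#' @slot seeds integer seeds used.
#' @export
setClass("CVReport",
  representation(foldMetrics = "data.frame", predictions = "data.frame",
                 bestModel = "character", confusion = "list",
                 seeds = "integer"))

setMethod("show", "CVReport", function(object) {
  agg <- aggregate(accuracy ~ dataset + model, object@foldMetrics, mean)
  cat("CVReport:", length(unique(object@foldMetrics$dataset)), "dataset(s),",
      length(unique(object@foldMetrics$model)), "model(s),",
      max(object@foldMetrics$fold), "folds\n")
  for (d in unique(agg$dataset)) {
    b <- object@bestModel[[d]]
    acc <- mean(object@foldMetrics$accuracy[
      object@foldMetrics$dataset == d & object@foldMetrics$model == b])
    cat(sprintf("  %s: best model %s, mean accuracy %.3f\n", d, b, acc))
  }
})

#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))
#' Accessors for CVReport
#' @param x a \linkS4class{CVReport}.
#' @rdname CVReport-class
#' @export
setMethod("foldMetrics", "CVReport", function(x) x@foldMetrics)
#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))
#' @rdname CVReport-class
#' @export
setMethod("bestModel", "CVReport", function(x) x@bestModel)
#' @export
setGeneric("oofPredictions", function(x) standardGeneric("oofPredictions"))
#' @rdname CVReport-class
#' @export
setMethod("oofPredictions", "CVReport", function(x) x@predictions)
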