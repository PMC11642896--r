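## Feature extraction: one recording -> 157 named values; one cohort ->
## a features x subjects SummarizedExperiment.

#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame
NULL

#' Extract the full 157-feature vector for one recording
#'
#' Runs preprocessing (band-pass, tachogram, 25 Hz variants), then the
#' demographic, cardiac, respiratory and causal/information blocks of the
#' manifest. Features that cannot be computed are NA (masked), never
#' errors.
#'
#' @param rec a \linkS4class{CRRecording}.
#' @param control coupling settings from [couplingControl()].
#' @return named numeric vector ordered exactly as [featureManifest()].
#' @export
extractFeatureVector <- function(rec, control = couplingControl()) {
  m <- featureManifest()
  pre <- preprocessRecording(rec)
  d <- demographics(rec)
  demo <- c(Age = d$age %||% NA_real_,
            Sex = if (is.null(d$sex)) NA_real_ else as.numeric(d$sex == "M"),
            Height = d$height_cm %||% NA_real_,
            Weight = d$weight_kg %||% NA_real_,
            BMI = d$bmi %||% NA_real_)
  card <- cardiacFeatures(rri(rec))
  breaths <- detectBreaths(pre$respFiltered, samplingRate(rec))
  respf <- respiratoryFeatures(breaths)
  coup <- assembleCouplingFeatures(pre, control)
  v <- c(demo, card, respf, coup)
  stopifnot(setequal(names(v), m$name))
  out <- v[m$name]
  attr(out, "log") <- attr(coup, "log")
  out
}

#' Extract the cohort feature table
#'
#' @param cohort a \linkS4class{CRCohort}.
#' @param control coupling settings from [couplingControl()].
#' @param verbose print progress every 10 subjects.
#' @return a \code{SummarizedExperiment}: assay \code{"features"} (157 x n
#'   subjects), rowData = manifest (domain, category, variant,
#'   description), colData = demographics + group label.
#' @examples
#' \dontrun{
#' coh <- generateCohort(nPerGroup = c(3, 3, 3), seed = 1)
#' se <- extractFeatures(coh)
#' dim(se)  # 157 x 9
#' }
#' @export
extractFeatures <- function(cohort, control = couplingControl(),
                            verbose = FALSE) {
  m <- featureManifest()
  n <- length(cohort)
  X <- matrix(NA_real_, nrow = nrow(m), ncol = n,
              dimnames = list(m$name, subjectIds(cohort)))
  for (i in seq_len(n)) {
    X[, i] <- extractFeatureVector(cohort[[i]], control)
    if (verbose && i %% 10 == 0)
      message(sprintf("extracted %d/%d subjects", i, n))
  }
  cd <- cohortManifest(cohort)
  rownames(cd) <- cd$subject_id
  SummarizedExperiment(
    assays = list(features = X),
    rowData = DataFrame(m[, c("domain", "category", "variant", "description")],
                        row.names = m$name),
    colData = DataFrame(cd))
}
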