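## Plain-text file formats: per-subject recording directories (signal CSV,
## RR-interval text, metadata JSON), cohort manifest CSV, feature table
## CSV + manifest JSON, and the pipeline configuration.

#' Write a recording to a subject directory
#'
#' Layout: \code{resp.csv} (header \code{time_s,resp}), \code{rri.txt}
#' (one RR interval in ms per line), \code{meta.json} (demographics,
#' label, sampling rate, generator metadata).
#'
#' @param rec a \linkS4class{CRRecording}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeRecording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(resp(rec))
  df <- data.frame(time_s = (seq_len(n) - 1) / samplingRate(rec),
                   resp = resp(rec))
  write.csv(df, file.path(dir, "resp.csv"), row.names = FALSE)
  writeLines(format(rri(rec), scientific = FALSE, trim = TRUE, digits = 15),
             file.path(dir, "rri.txt"))
  meta <- list(fs = samplingRate(rec), group = groupLabel(rec),
               demographics = demographics(rec), meta = recordingMeta(rec))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a recording from a subject directory
#'
#' Validates the files: the time column must be monotone with a constant
#' step, RR intervals must be positive finite numbers (a malformed line is
#' reported with its line number).
#'
#' @param dir directory written by [writeRecording()].
#' @return a \linkS4class{CRRecording}.
#' @export
readRecording <- function(dir) {
  fResp <- file.path(dir, "resp.csv")
  fRri <- file.path(dir, "rri.txt")
  fMeta <- file.path(dir, "meta.json")
  for (f in c(fResp, fRri, fMeta))
    if (!file.exists(f)) stop("missing file: ", f)
  df <- read.csv(fResp)
  if (!all(c("time_s", "resp") %in% names(df)))
    stop("resp.csv must have columns time_s,resp")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("non-monotone time column in resp.csv at row ",
                         which(dt <= 0)[1] + 1)
  lines <- readLines(fRri)
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad))
    stop("invalid RR interval in rri.txt at line ", bad[1], ": '",
         lines[bad[1]], "'")
  meta <- jsonlite::read_json(fMeta, simplifyVector = TRUE)
  fs <- meta$fs %||% round(1 / median(dt))
  crRecording(df$resp, vals, fs = fs,
              demographics = as.list(meta$demographics),
              groupLabel = meta$group %||% NA_character_,
              meta = as.list(meta$meta))
}

#' Write / read a cohort
#'
#' One subdirectory per subject plus \code{manifest.csv}
#' (\code{subject_id,group,age,sex,height_cm,weight_kg,bmi}).
#'
#' @param cohort a \linkS4class{CRCohort}.
#' @param dir cohort directory.
#' @return \code{dir} (write) or a \linkS4class{CRCohort} (read).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- subjectIds(cohort)
  for (i in seq_along(ids))
    writeRecording(cohort[[i]], file.path(dir, ids[i]))
  write.csv(cohortManifest(cohort), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(man$subject_id, function(id)
    readRecording(file.path(dir, id)))
  crCohort(recs, subjectIds = as.character(man$subject_id))
}

#' Write / read the cohort feature table
#'
#' CSV with \code{subject_id}, \code{group} and one column per manifest
#' feature; the manifest itself goes to a JSON side file.
#'
#' @param se feature SummarizedExperiment.
#' @param path CSV path (the manifest JSON replaces the extension).
#' @return \code{path} (write) or a SummarizedExperiment (read).
#' @export
writeFeatureTable <- function(se, path) {
  X <- t(assay(se, "features"))
  df <- data.frame(subject_id = rownames(X),
                   group = as.character(colData(se)$group),
                   X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(featureManifest(),
                       sub("\\.csv$", "_manifest.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- featureManifest()
  miss <- setdiff(m$name, names(df))
  if (length(miss)) stop("feature table missing columns: ",
                         paste(head(miss, 5), collapse = ", "))
  X <- t(as.matrix(df[, m$name, drop = FALSE]))
  colnames(X) <- df$subject_id
  SummarizedExperiment(
    assays = list(features = X),
    rowData = DataFrame(m[, c("domain", "category", "variant",
                              "description")], row.names = m$name),
    colData = DataFrame(subject_id = df$subject_id, group = df$group,
                        row.names = df$subject_id))
}

#' Pipeline configuration
#'
#' All defaults match the analysis constants: 250 Hz acquisition, 25 Hz
#' causal-feature grid, 0.05-0.67 Hz respiration band, 10 folds, SMOTE
#' strategy 200/200/200, 30 permutation-importance rounds, top-35
#' selection. The configuration round-trips losslessly through JSON.
#'
#' @param fs,fsDown sampling rates, Hz.
#' @param band respiration passband, Hz.
#' @param folds CV folds.
#' @param seed base seed.
#' @param smoteStrategy named per-class counts.
#' @param xaiRounds permutation-importance rounds.
#' @param selectionK reduced feature-set size.
#' @param models model-zoo subset.
#' @return named list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(fs = 250, fsDown = 25, band = c(0.05, 0.67),
                           folds = 10, seed = 1,
                           smoteStrategy = c(Cardiac = 200, Healthy = 200,
                                             Sport = 200),
                           xaiRounds = 30, selectionK = 35,
                           models = names(modelZoo())) {
  structure(list(fs = fs, fsDown = fsDown, band = band, folds = folds,
                 seed = seed, smoteStrategy = smoteStrategy,
                 xaiRounds = xaiRounds, selectionK = selectionK,
                 models = models),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a PipelineConfig.
#' @param path JSON path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipelineConfig()
  for (nm in names(x)) cfg[[nm]] <- x[[nm]]
  cfg$smoteStrategy <- unlist(cfg$smoteStrategy)
  class(cfg) <- "PipelineConfig"
  cfg
}
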