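# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# one Healthy recording with full demographics
healthyRecording <- function() fixture("healthyRec", function() {
  p <- defaultPresets()$Healthy
  generateRecording(p, seed = 101, subjectTargets = list(
    demographics = list(age = 11, sex = "M", height_cm = 151,
                        weight_kg = 43.5, bmi = 43.5 / 1.51^2)))
})

healthyPre <- function() fixture("healthyPre", function()
  preprocessRecording(healthyRecording()))

# tiny labeled cohort (3 per group), full default presets
tinyCohort <- function() fixture("tinyCohort", function()
  generateCohort(nPerGroup = c(3, 3, 3), seed = 7, nPilot = 100))

# feature table of the tiny cohort
tinySE <- function() fixture("tinySE", function()
  extractFeatures(tinyCohort(), couplingControl(seed = 7)))

# an easily separable tabular 3-class problem (for model/XAI tests)
separableData <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("Cardiac", "Healthy", "Sport"), length.out = n))
    mu <- c(Cardiac = -10, Healthy = 0, Sport = 10)
    X <- cbind(signal1 = mu[as.character(y)] + rnorm(n),
               signal2 = mu[as.character(y)] / 2 + rnorm(n),
               noise1 = rnorm(n), noise2 = rnorm(n))
    rownames(X) <- sprintf("S%03d", seq_len(n))
    list(X = X, y = y)
  })
}

# wrap a tabular dataset as the feature-table container used by runCV
seFromMatrix <- function(X, y) {
  m <- featureManifest()
  full <- matrix(NA_real_, nrow = nrow(m), ncol = nrow(X),
                 dimnames = list(m$name, rownames(X)))
  k <- min(ncol(X), sum(m$domain == "cardiac"))
  cardiacNames <- m$name[m$domain == "cardiac"][seq_len(k)]
  full[cardiacNames, ] <- t(X[, seq_len(k)])
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = full),
    rowData = S4Vectors::DataFrame(
      m[, c("domain", "category", "variant", "description")],
      row.names = m$name),
    colData = S4Vectors::DataFrame(subject_id = rownames(X),
                                   group = as.character(y),
                                   row.names = rownames(X)))
}
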