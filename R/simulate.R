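## Synthetic cohorts with the statistical structure the analysis assumes:
## labeled subjects with Table-1-like covariates, three specimen types, six
## replicate raw spectra per sample, and known ground-truth discriminative
## peaks. Everything is a pure function of (config, seed).

studyTopPeaks <- function() {
  list(
    saliva = data.frame(
      mz = c(2620, 3372, 3443, 3519, 3550, 6352, 6735, 7746, 12692, 13461),
      direction = c(-1, 1, 1, 1, 1, 1, 1, -1, 1, 1)),
    gcf = data.frame(
      mz = c(3775, 4235, 4944, 5296, 5728, 5893, 10586, 11324, 11359, 11447),
      direction = c(1, 1, -1, 1, 1, 1, 1, 1, 1, 1)),
    plaque = data.frame(
      mz = c(2407, 2627, 2783, 2818, 3038, 3077, 3194, 4065, 4931, 14693),
      direction = rep(-1, 10)))
}

makeTemplate <- function(nPeaks, discriminative, effectSize, seed, label,
                         presenceBase = 0.9, markerSdLog = 0.5) {
  withStageSeed(seed, paste0("template:", label), {
    extra <- nPeaks - nrow(discriminative)
    if (extra < 0) stopf("template smaller than its discriminative set")
    ## masses log-uniform across the acquisition range, kept clear of the
    ## planted masses so bins stay distinct at the default tolerance
    mzs <- numeric(0)
    while (length(mzs) < extra) {
      cand <- exp(stats::runif(extra * 2, log(2100), log(19500)))
      all_ <- c(discriminative$mz, mzs)
      cand <- cand[vapply(cand, function(m)
        all(abs(all_ - m) / m > 0.006), logical(1))]
      mzs <- c(mzs, cand[seq_len(min(length(cand), extra - length(mzs)))])
    }
    mz <- c(discriminative$mz, mzs)
    amp <- exp(stats::rnorm(nPeaks, log(3e4), 0.7))
    df <- data.frame(
      mz = mz, amp = amp,
      direction = c(discriminative$direction, rep(0, extra)),
      effect = c(rep(effectSize, nrow(discriminative)), rep(0, extra)),
      presenceCase = c(discriminative$presenceCase %||%
                         rep(presenceBase, nrow(discriminative)),
                       rep(presenceBase, extra)),
      presenceControl = c(discriminative$presenceControl %||%
                            rep(presenceBase, nrow(discriminative)),
                          rep(presenceBase, extra)),
      sdLog = c(rep(markerSdLog, nrow(discriminative)), rep(0.5, extra)))
    df[order(df$mz), ]
  })
}

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic cohort generator.
#' Presets:
#' \describe{
#'   \item{`"smoke"`}{3 + 3 subjects, 3 specimen types, 6 replicates, 30-peak
#'     templates — a fast end-to-end fixture.}
#'   \item{`"fullscale"`}{67 + 74 subjects; 217/176/124-peak templates for
#'     saliva/GCF/plaque whose top-10 discriminative masses and directions
#'     mirror the study (8+/2- saliva, 9+/1- GCF, 10- plaque); per-type
#'     missing-sample rates matching the collected sample counts.}
#'   \item{`"recovery"`}{one specimen type, 60 + 60 subjects, a single
#'     presence/absence marker (present in 80\% of cases, 20\% of controls,
#'     no intensity shift) in a deliberately small 12-peak template —
#'     designed Bayes sensitivity and specificity 0.80/0.80.}
#'   \item{`"null"`}{as recovery but with no discriminative peak at all.}
#'   \item{`"ranking"`}{5 planted intensity markers (1.5 log-unit shift)
#'     among 50 peaks, for ranking-recovery checks.}
#' }
#'
#' @param preset one of smoke/fullscale/recovery/null/ranking.
#' @param seed master seed; every draw derives from it.
#' @param ... overrides for any config entry (nCases, nControls, noiseSD,
#'   replicateCV, warpJitter, baselineAmplitude, baselineDecay, mzStep,
#'   effectSize, missingSampleProb, ...).
#' @return list of class `"SimConfig"`.
#' @export
simConfig <- function(preset = c("smoke", "fullscale", "recovery", "null",
                                 "ranking"), seed = 1, ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset, seed = as.integer(seed),
    mzRange = c(2000, 20000), mzStep = 4,
    baselineAmplitude = 3000, baselineDecay = 3e-4,
    noiseSD = 150, replicateCV = 0.25, warpJitter = 0.0015,
    nReplicates = 6L, effectSize = 1.5,
    missingSampleProb = c(saliva = 0, gcf = 0, plaque = 0),
    covariateRates = NULL)
  top <- studyTopPeaks()
  cfg <- switch(preset,
    smoke = within(base, {
      nCases <- 3L; nControls <- 3L
      sampleTypes <- SAMPLE_TYPES
      nPeaks <- c(saliva = 30L, gcf = 30L, plaque = 30L)
      discriminative <- lapply(top, function(d) {
        d$presenceCase <- 1; d$presenceControl <- 1; d })
    }),
    fullscale = within(base, {
      nCases <- 67L; nControls <- 74L
      sampleTypes <- SAMPLE_TYPES
      nPeaks <- c(saliva = 217L, gcf = 176L, plaque = 124L)
      discriminative <- lapply(top, function(d) {
        d$presenceCase <- 1; d$presenceControl <- 1; d })
      missingSampleProb <- c(saliva = 1 - 119 / 141, gcf = 1 - 104 / 141,
                             plaque = 1 - 110 / 141)
    }),
    recovery = within(base, {
      nCases <- 60L; nControls <- 60L
      sampleTypes <- "saliva"
      ## calibration design: one presence/absence marker among a small
      ## template, so the tree's cross-validated performance estimates the
      ## designed Bayes rule without the selection-bias overfitting that a
      ## wide spurious feature pool induces
      nPeaks <- c(saliva = 12L)
      effectSize <- 0
      discriminative <- list(saliva = data.frame(
        mz = 6000, direction = 1, presenceCase = 0.8, presenceControl = 0.2))
      markerSdLog <- 0.2
      designSensitivity <- 0.8
      designSpecificity <- 0.8
    }),
    null = within(base, {
      nCases <- 60L; nControls <- 60L
      sampleTypes <- "saliva"
      nPeaks <- c(saliva = 50L)
      discriminative <- list(saliva = data.frame(
        mz = numeric(0), direction = numeric(0)))
    }),
    ranking = within(base, {
      nCases <- 60L; nControls <- 60L
      sampleTypes <- "saliva"
      nPeaks <- c(saliva = 50L)
      discriminative <- list(saliva = data.frame(
        mz = c(3000, 5000, 8000, 11000, 15000), direction = 1,
        presenceCase = 0.95, presenceControl = 0.95))
    }))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (cfg$nCases < 2L || cfg$nControls < 2L)
    stopf("need at least 2 subjects per group")
  stopifnot(all(unlist(lapply(cfg$discriminative, function(d)
    d$mz >= cfg$mzRange[1] & d$mz <= cfg$mzRange[2]))))
  cfg$templates <- lapply(cfg$sampleTypes, function(st)
    makeTemplate(cfg$nPeaks[[st]], cfg$discriminative[[st]], cfg$effectSize,
                 cfg$seed, st, markerSdLog = cfg$markerSdLog %||% 0.5))
  names(cfg$templates) <- cfg$sampleTypes
  structure(cfg, class = "SimConfig")
}

defaultCovariateRates <- function() {
  ct <- cohortTableCounts()
  b <- ct$binary
  data.frame(covariate = b$covariate,
             caseRate = b$casesYes / ct$nCases,
             controlRate = b$controlsYes / ct$nControls,
             stringsAsFactors = FALSE)
}

#' Simulate a subject cohort
#'
#' Draws subjects with group labels, sex, age and the binary risk-factor
#' covariates at the study's observed per-group frequencies (configurable).
#' Covariates are drawn independently of the spectral ground truth, so the
#' peak-covariate independence screen holds under the null by construction.
#'
#' @param config a [simConfig()] object.
#' @return list with `cohort` (data.frame: subject, group, sex, age, one
#'   column per covariate) and `truth` (list: per sample type the
#'   discriminative masses and directions, plus any designed Bayes
#'   sensitivity/specificity).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  rates <- config$covariateRates %||% defaultCovariateRates()
  n <- config$nCases + config$nControls
  cohort <- withStageSeed(config$seed, "cohort", {
    df <- data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = rep(c(POSITIVE_CLASS, NEGATIVE_CLASS),
                  c(config$nCases, config$nControls)),
      stringsAsFactors = FALSE)
    case <- df$group == POSITIVE_CLASS
    df$sex <- ifelse(stats::runif(n) < ifelse(case, 53 / 67, 49 / 74),
                     "female", "male")
    age <- ifelse(case, stats::rnorm(n, 50.18, 13.85),
                  stats::rnorm(n, 24.50, 3.28))
    df$age <- round(pmin(pmax(age, 18), 80), 0)
    for (i in seq_len(nrow(rates))) {
      p <- ifelse(case, rates$caseRate[i], rates$controlRate[i])
      df[[rates$covariate[i]]] <- as.integer(stats::runif(n) < p)
    }
    df
  })
  truth <- list(
    labels = stats::setNames(cohort$group, cohort$subject),
    discriminative = lapply(config$templates, function(tp)
      tp[tp$direction != 0 | tp$effect != 0 |
           tp$presenceCase != tp$presenceControl,
         c("mz", "direction", "effect", "presenceCase", "presenceControl")]),
    designSensitivity = config$designSensitivity %||% NA_real_,
    designSpecificity = config$designSpecificity %||% NA_real_)
  list(cohort = cohort, truth = truth)
}

## per-(subject, sample type) latent peak state: presence and subject-level
## amplitude of every template peak; replicates share it
samplePeakState <- function(config, subject, group, sampleType) {
  tp <- config$templates[[sampleType]]
  if (is.null(tp)) stopf("no template for sample type '%s'", sampleType)
  withStageSeed(config$seed, paste0("state:", subject, ":", sampleType), {
    p <- if (group == POSITIVE_CLASS) tp$presenceCase else tp$presenceControl
    present <- stats::runif(nrow(tp)) < p
    shift <- if (group == POSITIVE_CLASS) tp$direction * tp$effect
             else numeric(nrow(tp))
    amp <- tp$amp * exp(shift) * exp(stats::rnorm(nrow(tp), 0, tp$sdLog))
    list(mz = tp$mz, amp = amp * present, present = present)
  })
}

#' Simulate one replicate raw spectrum
#'
#' Closed-form generative model on a regular m/z grid: a sum of Gaussian
#' peaks (width 0.0005 of their mass, linear-mode resolution) at the
#' subject's latent amplitudes, an exponentially decaying chemical baseline,
#' i.i.d. Gaussian detector noise, a per-replicate lognormal intensity
#' factor and a per-spectrum quadratic mass miscalibration bounded by
#' `warpJitter` (relative). Peak identities depend only on (subject, sample
#' type); replicate index changes only noise, intensity factor and jitter.
#'
#' @param config a [simConfig()].
#' @param subject subject id (from [simulateCohort()]).
#' @param group the subject's group label.
#' @param sampleType saliva/gcf/plaque.
#' @param replicate replicate index 1..6.
#' @return A [MassSpectrum-class].
#' @export
simulateSpectrum <- function(config, subject, group, sampleType, replicate) {
  stopifnot(inherits(config, "SimConfig"))
  checkSampleType(sampleType)
  state <- samplePeakState(config, subject, group, sampleType)
  grid <- seq(config$mzRange[1], config$mzRange[2], by = config$mzStep)
  withStageSeed(config$seed,
                paste0("rep:", subject, ":", sampleType, ":", replicate), {
    cv <- config$replicateCV
    repFactor <- if (cv > 0)
      exp(stats::rnorm(1, -0.5 * log(1 + cv^2), sqrt(log(1 + cv^2)))) else 1
    j <- config$warpJitter
    c1 <- if (j > 0) stats::runif(1, -j / 2, j / 2) else 0
    c2 <- if (j > 0) stats::runif(1, -j / 2, j / 2) else 0
    warped <- state$mz * (1 + c1 + c2 * state$mz / config$mzRange[2])
    signal <- numeric(length(grid))
    for (k in which(state$amp > 0)) {
      mu <- warped[k]
      sg <- 5e-4 * state$mz[k]
      win <- abs(grid - mu) < 6 * sg
      signal[win] <- signal[win] +
        state$amp[k] * exp(-0.5 * ((grid[win] - mu) / sg)^2)
    }
    baseline <- config$baselineAmplitude *
      exp(-config$baselineDecay * (grid - config$mzRange[1]))
    noise <- if (config$noiseSD > 0)
      stats::rnorm(length(grid), 0, config$noiseSD) else 0
    MassSpectrum(grid, pmax(repFactor * (signal + baseline) + noise, 0),
                 metadata = list(subject = subject, sampleType = sampleType,
                                 replicate = as.integer(replicate),
                                 id = paste(subject, sampleType, replicate,
                                            sep = "_")))
  })
}

#' Simulate a binned intensity matrix directly
#'
#' Samples the same generative design as the raw-spectrum path, but at the
#' level the classifier consumes: one MSP-like intensity per (sample, peak),
#' lognormal around the template amplitude with the group effect applied,
#' zero when the peak is absent. Used for repeated-cohort calibration
#' studies where simulating thousands of raw spectra would add nothing but
#' runtime.
#'
#' @param config a [simConfig()].
#' @param sampleType which template to use (default the first).
#' @return list with `pm` (a [PeakMatrix-class]), `cohort`, `truth`.
#' @export
simulateIntensityMatrix <- function(config, sampleType = config$sampleTypes[1]) {
  sc <- simulateCohort(config)
  cohort <- sc$cohort
  tp <- config$templates[[sampleType]]
  n <- nrow(cohort)
  mat <- matrix(0, nrow = nrow(tp), ncol = n)
  for (i in seq_len(n)) {
    st <- samplePeakState(config, cohort$subject[i], cohort$group[i],
                          sampleType)
    mat[, i] <- st$amp
  }
  cd <- data.frame(subject = cohort$subject, sampleType = sampleType,
                   group = cohort$group,
                   row.names = paste(cohort$subject, sampleType, sep = "."),
                   stringsAsFactors = FALSE)
  colnames(mat) <- rownames(cd)
  list(pm = newPeakMatrix(mat, binMass = tp$mz, colData = cd),
       cohort = cohort, truth = sc$truth)
}

#' Write a ready-to-run fixture set
#'
#' Materialises a simulated cohort as on-disk pipeline input: one TSV
#' spectrum per (subject, sample type, replicate), a sample manifest, the
#' cohort covariate table and the ground truth as JSON. Samples are dropped
#' with the per-type missing-sample probability.
#'
#' @param config a [simConfig()].
#' @param outDir output directory (created if needed).
#' @return list with `manifest` (path), `cohortFile`, `truthFile`,
#'   `nSpectra`, plus the in-memory `cohort` and `truth`.
#' @export
writeFixtureSet <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sc <- simulateCohort(config)
  cohort <- sc$cohort
  rows <- list()
  nSpectra <- 0L
  for (i in seq_len(nrow(cohort))) {
    for (st in config$sampleTypes) {
      miss <- config$missingSampleProb[[st]] %||% 0
      drop <- withStageSeed(config$seed,
                            paste0("miss:", cohort$subject[i], ":", st),
                            stats::runif(1) < miss)
      if (drop) next
      for (r in seq_len(config$nReplicates)) {
        sp <- simulateSpectrum(config, cohort$subject[i], cohort$group[i],
                               st, r)
        fn <- sprintf("%s_%s_rep%d.tsv", cohort$subject[i], st, r)
        writeSpectrum(sp, file.path(outDir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          file = fn, subject = cohort$subject[i], sample_type = st,
          replicate = r, group = cohort$group[i], stringsAsFactors = FALSE)
        nSpectra <- nSpectra + 1L
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(outDir, "manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cohortPath <- file.path(outDir, "cohort.tsv")
  utils::write.table(cohort, cohortPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(
    list(labels = as.list(sc$truth$labels),
         discriminative = sc$truth$discriminative,
         designSensitivity = sc$truth$designSensitivity,
         designSpecificity = sc$truth$designSpecificity),
    truthPath, auto_unbox = TRUE, digits = NA, na = "null")
  list(manifest = manifestPath, cohortFile = cohortPath,
       truthFile = truthPath, nSpectra = nSpectra, cohort = cohort,
       truth = sc$truth)
}
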