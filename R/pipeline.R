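#' Preprocess all spectra of a manifest into main spectrum profiles
#'
#' Runs the per-replicate chain (QC, smoothing, SNIP baseline, TIC,
#' peak picking) on every spectrum file, aligns the surviving peak lists
#' within each sample type, and averages each sample's replicates into a
#' main spectrum profile. A sample survives when at least one replicate
#' passes QC.
#'
#' @param manifest data.frame from [readManifest()].
#' @param dir directory the manifest's file paths are relative to.
#' @param halfWindow,iterations,snrThreshold,minMaxIntensity,minSpectrumSNR
#'   per-replicate parameters, see [preprocessSpectrum()].
#' @param tolerance,minPeakFrequency alignment parameters, see
#'   [alignSpectra()].
#' @param minFrequency MSP replicate-frequency threshold, see
#'   [averageReplicates()].
#' @return list with `msps` (per sample type: named list of
#'   [MainSpectrumProfile-class]), `sampleInfo` (per sample type:
#'   data.frame subject/sampleType/group) and `qc` (data.frame of discarded
#'   replicates with reasons).
#' @export
preprocessManifest <- function(manifest, dir = ".", halfWindow = 8,
                               iterations = 100, snrThreshold = 3,
                               minMaxIntensity = 1e4, minSpectrumSNR = 3,
                               tolerance = 0.002, minPeakFrequency = 0.9,
                               minFrequency = 0.25) {
  qc <- list()
  byType <- split(manifest, manifest$sample_type)
  msps <- list()
  sampleInfo <- list()
  for (st in names(byType)) {
    mf <- byType[[st]]
    peaklists <- list()
    key <- character()
    for (i in seq_len(nrow(mf))) {
      path <- file.path(dir, mf$file[i])
      sp <- readSpectrum(path, metadata = list(
        subject = mf$subject[i], sampleType = st,
        replicate = mf$replicate[i],
        id = paste(mf$subject[i], st, mf$replicate[i], sep = "_")))
      res <- preprocessSpectrum(sp, halfWindow, iterations, snrThreshold,
                                minMaxIntensity, minSpectrumSNR)
      if (!res$accept) {
        qc[[length(qc) + 1L]] <- data.frame(
          file = mf$file[i], subject = mf$subject[i], sample_type = st,
          replicate = mf$replicate[i],
          reasons = paste(res$reasons, collapse = ","),
          stringsAsFactors = FALSE)
        next
      }
      peaklists[[length(peaklists) + 1L]] <- res$peaks
      key <- c(key, mf$subject[i])
    }
    if (!length(peaklists)) next
    if (length(peaklists) >= 2L)
      peaklists <- suppressWarnings(
        alignSpectra(peaklists, tolerance, minPeakFrequency))$peaklists
    bySample <- split(seq_along(peaklists), key)
    msps[[st]] <- lapply(names(bySample), function(sub)
      averageReplicates(peaklists[bySample[[sub]]], minFrequency, tolerance,
                        source = paste(sub, st, sep = ".")))
    names(msps[[st]]) <- names(bySample)
    grp <- manifest$group[match(names(bySample), manifest$subject)]
    sampleInfo[[st]] <- data.frame(
      subject = names(bySample), sampleType = st, group = grp,
      row.names = paste(names(bySample), st, sep = "."),
      stringsAsFactors = FALSE)
  }
  list(msps = msps, sampleInfo = sampleInfo,
       qc = if (length(qc)) do.call(rbind, qc) else
         data.frame(file = character(), subject = character(),
                    sample_type = character(), replicate = integer(),
                    reasons = character()))
}

#' Run the full diagnostic pipeline
#'
#' Orchestrates simulate, preprocess, feature building, per-specimen
#' cross-validation, full-data tree training, subject-level fusion and the
#' cohort statistics as one seeded, reproducible run. Any stage failure
#' aborts with an error naming the stage.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   `seed` (integer, master seed);
#'   `sim` (list passed to [simConfig()]: `preset` and overrides);
#'   `preprocess` (optional overrides for [preprocessManifest()]);
#'   `cv` (list: `k`, `topK`, `minLeaf`, `pruneCf`);
#'   `fusion` (list: `tieBreak`);
#'   `workDir` (optional; where fixture spectra are written; defaults to a
#'   temporary directory).
#' @return list of class `"RunReport"`; serialise with [writeRunReport()].
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "sim", "preprocess", "cv", "fusion", "workDir")
  bad <- setdiff(names(config), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s': %s", name, conditionMessage(e)))
  }
  simArgs <- config$sim %||% list(preset = "smoke")
  simArgs$seed <- seed
  sc <- stage("simulate", do.call(simConfig, simArgs))
  workDir <- config$workDir %||% tempfile("periospec-run-")
  fix <- stage("simulate", writeFixtureSet(sc, workDir))
  manifest <- stage("simulate", readManifest(fix$manifest))

  preArgs <- c(list(manifest = manifest, dir = workDir),
               config$preprocess %||% list())
  pre <- stage("preprocess", do.call(preprocessManifest, preArgs))

  cv <- config$cv %||% list()
  k <- cv$k %||% 10L
  topK <- cv$topK %||% 30L
  minLeaf <- cv$minLeaf %||% 2L
  pruneCf <- cv$pruneCf %||% 0.25
  tieBreak <- (config$fusion %||% list())$tieBreak %||% "positive"

  perType <- list()
  preds <- list()
  for (st in names(pre$msps)) {
    msps <- pre$msps[[st]]
    bins <- stage("features", binPeaks(msps))
    pm <- stage("features",
                buildIntensityMatrix(msps, bins, pre$sampleInfo[[st]]))
    screen <- stage("features", screenPeaks(pm))
    cvRes <- stage("classifier",
                   crossValidate(pm, k = k, seed = seed, topK = topK,
                                 minLeaf = minLeaf, pruneCf = pruneCf))
    ## full-data tree for fusion
    dpm <- stage("classifier", dichotomize(pm))
    rk <- stage("classifier", bindaRank(dpm, SummarizedExperiment::colData(pm)$group))
    bm <- SummarizedExperiment::rowData(pm)$binMass
    sel <- match(rk$binMass[seq_len(min(topK, nrow(rk)))], bm)
    x <- t(SummarizedExperiment::assay(dpm, "binary")[sel, , drop = FALSE])
    colnames(x) <- sprintf("%.9g", bm[sel])
    tree <- stage("classifier",
                  trainTree(x, SummarizedExperiment::colData(pm)$group,
                            minLeaf = minLeaf, pruneCf = pruneCf,
                            meta = list(sampleType = st)))
    p <- predictTree(tree, x)
    preds[[st]] <- stats::setNames(p, SummarizedExperiment::colData(pm)$subject)
    perType[[st]] <- list(
      nSamples = ncol(pm), nBins = nrow(pm),
      nSignificant = attr(screen, "nSignificant"),
      alpha = attr(screen, "alpha"),
      cv = list(k = cvRes$k,
                sensitivity = unname(cvRes$sensitivity),
                specificity = unname(cvRes$specificity)),
      treeLeaves = treeLeafCount(tree@root),
      topPeaks = rk$binMass[seq_len(min(10L, nrow(rk)))])
  }

  fusion <- stage("fusion", {
    subjects <- unique(unlist(lapply(preds, names)))
    fused <- lapply(subjects, function(sub) {
      pp <- unlist(lapply(preds, function(p) unname(p[sub])))
      names(pp) <- names(preds)
      pp <- pp[!is.na(pp)]
      fusePredictions(pp, tieBreak = tieBreak, subject = sub)
    })
    ev <- evaluateFusion(fused, fix$truth$labels)
    list(tieBreak = tieBreak,
         nDeterminate = ev$nDeterminate,
         nIndeterminate = ev$nIndeterminate,
         sensitivity = ev$sensitivity$estimate,
         specificity = ev$specificity$estimate,
         ppv = ev$ppv$estimate, npv = ev$npv$estimate,
         ci = list(sensitivity = unname(ev$sensitivity$ci),
                   specificity = unname(ev$specificity$ci)))
  })

  epi <- stage("epistats", {
    cohort <- utils::read.delim(fix$cohortFile, stringsAsFactors = FALSE)
    assoc <- list()
    for (st in names(pre$msps)) {
      msps <- pre$msps[[st]]
      bins <- binPeaks(msps)
      pm <- buildIntensityMatrix(msps, bins, pre$sampleInfo[[st]])
      dpm <- dichotomize(pm)
      rk <- bindaRank(dpm, SummarizedExperiment::colData(pm)$group)
      bm <- SummarizedExperiment::rowData(pm)$binMass
      sel <- match(rk$binMass[seq_len(min(10L, nrow(rk)))], bm)
      peaks <- t(SummarizedExperiment::assay(pm, "intensity")[sel, , drop = FALSE])
      colnames(peaks) <- sprintf("%.9g", bm[sel])
      covs <- cohort[match(SummarizedExperiment::colData(pm)$subject,
                           cohort$subject),
                     setdiff(names(cohort), c("subject", "group", "sex")),
                     drop = FALSE]
      r <- tryCatch(suppressWarnings(peakCovariateAssociation(peaks, covs)),
                    error = function(e) NULL)
      assoc[[st]] <- if (is.null(r)) list(independent = NA) else
        list(independent = r$independent, maxCorrelation = r$maxCorrelation)
    }
    tests <- cohortTableTests()
    list(association = assoc,
         cohortTests = tests[, c("covariate", "p")])
  })

  report <- list(
    software = list(package = "periospec",
                    version = as.character(utils::packageVersion("periospec"))),
    config = list(seed = seed,
                  sim = simArgs[setdiff(names(simArgs), "templates")],
                  cv = list(k = k, topK = topK, minLeaf = minLeaf,
                            pruneCf = pruneCf),
                  fusion = list(tieBreak = tieBreak)),
    qc = list(nDiscarded = nrow(pre$qc),
              discarded = pre$qc,
              nSpectra = fix$nSpectra),
    perType = perType,
    fusion = fusion,
    epi = epi)
  class(report) <- "RunReport"
  report
}

#' @param report a `RunReport` from [runPipeline()].
#' @param path JSON output path.
#' @rdname runPipeline
#' @export
writeRunReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}
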