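#' Bin peaks across main spectrum profiles
#'
#' Pools the peak masses of all profiles and clusters them divisively: a
#' sorted block of masses forms one bin iff its relative spread
#' `(max - min)/mean` is at most `2 * tolerance`; otherwise the block is
#' split at its largest internal gap. Each profile contributes at most one
#' peak per bin (its strongest); bin reference masses are member means.
#'
#' @param msps list of [MainSpectrumProfile-class] (or [MassPeaks-class]).
#' @param tolerance relative mass tolerance (default 0.002).
#' @return list with `binMass` (strictly increasing reference masses) and
#'   `assignment`, a `data.frame` (`msp` index, `peak` index within that
#'   profile, `bin` index) of retained peak-to-bin assignments.
#' @export
binPeaks <- function(msps, tolerance = 0.002) {
  stopifnot(length(msps) >= 1L,
            all(vapply(msps, is, logical(1), "MassPeaks")))
  npk <- vapply(msps, function(p) length(p@mz), integer(1))
  allmz <- unlist(lapply(msps, mz))
  allint <- unlist(lapply(msps, intensity))
  srcMsp <- rep(seq_along(msps), npk)
  srcPeak <- unlist(lapply(npk, seq_len))
  if (!length(allmz))
    return(list(binMass = numeric(0),
                assignment = data.frame(msp = integer(), peak = integer(),
                                        bin = integer())))
  cl <- clusterMasses(allmz, tolerance)
  ids <- sort(unique(cl))
  binMass <- vapply(ids, function(id) mean(allmz[cl == id]), numeric(1))
  o <- order(binMass)
  binMass <- binMass[o]
  rank_ <- match(cl, ids[o])
  ## strongest peak per (msp, bin)
  ord <- order(srcMsp, rank_, -allint)
  keep <- ord[!duplicated(paste(srcMsp[ord], rank_[ord]))]
  assignment <- data.frame(msp = srcMsp[keep], peak = srcPeak[keep],
                           bin = rank_[keep])
  assignment <- assignment[order(assignment$msp, assignment$bin), ]
  rownames(assignment) <- NULL
  list(binMass = binMass, assignment = assignment)
}

#' Build the binned intensity matrix
#'
#' Fills a bins-by-samples matrix with the assigned profile intensities;
#' cells for which a sample has no peak in a bin are zero. Sample annotation
#' (subject, sample type, group) is taken from each profile's `source` name
#' and the supplied `sampleInfo`.
#'
#' @param msps list of [MainSpectrumProfile-class].
#' @param bins result of [binPeaks()] on the same profiles.
#' @param sampleInfo optional `data.frame` with one row per profile
#'   (columns `subject`, `sampleType`, `group`); defaults to the profiles'
#'   `source` strings with unknown group.
#' @return A [PeakMatrix-class] with an `"intensity"` assay.
#' @export
buildIntensityMatrix <- function(msps, bins, sampleInfo = NULL) {
  n <- length(msps)
  stopifnot(n >= 1L)
  if (is.null(sampleInfo)) {
    src <- vapply(seq_along(msps), function(i)
      if (is.na(msps[[i]]@source)) sprintf("sample%02d", i) else msps[[i]]@source,
      character(1))
    sampleInfo <- data.frame(subject = src, sampleType = NA_character_,
                             group = "unknown", stringsAsFactors = FALSE)
    rownames(sampleInfo) <- make.unique(src)
  }
  stopifnot(nrow(sampleInfo) == n)
  if (is.null(rownames(sampleInfo)) ||
      all(rownames(sampleInfo) == as.character(seq_len(n))))
    rownames(sampleInfo) <- make.unique(paste(sampleInfo$subject,
                                              sampleInfo$sampleType, sep = "."))
  mat <- matrix(0, nrow = length(bins$binMass), ncol = n,
                dimnames = list(NULL, rownames(sampleInfo)))
  a <- bins$assignment
  for (k in seq_len(nrow(a)))
    mat[a$bin[k], a$msp[k]] <- msps[[a$msp[k]]]@intensity[a$peak[k]]
  empty <- which(colSums(mat) == 0 &
                   vapply(msps, function(p) length(p@mz) == 0L, logical(1)))
  if (length(empty))
    warnf("sample(s) without any peaks: %s",
          paste(rownames(sampleInfo)[empty], collapse = ", "))
  newPeakMatrix(mat, binMass = bins$binMass, colData = sampleInfo)
}

#' Screen bins for between-group intensity differences
#'
#' Per-bin two-sided Wilcoxon rank-sum test of the intensities (zeros
#' included) between the two groups, unadjusted. The direction is the sign
#' of the group median difference (falling back to means on a median tie).
#'
#' @param pm a [PeakMatrix-class].
#' @param labels group label per sample (`periodontitis`/`control`);
#'   defaults to `colData(pm)$group`.
#' @param alpha significance level reported against (default 0.05).
#' @return A `data.frame` with one row per bin: `binMass`, `p`,
#'   `medianCase`, `medianControl`, `direction`; attributes `nDetected`,
#'   `nSignificant`, `alpha`.
#' @export
screenPeaks <- function(pm, labels = NULL, alpha = 0.05) {
  a <- SummarizedExperiment::assay(pm, "intensity")
  labels <- labels %||% SummarizedExperiment::colData(pm)$group
  labels <- as.character(labels)
  if (length(unique(labels[labels != "unknown"])) < 2L)
    stopf("peak screening needs two groups")
  case <- labels == POSITIVE_CLASS
  ctrl <- labels == NEGATIVE_CLASS
  if (sum(case) < 2L || sum(ctrl) < 2L)
    stopf("each group needs at least 2 samples")
  bm <- SummarizedExperiment::rowData(pm)$binMass
  res <- data.frame(binMass = bm, p = NA_real_, medianCase = NA_real_,
                    medianControl = NA_real_, direction = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(a))) {
    x <- a[j, case]; y <- a[j, ctrl]
    ## exact where tie-free (n < 50); with ties, the normal approximation
    ## without continuity correction so symmetric cases give p = 1
    res$p[j] <- if (all(c(x, y) == c(x, y)[1L])) 1
      else suppressWarnings(stats::wilcox.test(x, y, correct = FALSE)$p.value)
    mc <- stats::median(x); mh <- stats::median(y)
    d <- mc - mh
    if (d == 0) d <- mean(x) - mean(y)
    res$medianCase[j] <- mc
    res$medianControl[j] <- mh
    res$direction[j] <- if (d > 0) "higher-in-periodontitis"
      else if (d < 0) "higher-in-control" else "tied"
  }
  attr(res, "nDetected") <- nrow(res)
  attr(res, "nSignificant") <- sum(res$p < alpha, na.rm = TRUE)
  attr(res, "alpha") <- alpha
  res
}

#' Dichotomize intensities into presence calls
#'
#' Per bin, the threshold is the midpoint of the two group means; values
#' strictly above it become 1. Bins whose intensities are constant get that
#' constant as threshold, an all-zero binary row, and an `uninformative`
#' flag.
#'
#' @param pm a [PeakMatrix-class] with an `"intensity"` assay.
#' @param labels training group labels (default `colData(pm)$group`).
#' @return The [PeakMatrix-class] with an added `"binary"` assay and
#'   `rowData` columns `threshold` and `uninformative`.
#' @export
dichotomize <- function(pm, labels = NULL) {
  a <- SummarizedExperiment::assay(pm, "intensity")
  labels <- labels %||% SummarizedExperiment::colData(pm)$group
  labels <- as.character(labels)
  case <- labels == POSITIVE_CLASS
  ctrl <- labels == NEGATIVE_CLASS
  if (!any(case) || !any(ctrl))
    stopf("dichotomization needs training samples of both groups")
  thr <- (rowMeans(a[, case, drop = FALSE]) +
          rowMeans(a[, ctrl, drop = FALSE])) / 2
  uninformative <- apply(a, 1L, function(x) all(x == x[1L]))
  thr[uninformative] <- a[uninformative, 1L]
  bin <- (a > thr) * 1L
  bin[uninformative, ] <- 0L
  out <- pm
  SummarizedExperiment::assay(out, "binary", withDimnames = FALSE) <- bin
  SummarizedExperiment::rowData(out)$threshold <- unname(thr)
  SummarizedExperiment::rowData(out)$uninformative <- unname(uninformative)
  out
}

#' @rdname dichotomize
#' @param intensity numeric matrix bins x samples.
#' @param thresholds per-bin thresholds (e.g. `rowData(pm)$threshold` from a
#'   training fit) applied to new samples.
#' @return `applyThresholds`: a binary matrix of the same shape.
#' @export
applyThresholds <- function(intensity, thresholds) {
  stopifnot(nrow(intensity) == length(thresholds))
  (intensity > thresholds) * 1L
}

#' Rank bins by binary discriminant score
#'
#' For each bin, with regularised per-group presence frequencies
#' `p_g = (x_g + 1/2) / (n_g + 1)` and their size-weighted pooled frequency
#' `p = sum_g n_g p_g / n`, the score is
#' the group-wise binomial log-likelihood ratio against the pooled model,
#' `S = sum_g n_g * (p_g log(p_g/p) + (1 - p_g) log((1-p_g)/(1-p)))`.
#' Bins are ordered by descending score, ties broken by ascending reference
#' mass. The half-count regularisation keeps perfectly separating bins
#' finite.
#'
#' @param binary binary matrix bins x samples (or a [PeakMatrix-class] with a
#'   `"binary"` assay).
#' @param labels group label per sample.
#' @param binMass reference masses (taken from the `PeakMatrix` if given).
#' @return A `data.frame` ordered by rank: `rank`, `binMass`, `score`,
#'   `freqCase`, `freqControl`.
#' @export
bindaRank <- function(binary, labels, binMass = NULL) {
  if (is(binary, "PeakMatrix")) {
    binMass <- binMass %||% SummarizedExperiment::rowData(binary)$binMass
    binary <- SummarizedExperiment::assay(binary, "binary")
  }
  labels <- as.character(labels)
  case <- labels == POSITIVE_CLASS
  ctrl <- labels == NEGATIVE_CLASS
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L)
    stopf("binary discriminant ranking needs >= 2 samples per group")
  if (is.null(binMass)) binMass <- seq_len(nrow(binary))
  x1 <- rowSums(binary[, case, drop = FALSE])
  x2 <- rowSums(binary[, ctrl, drop = FALSE])
  score <- bindaScore(x1, n1, x2, n2)
  o <- order(-score, binMass)
  data.frame(rank = seq_along(o), binMass = binMass[o], score = score[o],
             freqCase = (x1 / n1)[o], freqControl = (x2 / n2)[o])
}

## vectorised score for presence counts x1/n1 (cases) and x2/n2 (controls);
## the pooled frequency is the sample-size-weighted mean of the regularised
## group frequencies, so identical group frequencies score exactly zero
bindaScore <- function(x1, n1, x2, n2) {
  p1 <- (x1 + 0.5) / (n1 + 1)
  p2 <- (x2 + 0.5) / (n2 + 1)
  p0 <- (n1 * p1 + n2 * p2) / (n1 + n2)
  term <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
  n1 * term(p1, p0) + n2 * term(p2, p0)
}
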