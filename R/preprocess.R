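#' Quality control of a raw spectrum
#'
#' A replicate spectrum is kept only if (i) its maximum raw intensity reaches
#' `minMaxIntensity` (default 1e4 AU, the acquisition acceptance level for
#' linear-mode profiles) and (ii) its strongest baseline-corrected signal
#' exceeds `minSpectrumSNR` times the robust noise level. Both checks run per
#' replicate, before any averaging.
#'
#' @param spectrum a [MassSpectrum-class] (raw).
#' @param minMaxIntensity minimum acceptable maximum intensity (AU).
#' @param minSpectrumSNR minimum ratio max(corrected)/noise.
#' @param iterations SNIP iterations used for the internal baseline estimate.
#' @return list with `accept` (logical) and `reasons` (character vector,
#'   subset of `"max-intensity"`, `"spectrum-snr"`).
#' @export
qcSpectrum <- function(spectrum, minMaxIntensity = 1e4, minSpectrumSNR = 3,
                       iterations = 100) {
  stopifnot(is(spectrum, "MassSpectrum"))
  reasons <- character()
  if (max(spectrum@intensity) < minMaxIntensity)
    reasons <- c(reasons, "max-intensity")
  corrected <- snipBaseline(spectrum, iterations = iterations)$corrected
  noise <- estimateNoise(corrected)
  snr <- if (noise > 0) max(intensity(corrected)) / noise
         else if (max(intensity(corrected)) > 0) Inf else 0
  if (snr < minSpectrumSNR) reasons <- c(reasons, "spectrum-snr")
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Moving-average smoothing
#'
#' Replaces every intensity by the unweighted mean of the surrounding
#' `2 * halfWindow + 1` points (default half window 8, i.e. 17 points).
#' Near the edges the window is truncated to the available points; m/z is
#' unchanged.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param halfWindow half window size in points.
#' @return A smoothed [MassSpectrum-class].
#' @export
smoothSpectrum <- function(spectrum, halfWindow = 8) {
  stopifnot(is(spectrum, "MassSpectrum"))
  n <- length(spectrum@intensity)
  if (n < 2 * halfWindow + 1)
    stopf("spectrum has %d points; smoothing needs at least %d",
          n, 2 * halfWindow + 1)
  y <- spectrum@intensity
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - halfWindow, 1L)
  hi <- pmin(i + halfWindow, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  MassSpectrum(spectrum@mz, sm, spectrum@metadata)
}

#' SNIP baseline estimation
#'
#' Statistics-sensitive non-linear iterative peak clipping with the standard
#' decreasing clipping-window schedule: at pass `m` (shrinking from
#' `iterations` points down to 1) each point is replaced by the minimum of
#' itself and the mean of its two neighbours `m` points away. Clipping acts
#' on the raw intensities; a baseline that is exactly linear over any
#' clipping window is therefore reproduced exactly. The optional
#' log-log-square-root (LLS) compression of the classic formulation is
#' available via `lls = TRUE`. The corrected trace is
#' `max(intensity - baseline, 0)`.
#'
#' @param spectrum a smoothed [MassSpectrum-class]; intensities must be
#'   non-negative.
#' @param iterations number of clipping iterations (= initial half window in
#'   points; default 100).
#' @param decreasing logical; use the decreasing-window schedule (default) or
#'   a fixed window of `iterations` points at every pass.
#' @param lls logical; clip LLS-compressed intensities instead of raw ones
#'   (default FALSE).
#' @return list with `baseline` (numeric vector) and `corrected`
#'   (a [MassSpectrum-class]).
#' @references Ryan et al. (1988) Nucl. Instrum. Methods B 34:396;
#'   Morhac (2009) Appl. Spectrosc. 63:1309.
#' @export
snipBaseline <- function(spectrum, iterations = 100, decreasing = TRUE,
                         lls = FALSE) {
  stopifnot(is(spectrum, "MassSpectrum"))
  y <- spectrum@intensity
  if (any(y < 0)) stopf("SNIP requires non-negative intensities")
  n <- length(y)
  v <- if (lls) log(log(sqrt(y + 1) + 1) + 1) else y
  maxWin <- min(iterations, (n - 1L) %/% 2L)
  schedule <- if (decreasing) seq(maxWin, 1L) else rep(maxWin, iterations)
  for (m in schedule) {
    idx <- (m + 1L):(n - m)
    clipped <- (v[idx - m] + v[idx + m]) / 2
    v[idx] <- pmin(v[idx], clipped)
  }
  baseline <- if (lls) (exp(exp(v) - 1) - 1)^2 - 1 else v
  baseline <- pmin(pmax(baseline, 0), y)
  corrected <- MassSpectrum(spectrum@mz, pmax(y - baseline, 0),
                            spectrum@metadata)
  list(baseline = baseline, corrected = corrected)
}

#' Total-ion-current normalisation
#'
#' Scales the intensities so they sum to one, turning them into relative
#' abundances. Profiles differing only by a positive factor (laser power,
#' deposit thickness) become identical.
#'
#' @param spectrum a [MassSpectrum-class] with positive total intensity.
#' @return The TIC-normalised [MassSpectrum-class].
#' @export
ticNormalize <- function(spectrum) {
  stopifnot(is(spectrum, "MassSpectrum"))
  tot <- sum(spectrum@intensity)
  if (tot <= 0) stopf("cannot TIC-normalize a spectrum with zero total intensity")
  MassSpectrum(spectrum@mz, spectrum@intensity / tot, spectrum@metadata)
}

#' Robust noise level of a spectrum
#'
#' Scaled median absolute deviation of the intensities,
#' `1.4826 * median(|y - median(y)|)`, consistent for the standard deviation
#' under Gaussian noise.
#'
#' @param spectrum a [MassSpectrum-class] or numeric vector.
#' @return noise level (AU), a single number.
#' @export
estimateNoise <- function(spectrum) {
  y <- if (is(spectrum, "MassSpectrum")) spectrum@intensity else as.numeric(spectrum)
  if (length(y) < 3L) stopf("need at least 3 points to estimate noise")
  stats::mad(y)   # constant = 1.4826
}

#' Peak detection
#'
#' A point is a peak iff it is the strict maximum of its +/- `halfWindow`
#' point neighbourhood and its intensity is at least `snrThreshold` times the
#' spectrum's MAD noise level. Run on the baseline-corrected, TIC-normalised
#' trace.
#'
#' @param spectrum corrected [MassSpectrum-class].
#' @param halfWindow neighbourhood half width in points (default 8).
#' @param snrThreshold minimum signal-to-noise ratio (default 3).
#' @return A [MassPeaks-class] (possibly empty) with per-peak SNR.
#' @export
detectPeaks <- function(spectrum, halfWindow = 8, snrThreshold = 3) {
  stopifnot(is(spectrum, "MassSpectrum"))
  y <- spectrum@intensity
  n <- length(y)
  noise <- estimateNoise(y)
  isMax <- y > 0
  for (d in seq_len(halfWindow)) {
    left <- c(rep(-Inf, d), y[seq_len(n - d)])
    right <- c(y[(d + 1L):n], rep(-Inf, d))
    isMax <- isMax & (y > left) & (y > right)
  }
  snr <- if (noise > 0) y / noise else ifelse(y > 0, Inf, 0)
  keep <- which(isMax & snr >= snrThreshold)
  MassPeaks(mz = spectrum@mz[keep], intensity = y[keep], snr = snr[keep],
            source = spectrum@metadata$id %||% NA_character_)
}

#' Fit a quadratic mass-warp against reference peaks
#'
#' Greedily matches observed peaks (ascending m/z) to the nearest unused
#' reference peak within the relative tolerance, then least-squares fits
#' `reference = a0 + a1 observed + a2 observed^2`. With fewer than three
#' anchors, or if the fitted warp is non-monotone or moves any mass by more
#' than 1\% over the fitted range, the identity warp is returned with a
#' warning.
#'
#' @param peaklist observed [MassPeaks-class].
#' @param reference reference [MassPeaks-class] (or numeric masses).
#' @param tolerance maximum relative mass error |dm|/m for a match
#'   (default 0.002).
#' @return A [WarpModel-class].
#' @export
fitWarp <- function(peaklist, reference, tolerance = 0.002) {
  obs <- if (is(peaklist, "MassPeaks")) peaklist@mz else as.numeric(peaklist)
  ref <- if (is(reference, "MassPeaks")) reference@mz else as.numeric(reference)
  used <- logical(length(ref))
  om <- numeric(0); rm_ <- numeric(0)
  for (m in obs) {   # ascending: ties resolve toward lower m/z reference
    d <- abs(ref - m) / m
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tolerance) {
      used[j] <- TRUE
      om <- c(om, m); rm_ <- c(rm_, ref[j])
    }
  }
  idWarp <- function() new("WarpModel", coefficients = c(0, 1, 0),
                           nAnchors = length(om), identity = TRUE)
  if (length(om) < 3L) {
    warnf("only %d matchable peak(s); using identity warp", length(om))
    return(idWarp())
  }
  fit <- stats::lm.fit(cbind(1, om, om^2), rm_)
  co <- unname(fit$coefficients)
  co[is.na(co)] <- 0
  ## sanity-check the warp over the whole observed peak range, not only the
  ## anchor span: quadratic extrapolation must stay monotone there too
  rng <- range(obs)
  grid <- seq(rng[1], rng[2], length.out = 64L)
  deriv <- co[2] + 2 * co[3] * grid
  shift <- abs(co[1] + co[2] * grid + co[3] * grid^2 - grid) / grid
  if (any(deriv <= 0) || any(shift > 0.01)) {
    warnf("fitted warp non-monotone or implausibly large; using identity")
    return(idWarp())
  }
  new("WarpModel", coefficients = co, nAnchors = length(om), identity = FALSE)
}

#' @param warp a [WarpModel-class].
#' @param peaklist a [MassPeaks-class] (or numeric masses) to correct.
#' @return `applyWarp`: the warped [MassPeaks-class] (or numeric vector).
#' @rdname fitWarp
#' @export
applyWarp <- function(warp, peaklist) {
  stopifnot(is(warp, "WarpModel"))
  co <- warp@coefficients
  f <- function(m) co[1] + co[2] * m + co[3] * m^2
  if (is(peaklist, "MassPeaks")) {
    out <- peaklist
    out@mz <- f(peaklist@mz)
    validObject(out)
    out
  } else f(as.numeric(peaklist))
}

#' Align a set of peak lists by quadratic warping
#'
#' Builds a reference peak set from masses that occur (within the relative
#' tolerance) in at least `minPeakFrequency` of the spectra, then warps every
#' peak list onto it with its own fitted [WarpModel-class]. If no reference
#' peak qualifies, the input is returned unchanged with a warning.
#'
#' @param peaklists list of [MassPeaks-class] (>= 2).
#' @param tolerance relative mass tolerance (default 0.002).
#' @param minPeakFrequency fraction of spectra a reference peak must appear
#'   in (default 0.9).
#' @return list with `peaklists` (aligned) and `reference` (a
#'   [MassPeaks-class]).
#' @export
alignSpectra <- function(peaklists, tolerance = 0.002, minPeakFrequency = 0.9) {
  stopifnot(length(peaklists) >= 2L,
            all(vapply(peaklists, is, logical(1), "MassPeaks")))
  allmz <- unlist(lapply(peaklists, mz))
  src <- rep(seq_along(peaklists), vapply(peaklists, function(p)
    length(p@mz), integer(1)))
  if (!length(allmz)) {
    warnf("no peaks at all; alignment skipped")
    return(list(peaklists = peaklists, reference = MassPeaks()))
  }
  cl <- clusterMasses(allmz, tolerance)
  refmass <- refcount <- numeric(0)
  for (id in unique(cl)) {
    sel <- cl == id
    nspec <- length(unique(src[sel]))
    if (nspec >= minPeakFrequency * length(peaklists)) {
      refmass <- c(refmass, mean(allmz[sel]))
      refcount <- c(refcount, nspec)
    }
  }
  if (!length(refmass)) {
    warnf("no reference peaks at frequency >= %.2f; alignment skipped",
          minPeakFrequency)
    return(list(peaklists = peaklists, reference = MassPeaks()))
  }
  ref <- MassPeaks(mz = sort(refmass),
                   intensity = rep(NA_real_, length(refmass)),
                   source = "alignment-reference")
  aligned <- lapply(peaklists, function(p) {
    w <- suppressWarnings(fitWarp(p, ref, tolerance))
    applyWarp(w, p)
  })
  list(peaklists = aligned, reference = ref)
}

#' Average technical replicates into a main spectrum profile
#'
#' Clusters the peaks of a sample's aligned replicate peak lists within the
#' relative mass tolerance; clusters represented in fewer than
#' `ceiling(minFrequency * R)` replicates are dropped. A retained peak's mass
#' is the mean of its members' masses and its intensity the mean over all `R`
#' replicates, replicates lacking the peak contributing zero. Where one
#' replicate contributes several peaks to a cluster only the strongest
#' counts.
#'
#' @param peaklists list of 1-6 [MassPeaks-class] replicates of one sample.
#' @param minFrequency minimum fraction of replicates a peak must appear in
#'   (default 0.25).
#' @param tolerance relative mass tolerance for clustering (default 0.002).
#' @param source identifier for the resulting profile.
#' @return A [MainSpectrumProfile-class].
#' @export
averageReplicates <- function(peaklists, minFrequency = 0.25,
                              tolerance = 0.002, source = NA_character_) {
  if (!length(peaklists)) stopf("no replicate peak lists supplied")
  stopifnot(all(vapply(peaklists, is, logical(1), "MassPeaks")),
            length(peaklists) <= 6L)
  R <- length(peaklists)
  allmz <- unlist(lapply(peaklists, mz))
  allint <- unlist(lapply(peaklists, intensity))
  allsnr <- unlist(lapply(peaklists, peakSNR))
  rep_ <- rep(seq_len(R), vapply(peaklists, function(p) length(p@mz),
                                 integer(1)))
  if (!length(allmz))
    return(new("MainSpectrumProfile", MassPeaks(source = source),
               replicateCount = as.integer(R)))
  cl <- clusterMasses(allmz, tolerance)
  need <- ceiling(minFrequency * R)
  mzs <- ints <- snrs <- numeric(0)
  for (id in unique(cl)) {
    sel <- which(cl == id)
    ## strongest peak per replicate within the cluster
    best <- sel[order(rep_[sel], -allint[sel])]
    best <- best[!duplicated(rep_[best])]
    if (length(best) < need) next
    mzs <- c(mzs, mean(allmz[best]))
    ints <- c(ints, sum(allint[best]) / R)
    snrs <- c(snrs, mean(allsnr[best]))
  }
  pk <- MassPeaks(mz = mzs, intensity = ints, snr = snrs, source = source)
  new("MainSpectrumProfile", pk, replicateCount = as.integer(R))
}

#' Per-replicate preprocessing chain
#'
#' Convenience wrapper running QC, smoothing, SNIP baseline correction, TIC
#' normalisation and peak detection on one raw spectrum, with the defaults of
#' the individual steps.
#'
#' @param spectrum raw [MassSpectrum-class].
#' @param halfWindow smoothing / peak-picking half window (points).
#' @param iterations SNIP iterations.
#' @param snrThreshold peak SNR threshold.
#' @param minMaxIntensity,minSpectrumSNR QC thresholds; see [qcSpectrum()].
#' @return list with `accept`, `reasons`, and (when accepted) `peaks`
#'   (a [MassPeaks-class]) and `corrected` (the processed trace).
#' @export
preprocessSpectrum <- function(spectrum, halfWindow = 8, iterations = 100,
                               snrThreshold = 3, minMaxIntensity = 1e4,
                               minSpectrumSNR = 3) {
  qc <- qcSpectrum(spectrum, minMaxIntensity, minSpectrumSNR, iterations)
  if (!qc$accept) return(list(accept = FALSE, reasons = qc$reasons))
  sm <- smoothSpectrum(spectrum, halfWindow)
  bc <- snipBaseline(sm, iterations)$corrected
  tn <- ticNormalize(bc)
  pk <- detectPeaks(tn, halfWindow, snrThreshold)
  list(accept = TRUE, reasons = character(), peaks = pk, corrected = tn)
}
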