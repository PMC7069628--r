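#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the spectral containers: `mz()` and
#' `intensity()` return the mass and intensity vectors of a
#' [MassSpectrum-class] or [MassPeaks-class]; `peakSNR()` the per-peak
#' signal-to-noise ratios; `spectrumMetadata()` the acquisition metadata
#' list; `replicateCount()` the number of technical replicates behind a
#' [MainSpectrumProfile-class].
#'
#' @param object a `MassSpectrum`, `MassPeaks` or `MainSpectrumProfile`.
#' @return A numeric vector (`mz`, `intensity`, `peakSNR`), a list
#'   (`spectrumMetadata`) or an integer (`replicateCount`).
#' @name accessors
#' @aliases mz intensity peakSNR spectrumMetadata replicateCount
#' @examples
#' s <- MassSpectrum(mz = c(2000, 2004), intensity = c(0, 5))
#' mz(s)
#' intensity(s)
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(object) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("peakSNR", function(object) standardGeneric("peakSNR"))

#' @rdname accessors
#' @export
setGeneric("spectrumMetadata", function(object) standardGeneric("spectrumMetadata"))

#' @rdname accessors
#' @export
setGeneric("replicateCount", function(object) standardGeneric("replicateCount"))
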