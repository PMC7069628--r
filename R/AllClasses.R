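#' Container for one raw or processed mass spectrum
#'
#' A `MassSpectrum` holds the (m/z, intensity) trace of a single technical
#' replicate acquired in linear mode, together with acquisition metadata
#' (subject id, sample type, replicate index). m/z values are in daltons and
#' must be strictly increasing; intensities are non-negative arbitrary units.
#'
#' @slot mz numeric, strictly increasing mass-to-charge values (Da).
#' @slot intensity numeric, non-negative intensities (AU), same length as `mz`.
#' @slot metadata list; recognised entries are `subject`, `sampleType`
#'   (one of `"saliva"`, `"gcf"`, `"plaque"`), `replicate` (1..6).
#'
#' @seealso [MassSpectrum()] for construction, [readSpectrum()] for file input.
#' @export
setClass("MassSpectrum",
  representation(mz = "numeric", intensity = "numeric", metadata = "list"),
  prototype(mz = numeric(), intensity = numeric(), metadata = list())
)

setValidity("MassSpectrum", function(object) {
  msgs <- character()
  if (length(object@mz) != length(object@intensity))
    msgs <- c(msgs, "mz and intensity must have equal length")
  if (length(object@mz) < 2L)
    msgs <- c(msgs, "a spectrum needs at least 2 points")
  if (anyNA(object@mz) || anyNA(object@intensity))
    msgs <- c(msgs, "mz and intensity must not contain NA")
  else {
    if (length(object@mz) >= 2L && any(diff(object@mz) <= 0))
      msgs <- c(msgs, "mz must be strictly increasing")
    if (any(object@intensity < 0))
      msgs <- c(msgs, "intensity must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' @param mz,intensity,metadata see slots.
#' @rdname MassSpectrum-class
#' @export
MassSpectrum <- function(mz, intensity, metadata = list()) {
  new("MassSpectrum", mz = as.numeric(mz), intensity = as.numeric(intensity),
      metadata = metadata)
}

#' Detected peaks of one spectrum or profile
#'
#' `MassPeaks` stores peak positions, intensities and signal-to-noise ratios
#' after peak picking. Positions are strictly increasing.
#'
#' @slot mz numeric, peak masses (Da), strictly increasing.
#' @slot intensity numeric, peak intensities (AU, possibly TIC-relative).
#' @slot snr numeric, per-peak signal-to-noise ratio.
#' @slot source character(1), identifier of the originating spectrum/profile.
#' @export
setClass("MassPeaks",
  representation(mz = "numeric", intensity = "numeric", snr = "numeric",
                 source = "character"),
  prototype(mz = numeric(), intensity = numeric(), snr = numeric(),
            source = NA_character_)
)

setValidity("MassPeaks", function(object) {
  msgs <- character()
  n <- length(object@mz)
  if (length(object@intensity) != n || length(object@snr) != n)
    msgs <- c(msgs, "mz, intensity and snr must have equal length")
  if (n >= 2L && any(diff(object@mz) <= 0))
    msgs <- c(msgs, "peak mz must be strictly increasing")
  if (n > 0L && !anyNA(object@intensity) && any(object@intensity < 0))
    msgs <- c(msgs, "peak intensity must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @param mz,intensity,snr,source see slots.
#' @rdname MassPeaks-class
#' @export
MassPeaks <- function(mz = numeric(), intensity = numeric(),
                      snr = rep(NA_real_, length(mz)),
                      source = NA_character_) {
  o <- order(mz)
  new("MassPeaks", mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o],
      snr = as.numeric(snr)[o], source = as.character(source)[1L])
}

#' Main spectrum profile (MSP)
#'
#' Consensus peak list of one sample, obtained by averaging the peak lists of
#' its aligned technical replicates: peaks seen in too few replicates are
#' dropped, and each retained peak's intensity is the mean over all
#' replicates (replicates lacking the peak contribute zero).
#'
#' @slot replicateCount integer(1), number of replicates averaged (1..6).
#' @seealso [averageReplicates()]
#' @export
setClass("MainSpectrumProfile",
  contains = "MassPeaks",
  representation(replicateCount = "integer"),
  prototype(replicateCount = 1L)
)

setValidity("MainSpectrumProfile", function(object) {
  if (length(object@replicateCount) != 1L || is.na(object@replicateCount) ||
      object@replicateCount < 1L)
    "replicateCount must be a single positive integer"
  else TRUE
})

#' Quadratic mass-warp model
#'
#' Correction `m' = a0 + a1 m + a2 m^2` mapping observed to reference masses,
#' fitted from matched landmark peaks. A model fitted from fewer than three
#' anchors degrades to the identity and carries `identity = TRUE`.
#'
#' @slot coefficients numeric(3), `(a0, a1, a2)`.
#' @slot nAnchors integer(1), number of matched landmark peaks.
#' @slot identity logical(1), `TRUE` when the model is the identity fallback.
#' @seealso [fitWarp()], [applyWarp()]
#' @export
setClass("WarpModel",
  representation(coefficients = "numeric", nAnchors = "integer",
                 identity = "logical"),
  prototype(coefficients = c(0, 1, 0), nAnchors = 0L, identity = TRUE)
)

setValidity("WarpModel", function(object) {
  if (length(object@coefficients) != 3L || anyNA(object@coefficients))
    "coefficients must be numeric(3) without NA"
  else TRUE
})

#' Binned peak intensity matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the binned
#' peak intensities: rows are peak bins (with reference mass `binMass` in
#' `rowData`), columns are samples (subject x sample type, with `subject`,
#' `sampleType` and `group` in `colData`). The `"intensity"` assay holds MSP
#' intensities (0 when a sample lacks the peak); [dichotomize()] adds a
#' `"binary"` assay.
#'
#' @seealso [buildIntensityMatrix()], [binPeaks()]
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("PeakMatrix", contains = "SummarizedExperiment")

setValidity("PeakMatrix", function(object) {
  msgs <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!"binMass" %in% colnames(rd))
    msgs <- c(msgs, "rowData must contain 'binMass'")
  else {
    bm <- rd$binMass
    if (length(bm) >= 2L && any(diff(bm) <= 0))
      msgs <- c(msgs, "binMass must be strictly increasing")
  }
  if ("intensity" %in% SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(a < 0, na.rm = TRUE))
      msgs <- c(msgs, "intensities must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary decision tree over peak features
#'
#' A gain-ratio (C4.5-style) binary classification tree over dichotomised
#' peak features. `root` is a recursive list of nodes; internal nodes carry
#' `feature` (the bin reference mass as a string), an `absent` (value 0) and
#' `present` (value 1) child; leaves carry `class` and the training class
#' counts. `meta` records the sample type, training size and parameters.
#'
#' @slot root list, recursive node structure.
#' @slot meta list, training metadata.
#' @seealso [trainTree()], [predictTree()], [writeTree()]
#' @export
setClass("PeakTree",
  representation(root = "list", meta = "list"),
  prototype(root = list(), meta = list())
)
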