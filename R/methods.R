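#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("mz", "MassSpectrum", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("mz", "MassPeaks", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("intensity", "MassSpectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("intensity", "MassPeaks", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("peakSNR", "MassPeaks", function(object) object@snr)

#' @rdname accessors
#' @export
setMethod("spectrumMetadata", "MassSpectrum", function(object) object@metadata)

#' @rdname accessors
#' @export
setMethod("replicateCount", "MainSpectrumProfile",
          function(object) object@replicateCount)

#' @param object a `MassSpectrum`.
#' @rdname MassSpectrum-class
#' @export
setMethod("show", "MassSpectrum", function(object) {
  md <- object@metadata
  cat(sprintf("MassSpectrum: %d points, m/z %.1f-%.1f Da\n",
              length(object@mz), min(object@mz), max(object@mz)))
  if (length(md))
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                    collapse = ", "), "\n", sep = "")
  invisible(object)
})

#' @param object a `MassPeaks`.
#' @rdname MassPeaks-class
#' @export
setMethod("show", "MassPeaks", function(object) {
  cat(sprintf("MassPeaks: %d peaks", length(object@mz)))
  if (length(object@mz))
    cat(sprintf(", m/z %.1f-%.1f Da", min(object@mz), max(object@mz)))
  if (!is.na(object@source)) cat(" [", object@source, "]", sep = "")
  cat("\n")
  invisible(object)
})

#' @param object a `MainSpectrumProfile`.
#' @rdname MainSpectrumProfile-class
#' @export
setMethod("show", "MainSpectrumProfile", function(object) {
  cat(sprintf("MainSpectrumProfile: %d peaks from %d replicate(s)",
              length(object@mz), object@replicateCount))
  if (!is.na(object@source)) cat(" [", object@source, "]", sep = "")
  cat("\n")
  invisible(object)
})

#' @param object a `WarpModel`.
#' @rdname WarpModel-class
#' @export
setMethod("show", "WarpModel", function(object) {
  co <- object@coefficients
  cat(sprintf("WarpModel: m' = %.6g + %.8g m + %.3g m^2 (%d anchors%s)\n",
              co[1], co[2], co[3], object@nAnchors,
              if (object@identity) ", identity fallback" else ""))
  invisible(object)
})

#' @param object a `PeakTree`.
#' @rdname PeakTree-class
#' @export
setMethod("show", "PeakTree", function(object) {
  cat(sprintf("PeakTree (%s): %d leaves, depth %d, trained on n = %s\n",
              if (is.null(object@meta$sampleType)) "?" else object@meta$sampleType,
              treeLeafCount(object@root), treeDepth(object@root),
              if (is.null(object@meta$n)) "?" else object@meta$n))
  showNode(object@root, indent = "  ")
  invisible(object)
})

showNode <- function(node, indent = "") {
  if (isTRUE(node$leaf)) {
    cat(indent, "-> ", node$class, " (", paste(node$counts, collapse = "/"),
        ")\n", sep = "")
  } else {
    cat(indent, "m/z ", node$feature, " absent:\n", sep = "")
    showNode(node$absent, paste0(indent, "  "))
    cat(indent, "m/z ", node$feature, " present:\n", sep = "")
    showNode(node$present, paste0(indent, "  "))
  }
}

treeLeafCount <- function(node) {
  if (isTRUE(node$leaf)) 1L
  else treeLeafCount(node$absent) + treeLeafCount(node$present)
}

treeDepth <- function(node) {
  if (isTRUE(node$leaf)) 0L
  else 1L + max(treeDepth(node$absent), treeDepth(node$present))
}
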