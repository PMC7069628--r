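#' Read a single mass spectrum
#'
#' Reads one replicate spectrum either from two-column text (m/z, intensity;
#' tab- or whitespace-separated, optional header) or from an mzML file (first
#' spectrum; via \pkg{mzR}). Unsorted m/z values are sorted with a warning;
#' exact duplicate masses are an error.
#'
#' @param path file path.
#' @param format `"tsv"` (native two-column text) or `"mzml"`.
#' @param metadata optional list of acquisition metadata (subject, sampleType,
#'   replicate) attached to the returned object.
#' @return A [MassSpectrum-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("2000\t0.0", "2001\t5.0"), f)
#' readSpectrum(f)
#' @export
readSpectrum <- function(path, format = c("tsv", "mzml"), metadata = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (format == "tsv") {
    dat <- tryCatch(
      utils::read.table(path, header = FALSE, colClasses = "character",
                        comment.char = "#", blank.lines.skip = TRUE),
      error = function(e) stopf("cannot parse '%s' as two-column text: %s",
                                path, conditionMessage(e)))
    if (ncol(dat) < 2L)
      stopf("'%s': expected 2 columns, found %d", path, ncol(dat))
    ## tolerate a single header line of non-numeric tokens
    first <- suppressWarnings(as.numeric(dat[1L, 1:2]))
    if (anyNA(first)) dat <- dat[-1L, , drop = FALSE]
    mzv <- suppressWarnings(as.numeric(dat[[1L]]))
    iv <- suppressWarnings(as.numeric(dat[[2L]]))
    if (anyNA(mzv) || anyNA(iv)) {
      bad <- which(is.na(mzv) | is.na(iv))[1L]
      stopf("'%s': non-numeric value at data line %d", path, bad)
    }
  } else {
    h <- mzR::openMSfile(path)
    on.exit(mzR::close(h))
    pk <- mzR::peaks(h, 1L)
    mzv <- pk[, 1L]
    iv <- pk[, 2L]
  }
  if (anyDuplicated(mzv))
    stopf("'%s': duplicate m/z value(s), e.g. %.6g", path,
          mzv[duplicated(mzv)][1L])
  if (is.unsorted(mzv, strictly = TRUE)) {
    warnf("'%s': m/z not sorted; re-sorting", path)
    o <- order(mzv)
    mzv <- mzv[o]
    iv <- iv[o]
  }
  if (any(iv < 0))
    stopf("'%s': negative intensity at m/z %.6g", path, mzv[which(iv < 0)[1L]])
  MassSpectrum(mz = mzv, intensity = iv, metadata = metadata)
}

#' Write a spectrum as two-column text
#'
#' Writes the native tab-separated (m/z, intensity) representation with a
#' header line and full double precision (15 significant digits), so that
#' [readSpectrum()] round-trips the arrays.
#'
#' @param spectrum a [MassSpectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "MassSpectrum"))
  validObject(spectrum)
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines("mz\tintensity", con)
  writeLines(sprintf("%.15g\t%.15g", spectrum@mz, spectrum@intensity), con)
  invisible(path)
}

#' Read a sample manifest
#'
#' Reads the tab-separated manifest that maps spectrum files to samples.
#' Required columns: `file`, `subject`, `sample_type`, `replicate`; optional
#' `group`. When `group` is missing all labels become `"unknown"` (blinded
#' mode). Sample types must be saliva/gcf/plaque; (subject, sample type,
#' replicate) must be unique with 1-6 replicates per sample.
#'
#' @param path TSV path with header row.
#' @return A `data.frame` with columns file, subject, sample_type, replicate,
#'   group.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("file", "subject", "sample_type", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("manifest misses column(s): %s", paste(miss, collapse = ", "))
  if (!"group" %in% names(df)) df$group <- "unknown"
  df$group[is.na(df$group) | df$group == ""] <- "unknown"
  df$subject <- as.character(df$subject)
  df$replicate <- as.integer(df$replicate)
  checkSampleType(df$sample_type)
  checkGroup(df$group)
  key <- paste(df$subject, df$sample_type, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (subject, sample type, replicate): %s",
          gsub("\r", "/", key[duplicated(key)][1L]))
  reps <- tapply(df$replicate, paste(df$subject, df$sample_type, sep = "\r"),
                 length)
  if (any(reps > 6L))
    stopf("more than 6 replicates for sample %s",
          gsub("\r", "/", names(reps)[which(reps > 6L)[1L]]))
  if (any(df$replicate < 1L | df$replicate > 6L, na.rm = TRUE))
    stopf("replicate index must be in 1..6")
  ## one group per subject
  g <- tapply(df$group, df$subject, function(x) length(unique(x)))
  if (any(g > 1L))
    stopf("subject %s has conflicting group labels", names(g)[which(g > 1L)[1L]])
  df[, c("file", "subject", "sample_type", "replicate", "group")]
}

#' Write / read a binned intensity matrix as TSV
#'
#' The on-disk layout has samples as rows: the columns `sample`, `subject`,
#' `sample_type`, `group`, then one numeric column per bin named by its
#' reference mass (Da, 9 significant digits).
#'
#' @param pm a [PeakMatrix-class].
#' @param path TSV path.
#' @return `writeIntensityMatrix`: `path` invisibly; `readIntensityMatrix`:
#'   a [PeakMatrix-class] with an `"intensity"` assay.
#' @export
writeIntensityMatrix <- function(pm, path) {
  stopifnot(is(pm, "PeakMatrix"))
  a <- SummarizedExperiment::assay(pm, "intensity")
  cd <- SummarizedExperiment::colData(pm)
  out <- data.frame(sample = colnames(pm),
                    subject = cd$subject,
                    sample_type = cd$sampleType,
                    group = cd$group,
                    t(a), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[-(1:4)] <-
    sprintf("%.9g", SummarizedExperiment::rowData(pm)$binMass)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensityMatrix
#' @export
readIntensityMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  idcols <- c("sample", "subject", "sample_type", "group")
  miss <- setdiff(idcols, names(df))
  if (length(miss))
    stopf("matrix TSV misses column(s): %s", paste(miss, collapse = ", "))
  binMass <- as.numeric(setdiff(names(df), idcols))
  a <- t(as.matrix(df[, setdiff(names(df), idcols), drop = FALSE]))
  colnames(a) <- df$sample
  newPeakMatrix(a, binMass = binMass,
                colData = data.frame(subject = df$subject,
                                     sampleType = df$sample_type,
                                     group = df$group,
                                     row.names = df$sample,
                                     stringsAsFactors = FALSE))
}

## internal constructor: assay rows = bins, cols = samples
newPeakMatrix <- function(intensity, binMass, colData,
                          binary = NULL, rowExtra = NULL) {
  o <- order(binMass)
  intensity <- intensity[o, , drop = FALSE]
  binMass <- binMass[o]
  rn <- sprintf("%.9g", binMass)
  rownames(intensity) <- rn
  assays <- list(intensity = intensity)
  if (!is.null(binary)) {
    binary <- binary[o, , drop = FALSE]
    rownames(binary) <- rn
    assays$binary <- binary
  }
  rd <- S4Vectors::DataFrame(binMass = binMass, row.names = rn)
  if (!is.null(rowExtra))
    for (nm in names(rowExtra)) rd[[nm]] <- rowExtra[[nm]][o]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd, colData = S4Vectors::DataFrame(colData))
  new("PeakMatrix", se)
}

#' Serialize / restore a decision tree as JSON
#'
#' Trees are written as nested JSON objects (internal nodes: `feature`,
#' `absent`, `present`; leaves: `class`, `counts`), plus the training
#' metadata, so a fitted diagnostic tree is portable and auditable.
#'
#' @param tree a [PeakTree-class].
#' @param path JSON path.
#' @return `writeTree`: `path`, invisibly. `readTree`: a [PeakTree-class].
#' @export
writeTree <- function(tree, path) {
  stopifnot(is(tree, "PeakTree"))
  jsonlite::write_json(list(meta = tree@meta, root = tree@root), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTree
#' @export
readTree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (node$leaf) {
      node$counts <- unlist(node$counts)
    } else {
      node$absent <- fix(node$absent)
      node$present <- fix(node$present)
    }
    node
  }
  new("PeakTree", root = fix(x$root), meta = x$meta)
}
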