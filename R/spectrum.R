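# Centroid spectra: one sorted (m/z, intensity) peak list per well and
# polarity, plus the nearest-peak query primitive used by calibration and
# screening.

#' Centroid spectrum
#'
#' Constructs a validated centroided spectrum for one plate well: a strictly
#' increasing m/z vector with non-negative peak heights, a polarity and a
#' well identifier. "Peak height" throughout the package means this stored
#' centroid intensity; no area integration is performed.
#'
#' @param mz Numeric vector of m/z values in Da.
#' @param intensity Numeric vector of peak heights (same length, all
#'   `>= 0`).
#' @param polarity `"positive"` or `"negative"`.
#' @param well_id Well identifier string.
#' @param sort If `TRUE` (default) unsorted input is sorted with a warning;
#'   if `FALSE`, unsorted input is an error.
#' @return A `centroid_spectrum` object.
#' @export
#' @examples
#' centroid_spectrum(c(100, 200), c(5, 7), "positive", "W01")
centroid_spectrum <- function(mz, intensity, polarity = c("positive", "negative"),
                              well_id = "", sort = TRUE) {
  polarity <- match.arg(polarity)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite m/z or intensity", call. = FALSE)
  if (any(intensity < 0))
    stop("negative intensities", call. = FALSE)
  if (is.unsorted(mz, strictly = FALSE)) {
    if (!sort) stop("m/z values are not sorted", call. = FALSE)
    warning("unsorted peak list; sorting by m/z", call. = FALSE)
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
  }
  structure(list(mz = mz, intensity = intensity, polarity = polarity,
                 well_id = as.character(well_id)),
            class = "centroid_spectrum")
}

#' @export
print.centroid_spectrum <- function(x, ...) {
  cat("<centroid spectrum> well '", x$well_id, "' (", x$polarity, "), ",
      length(x$mz), " peaks", sep = "")
  if (length(x$mz))
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}

#' @export
length.centroid_spectrum <- function(x) length(x$mz)

#' Read / write a centroided spectrum
#'
#' Two dialects are supported. `"tsv"` is a plain-text peak list: two numeric
#' columns (m/z, intensity), tab- or comma-separated, `#` comment lines
#' allowed; polarity is not stored in the file and must be supplied (usually
#' from the plate manifest). `"mzML"` goes through the `mzR` library; the
#' spectrum must be centroided (profile data is an error) and polarity is
#' taken from the file metadata. Duplicate m/z rows are kept as-is: the
#' reader is faithful and never merges peaks.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"mzML"`; default guesses from the file
#'   extension.
#' @param polarity Polarity for TSV input (ignored for mzML).
#' @param well_id Well identifier; defaults to the file base name.
#' @return [read_spectrum()]: a `centroid_spectrum`.
#' @export
read_spectrum <- function(path, dialect = c("auto", "tsv", "mzML"),
                          polarity = c("positive", "negative"),
                          well_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (tolower(tools::file_ext(path)) == "mzml") "mzML" else "tsv"
  if (is.null(well_id))
    well_id <- tools::file_path_sans_ext(basename(path))
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    polarity <- match.arg(polarity)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) == 0L)
      return(centroid_spectrum(numeric(0), numeric(0), polarity, well_id))
    parts <- strsplit(lines, "[\t,]")
    if (any(lengths(parts) < 2L))
      stop("malformed peak list: ", path, call. = FALSE)
    mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
    inten <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(mz) || anyNA(inten))
      stop("non-numeric peak values in ", path, call. = FALSE)
    centroid_spectrum(mz, inten, polarity, well_id)
  } else {
    fh <- mzR::openMSfile(path)
    on.exit(mzR::close(fh))
    hdr <- mzR::header(fh)
    if (nrow(hdr) < 1L) stop("no spectra in ", path, call. = FALSE)
    if (isFALSE(hdr$centroided[1L]))
      stop("profile-mode mzML not supported; centroid first: ", path,
           call. = FALSE)
    pk <- mzR::peaks(fh, 1L)
    polarity <- if (!is.na(hdr$polarity[1L]) && hdr$polarity[1L] == 0L)
      "negative" else "positive"
    centroid_spectrum(pk[, 1L], pk[, 2L], polarity, well_id)
  }
}

#' @param s A `centroid_spectrum`.
#' @rdname read_spectrum
#' @return [write_spectrum()]: `path`, invisibly.
#' @export
write_spectrum <- function(s, path, dialect = c("auto", "tsv", "mzML")) {
  stopifnot(inherits(s, "centroid_spectrum"))
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (tolower(tools::file_ext(path)) == "mzml") "mzML" else "tsv"
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# centroid spectrum well=%s polarity=%s",
                         s$well_id, s$polarity),
                 sprintf("%.6f\t%.6f", s$mz, s$intensity)), con)
  } else {
    n <- length(s$mz)
    hdr <- data.frame(
      seqNum = 1L, acquisitionNum = 1L, msLevel = 1L,
      polarity = if (s$polarity == "positive") 1L else 0L,
      peaksCount = n, totIonCurrent = sum(s$intensity),
      retentionTime = 0, basePeakMZ = if (n) s$mz[which.max(s$intensity)] else 0,
      basePeakIntensity = if (n) max(s$intensity) else 0,
      collisionEnergy = NA_real_, ionisationEnergy = 0,
      lowMZ = if (n) min(s$mz) else 0, highMZ = if (n) max(s$mz) else 0,
      precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
      precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
      mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = "scan=1", centroided = TRUE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = NA_real_,
      isolationWindowLowerOffset = NA_real_,
      isolationWindowUpperOffset = NA_real_,
      scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
      stringsAsFactors = FALSE)
    mzR::writeMSData(list(cbind(mz = s$mz, intensity = s$intensity)),
                     file = path, header = hdr)
  }
  invisible(path)
}

#' Nearest peak within a mass tolerance
#'
#' The spectrum query primitive behind calibration-reference matching and
#' exact-mass screening: among peaks within `target_mz +/- tol`, returns the
#' one minimising the absolute mass deviation. Ties on distance are broken
#' towards the higher intensity, then the lower m/z. Total on any input:
#' an empty spectrum or an empty tolerance window yields `NULL`.
#'
#' @param s A `centroid_spectrum`.
#' @param target_mz Target m/z in Da.
#' @param tol Tolerance in Da (`> 0`); screening uses 0.005 Da (5 mDa).
#' @return `list(mz=, intensity=, index=)` or `NULL` when no peak qualifies.
#' @export
#' @examples
#' s <- centroid_spectrum(c(249.0320, 300), c(10, 5), "negative")
#' nearest_peak(s, 249.0317, 0.005)
nearest_peak <- function(s, target_mz, tol) {
  stopifnot(inherits(s, "centroid_spectrum"), tol > 0)
  n <- length(s$mz)
  if (n == 0L) return(NULL)
  lo <- findInterval(target_mz - tol, s$mz) + 1L
  hi <- findInterval(target_mz + tol, s$mz)
  if (lo > hi) return(NULL)
  idx <- lo:hi
  d <- abs(s$mz[idx] - target_mz)
  keep <- d <= tol
  if (!any(keep)) return(NULL)
  idx <- idx[keep]
  d <- d[keep]
  # order: distance, then -intensity, then m/z
  best <- idx[order(d, -s$intensity[idx], s$mz[idx])][1L]
  list(mz = s$mz[best], intensity = s$intensity[best], index = best)
}
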