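# Centroided spectra and peak-list input/output.

#' Construct a centroided spectrum
#'
#' @param mz Numeric m/z values (Th), all `> 0`.
#' @param intensity Non-negative intensities (arbitrary units).
#' @param level Measurement tier: `"MS1"` (intact complex), `"MS2"` (ejected
#'   subunits) or `"MS3"` (backbone fragments).
#' @param metadata Free-form key/value list.
#' @return An object of class `ntdms_spectrum`: a list with `peaks`
#'   (data.frame `mz`, `intensity`, sorted by m/z; peaks closer than 1e-6 Th
#'   are merged by summing intensity), `level` and `metadata`.
#' @export
ms_spectrum <- function(mz = numeric(0), intensity = numeric(0),
                     level = c("MS1", "MS2", "MS3"), metadata = list()) {
  level <- match.arg(level)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (any(mz <= 0)) stop("m/z values must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (length(mz) > 1) {
    # merge duplicates closer than 1e-6 Th by summing intensity
    grp <- cumsum(c(TRUE, diff(mz) > 1e-6))
    newmz <- as.numeric(tapply(mz, grp, mean))
    intensity <- as.numeric(tapply(intensity, grp, sum))
    mz <- newmz
  }
  structure(list(peaks = data.frame(mz = mz, intensity = intensity),
                 level = level, metadata = metadata),
            class = "ntdms_spectrum")
}

#' @export
print.ntdms_spectrum <- function(x, ...) {
  cat(sprintf("<%s spectrum: %d peaks", x$level, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    cat(sprintf(", m/z %.2f-%.2f", min(x$peaks$mz), max(x$peaks$mz)))
  }
  cat(">\n")
  invisible(x)
}

#' Read a two-column peak list
#'
#' Reads whitespace- or tab-separated text with two numeric columns (m/z,
#' intensity); `#` starts a comment. A malformed line raises an error naming
#' the line number; an empty file yields an empty spectrum with a warning.
#'
#' @param path Input path.
#' @inheritParams ms_spectrum
#' @return An [ms_spectrum()] object.
#' @export
read_peaklist <- function(path, level = c("MS1", "MS2", "MS3")) {
  level <- match.arg(level)
  lines <- readLines(path)
  lines_clean <- sub("#.*$", "", lines)
  keep <- which(trimws(lines_clean) != "")
  if (!length(keep)) {
    warning("empty peak list: ", path, call. = FALSE)
    return(ms_spectrum(level = level, metadata = list(source = path)))
  }
  toks <- strsplit(trimws(lines_clean[keep]), "[[:space:]]+")
  vals <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (length(v) != 2 || anyNA(v)) {
      stop("malformed peak-list line ", keep[i], " in ", path, ": '",
           lines[keep[i]], "'", call. = FALSE)
    }
    v
  })
  m <- do.call(rbind, vals)
  ms_spectrum(m[, 1], m[, 2], level = level, metadata = list(source = path))
}

#' Write a peak list in canonical form
#'
#' Writes m/z to 5 decimals and intensity to 3, tab-separated, so that
#' write-read-write round trips are byte-identical.
#'
#' @param spec An [ms_spectrum()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spec, path) {
  lines <- sprintf("%.5f\t%.3f", spec$peaks$mz, spec$peaks$intensity)
  writeLines(lines, path)
  invisible(path)
}

#' Read centroided spectra from an mzML file
#'
#' Uses the `mzR` package (Suggests) to read centroided scans. Intended for
#' interoperability; tab-separated peak lists are the package's primary
#' format.
#'
#' @param path mzML file path.
#' @param level Spectrum level to stamp on the returned objects.
#' @param scans Scan indices to read; `NULL` reads all.
#' @return A list of [ms_spectrum()] objects.
#' @export
read_mzml <- function(path, level = c("MS1", "MS2", "MS3"), scans = NULL) {
  level <- match.arg(level)
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  n <- nrow(mzR::header(handle))
  if (is.null(scans)) scans <- seq_len(n)
  lapply(scans, function(i) {
    pk <- mzR::peaks(handle, i)
    ms_spectrum(pk[, 1], pk[, 2], level = level,
             metadata = list(source = path, scan = i))
  })
}

#' Suppress a periodic background peak series
#'
#' Optional pre-filter for lipid-cluster background: removes runs of at
#' least `min_run` peaks whose consecutive m/z spacings match a configured
#' repeat mass within `tol`. Off by default in the pipeline, since such
#' background is normally handled instrumentally.
#'
#' @param spec An [ms_spectrum()] object.
#' @param spacing Repeat spacing in Th (e.g. a lipid monomer mass).
#' @param tol Spacing tolerance in Th.
#' @param min_run Minimum number of consecutive peaks forming a series.
#' @return The filtered [ms_spectrum()].
#' @export
remove_periodic_series <- function(spec, spacing, tol = 0.25, min_run = 3) {
  pk <- spec$peaks
  if (nrow(pk) < min_run) return(spec)
  gaps <- diff(pk$mz)
  periodic_gap <- abs(gaps - spacing) <= tol
  run <- rle(periodic_gap)
  drop <- logical(nrow(pk))
  pos <- cumsum(c(1, run$lengths))
  for (k in seq_along(run$lengths)) {
    if (run$values[k] && run$lengths[k] >= (min_run - 1)) {
      drop[pos[k]:(pos[k] + run$lengths[k])] <- TRUE
    }
  }
  ms_spectrum(pk$mz[!drop], pk$intensity[!drop], level = spec$level,
           metadata = spec$metadata)
}
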