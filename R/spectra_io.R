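#' @title Spectrum input and per-file processing
#' @description Readers for centroided spectra (mzML via mzR, or a simple
#'   two-column TSV peak-list dialect), consolidation of per-scan centroids
#'   into one peak list per infusion ("mass traces"), and normalization of
#'   intensities to total usable signal.
#' @name spectra_io
NULL

#' Construct a sample peak list
#'
#' A sample peak list holds one file's (m/z, intensity) peaks together with
#' its manifest metadata and a flag recording whether intensities have been
#' normalized to total usable signal.
#'
#' @param peaks data.frame with numeric columns `mz` (> 0) and
#'   `intensity` (>= 0); re-sorted ascending by mz.
#' @param meta optional named list or one-row data.frame of manifest metadata
#'   (sample_id, document_id, author, substrate, replicate, is_blank).
#' @param normalized logical; TRUE once intensities sum to 1000.
#' @return object of class `sample_peaklist`.
#' @export
sample_peaklist <- function(peaks, meta = NULL, normalized = FALSE) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  peaks <- peaks[, c("mz", "intensity"), drop = FALSE]
  if (nrow(peaks)) {
    if (!all(is.finite(peaks$mz)) || !all(is.finite(peaks$intensity)))
      stop("peaks must be finite")
    if (any(peaks$mz <= 0)) stop("mz values must be positive")
    if (any(peaks$intensity < 0)) stop("intensities must be non-negative")
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(meta = meta, peaks = peaks, normalized = isTRUE(normalized)),
            class = "sample_peaklist")
}

#' @export
print.sample_peaklist <- function(x, ...) {
  id <- if (!is.null(x$meta$sample_id)) x$meta$sample_id else "<unnamed>"
  cat(sprintf("sample_peaklist '%s': %d peaks, %s\n", id, nrow(x$peaks),
              if (x$normalized) "normalized (TUS = 1000)" else "raw intensities"))
  invisible(x)
}

#' Read centroided MS1 scans from an mzML file
#'
#' Returns the MS1 scans of a centroided mzML file in acquisition order.
#' MS2 (and higher level) scans are skipped; profile-mode MS1 data are
#' rejected because trace consolidation assumes centroided input.
#'
#' @param path path to an mzML file.
#' @return list of scans; each scan is a list with `scan_index` (0-based
#'   ordinal among retained MS1 scans) and `peaks` (data.frame mz, intensity,
#'   sorted ascending by mz).
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("read_mzml requires the mzR package")
  if (!file.exists(path)) stop("mzML file not found: ", path)
  h <- NULL
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  h <- mzR::header(fh)
  ms1 <- which(h$msLevel == 1L)
  if (length(ms1) == 0L) stop("no MS1 scans in ", path)
  if (any(h$centroided[ms1] %in% FALSE))
    stop("centroided input required: ", path, " contains profile-mode MS1 data")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- vector("list", length(ms1))
  for (k in seq_along(ms1)) {
    p <- pk[[ms1[k]]]
    df <- data.frame(mz = p[, 1], intensity = p[, 2])
    df <- df[order(df$mz), , drop = FALSE]
    rownames(df) <- NULL
    scans[[k]] <- list(scan_index = k - 1L, peaks = df)
  }
  scans
}

#' Read a TSV peak list
#'
#' Reads the simple peak-list dialect used throughout the package: UTF-8,
#' tab-separated, a header line `mz<TAB>intensity`, one peak per row,
#' `#`-prefixed comment lines ignored. CRLF line endings and a missing
#' trailing newline are tolerated.
#'
#' @param path path to the TSV file.
#' @param meta optional manifest metadata attached to the result.
#' @return an unnormalized [sample_peaklist()] sorted by mz.
#' @export
read_peaklist_tsv <- function(path, meta = NULL) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  raw <- sub("\r$", "", raw)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) == 0L) stop("empty peak list file: ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(trimws(hdr), c("mz", "intensity")))
    stop("peak list header must be 'mz<TAB>intensity', got: ", lines[1L])
  body <- lines[-1L]
  body_ln <- lineno[-1L]
  if (length(body) == 0L) {
    warning("peak list has no data rows: ", path)
    return(sample_peaklist(data.frame(mz = numeric(0), intensity = numeric(0)),
                           meta = meta))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: '%s'",
                 body_ln[bad[1L]], path, body[bad[1L]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 2L, byrow = TRUE)
  nas <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]))
  if (length(nas))
    stop(sprintf("non-numeric value at line %d of %s: '%s'",
                 body_ln[nas[1L]], path, body[nas[1L]]))
  if (any(m[, 2] < 0))
    stop(sprintf("negative intensity at line %d of %s",
                 body_ln[which(m[, 2] < 0)[1L]], path))
  sample_peaklist(data.frame(mz = m[, 1], intensity = m[, 2]), meta = meta)
}

#' Trace-consolidation parameters
#'
#' @param ppm_tol ppm tolerance for clustering centroids across scans
#'   (default 5, the alignment tolerance).
#' @param min_scan_fraction a trace must be present in at least this fraction
#'   of scans to be retained (default 0.5).
#' @param intensity_summary how to summarise member intensities into the
#'   trace intensity: "mean" (default), "sum" or "max".
#' @return a `trace_params` list.
#' @export
trace_params <- function(ppm_tol = 5, min_scan_fraction = 0.5,
                         intensity_summary = c("mean", "sum", "max")) {
  intensity_summary <- match.arg(intensity_summary)
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) stop("ppm_tol must be > 0")
  if (!is.numeric(min_scan_fraction) || min_scan_fraction <= 0 ||
      min_scan_fraction > 1)
    stop("min_scan_fraction must be in (0, 1]")
  structure(list(ppm_tol = ppm_tol, min_scan_fraction = min_scan_fraction,
                 intensity_summary = intensity_summary),
            class = "trace_params")
}

#' Consolidate per-scan centroids into mass traces
#'
#' Finds m/z values consistently present across the scans of one infusion.
#' All centroids from all scans are pooled, sorted by m/z (ties: scan-major)
#' and clustered with the same greedy running-mean ppm rule used for
#' cross-file alignment. Clusters observed in at least
#' `params$min_scan_fraction` of the scans are retained; each emits one peak
#' with m/z equal to the mean member m/z and intensity the chosen summary
#' over member intensities (scans missing the trace contribute nothing).
#'
#' @param scans list of scans as returned by [read_mzml()].
#' @param params a [trace_params()] object.
#' @return data.frame of consolidated peaks (mz, intensity), sorted by mz.
#' @export
consolidate_traces <- function(scans, params = trace_params()) {
  if (!length(scans)) stop("consolidate_traces: empty scan list")
  n_scans <- length(scans)
  pooled <- do.call(rbind, lapply(seq_along(scans), function(k) {
    p <- scans[[k]]$peaks
    if (!nrow(p)) return(NULL)
    data.frame(mz = p$mz, intensity = p$intensity, scan = k)
  }))
  if (is.null(pooled) || !nrow(pooled))
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  pooled <- pooled[order(pooled$mz, pooled$scan, -pooled$intensity), ,
                   drop = FALSE]
  cl <- greedy_ppm_cluster(pooled$mz, params$ppm_tol)
  summ <- switch(params$intensity_summary, mean = mean, sum = sum, max = max)
  present <- tapply(pooled$scan, cl, function(s) length(unique(s))) / n_scans
  mzs <- tapply(pooled$mz, cl, mean)
  ints <- tapply(pooled$intensity, cl, summ)
  keep <- present >= params$min_scan_fraction
  out <- data.frame(mz = as.numeric(mzs[keep]),
                    intensity = as.numeric(ints[keep]))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalize a peak list to total usable signal
#'
#' Divides each intensity by the file's total usable signal (the sum of all
#' peak intensities) and scales by 1000, so every normalized spectrum sums to
#' 1000 relative-intensity units. Normalizing an already normalized sample is
#' an error (the operation is not idempotent on raw counts).
#'
#' @param sample a [sample_peaklist()], not yet normalized.
#' @return the normalized sample_peaklist.
#' @export
normalize_tus <- function(sample) {
  stopifnot(inherits(sample, "sample_peaklist"))
  if (sample$normalized) stop("sample is already normalized")
  if (nrow(sample$peaks) == 0L) {
    warning("normalizing an empty peak list")
    sample$normalized <- TRUE
    return(sample)
  }
  tot <- sum(sample$peaks$intensity)
  if (tot <= 0) stop("total usable signal is zero; cannot normalize")
  sample$peaks$intensity <- sample$peaks$intensity / tot * 1000
  sample$normalized <- TRUE
  sample
}

#' Read a sample manifest
#'
#' The manifest is a CSV with columns sample_id, file, document_id, author,
#' substrate, replicate, is_blank (0/1). Blank samples must carry an empty or
#' "blank" author label and substrate "blank"; non-blank samples must not.
#'
#' @param path path to the manifest CSV.
#' @return data.frame with `is_blank` as logical; one row per sample.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(sample_id = "character",
                                      document_id = "character",
                                      author = "character"))
  req <- c("sample_id", "file", "document_id", "author", "substrate",
           "replicate", "is_blank")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest")
  m$is_blank <- as.logical(as.integer(m$is_blank))
  blank_author <- m$author %in% c("", "blank", NA)
  if (!all(m$is_blank == blank_author))
    stop("manifest inconsistent: is_blank must hold exactly for samples with a blank author label")
  m
}
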