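#' @title Cross-file peak alignment
#' @description Aligns normalized per-file peak lists into cross-file
#'   peaksets with a greedy running-mean ppm rule, deduplicates multiple
#'   contributions of one file to a peakset, and builds the features-by-
#'   samples intensity matrix.
#' @name alignment
NULL

#' Alignment parameters
#'
#' @param ppm_tol ppm tolerance: a peak joins the open peakset iff its m/z is
#'   within this many ppm of the peakset's running mean m/z (default 5).
#' @return an `align_params` list.
#' @export
align_params <- function(ppm_tol = 5) {
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) stop("ppm_tol must be > 0")
  structure(list(ppm_tol = ppm_tol), class = "align_params")
}

new_peakset <- function(members) {
  members <- members[, c("sample_id", "mz", "intensity"), drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, mean_mz = mean(members$mz)),
            class = "peakset")
}

#' @export
print.peakset <- function(x, ...) {
  cat(sprintf("peakset: mean m/z %.6f, %d member peak(s) from %d file(s)\n",
              x$mean_mz, nrow(x$members), length(unique(x$members$sample_id))))
  invisible(x)
}

#' Greedy alignment of peak lists into peaksets
#'
#' Pools the peaks of all files, sorts them ascending by m/z (ties broken by
#' sample_id, then intensity descending) and scans left to right collecting
#' peaks into a peakset. A peakset is completed and the next peak placed into
#' a new peakset when its m/z is more than `ppm_tol` ppm away from the mean
#' m/z of the peaks already in the peakset; the mean is updated after each
#' admission. All inputs must be normalized first so intensities are
#' comparable across files.
#'
#' @param samples list of normalized [sample_peaklist()] objects.
#' @param params an [align_params()] object.
#' @return list of `peakset` objects sorted by mean m/z. A file may
#'   contribute several peaks to one peakset; apply [dedupe_within_file()]
#'   before building a matrix.
#' @export
align_greedy <- function(samples, params = align_params()) {
  if (!length(samples)) stop("align_greedy: no samples")
  ok <- vapply(samples, function(s) inherits(s, "sample_peaklist"),
               logical(1))
  if (!all(ok)) stop("align_greedy: inputs must be sample_peaklist objects")
  if (!all(vapply(samples, `[[`, logical(1), "normalized")))
    stop("align_greedy: all samples must be normalized (see normalize_tus)")
  pooled <- do.call(rbind, lapply(samples, function(s) {
    if (!nrow(s$peaks)) return(NULL)
    data.frame(sample_id = s$meta$sample_id, mz = s$peaks$mz,
               intensity = s$peaks$intensity, stringsAsFactors = FALSE)
  }))
  if (is.null(pooled)) return(list())
  pooled <- pooled[order(pooled$mz, pooled$sample_id, -pooled$intensity), ,
                   drop = FALSE]
  cl <- greedy_ppm_cluster(pooled$mz, params$ppm_tol)
  sets <- lapply(split(pooled, cl), new_peakset)
  sets <- sets[order(vapply(sets, `[[`, numeric(1), "mean_mz"))]
  names(sets) <- NULL
  sets
}

#' Retain one peak per file within a peakset
#'
#' If a file contributed more than one peak to a peakset, only the most
#' intense peak is retained (intensity ties broken towards the lower m/z).
#' The peakset mean m/z is recomputed from the survivors.
#'
#' @param peakset a `peakset` object.
#' @return the deduplicated peakset.
#' @export
dedupe_within_file <- function(peakset) {
  stopifnot(inherits(peakset, "peakset"))
  m <- peakset$members
  if (!anyDuplicated(m$sample_id)) return(peakset)
  m <- m[order(m$sample_id, -m$intensity, m$mz), , drop = FALSE]
  m <- m[!duplicated(m$sample_id), , drop = FALSE]
  new_peakset(m[order(m$mz, m$sample_id), , drop = FALSE])
}

#' Build the features-by-samples intensity matrix
#'
#' One row per (deduplicated) peakset ordered by mean m/z, one column per
#' manifest sample. Cells where a sample contributed no peak are `NA`
#' (explicit missing, imputed only at the statistics stage).
#'
#' @param peaksets list of deduplicated `peakset` objects.
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @return object of class `peak_matrix`: list with `mz` (numeric vector of
#'   feature mean m/z, ascending), `values` (features x samples matrix) and
#'   `meta` (the manifest, one row per column).
#' @export
build_matrix <- function(peaksets, manifest) {
  stopifnot(is.data.frame(manifest), "sample_id" %in% names(manifest))
  if (!is.null(manifest$is_blank))
    manifest$is_blank <- as.logical(manifest$is_blank)
  ids <- manifest$sample_id
  mz <- vapply(peaksets, `[[`, numeric(1), "mean_mz")
  ord <- order(mz)
  peaksets <- peaksets[ord]
  mz <- mz[ord]
  vals <- matrix(NA_real_, nrow = length(peaksets), ncol = length(ids),
                 dimnames = list(NULL, ids))
  for (i in seq_along(peaksets)) {
    m <- peaksets[[i]]$members
    if (anyDuplicated(m$sample_id))
      stop("build_matrix: peaksets must be deduplicated first")
    unknown <- setdiff(m$sample_id, ids)
    if (length(unknown))
      stop("build_matrix: sample(s) not in manifest: ",
           paste(unknown, collapse = ", "))
    vals[i, m$sample_id] <- m$intensity
  }
  structure(list(mz = mz, values = vals, meta = manifest),
            class = "peak_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  nb <- sum(!x$meta$is_blank)
  cat(sprintf("peak_matrix: %d features x %d samples (%d blanks), %.1f%% missing\n",
              length(x$mz), ncol(x$values), ncol(x$values) - nb,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.peak_matrix <- function(x) dim(x$values)

#' Subset a peak matrix
#'
#' @param x a `peak_matrix`.
#' @param features integer/logical index over features (rows).
#' @param samples integer/logical/character index over samples (columns).
#' @return the subsetted `peak_matrix`.
#' @export
subset_matrix <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "peak_matrix"))
  if (!is.null(features)) {
    x$mz <- x$mz[features]
    x$values <- x$values[features, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colnames(x$values))
    x$values <- x$values[, samples, drop = FALSE]
    x$meta <- x$meta[samples, , drop = FALSE]
  }
  x
}

#' Export a peak matrix as CSV
#'
#' First column is the feature m/z at 6 decimal places; one column per
#' sample_id; missing cells are written empty.
#'
#' @param x a `peak_matrix`.
#' @param path output CSV path.
#' @export
write_matrix_csv <- function(x, path) {
  stopifnot(inherits(x, "peak_matrix"))
  df <- data.frame(feature_mz = sprintf("%.6f", x$mz),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(x$values)))
    df[[colnames(x$values)[j]]] <- x$values[, j]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
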