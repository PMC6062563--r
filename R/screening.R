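#' @title Feature screening and differential statistics
#' @description Presence/blank feature filtering, missing-value imputation
#'   and logging, per-feature Welch t-tests between author groups, and
#'   Benjamini-Hochberg FDR correction.
#' @name screening
NULL

#' Screening parameters
#'
#' @param min_present a feature must be present (non-missing) in at least
#'   this many non-blank samples (default 3).
#' @param q_threshold FDR level for calling a feature significant
#'   (default 0.05).
#' @param impute_value small constant imputed into missing cells prior to
#'   logging (default 1e-5).
#' @param log_base "10" (default) or "e". The t statistic is invariant to
#'   the base; it only rescales the logged intensities.
#' @return a `screen_params` list.
#' @export
screen_params <- function(min_present = 3, q_threshold = 0.05,
                          impute_value = 1e-5, log_base = c("10", "e")) {
  log_base <- match.arg(log_base)
  if (min_present < 1) stop("min_present must be >= 1")
  if (q_threshold <= 0 || q_threshold >= 1) stop("q_threshold must be in (0,1)")
  if (impute_value <= 0) stop("impute_value must be > 0")
  structure(list(min_present = min_present, q_threshold = q_threshold,
                 impute_value = impute_value, log_base = log_base),
            class = "screen_params")
}

#' Filter features by presence and solvent-blank rules
#'
#' Retains features present (non-missing) in at least `min_present` non-blank
#' samples and absent from every solvent blank. The sample set is unchanged.
#'
#' @param matrix a `peak_matrix`.
#' @param params a [screen_params()] object.
#' @return the filtered `peak_matrix`.
#' @export
filter_features <- function(matrix, params = screen_params()) {
  stopifnot(inherits(matrix, "peak_matrix"))
  blanks <- matrix$meta$is_blank
  if (!any(blanks))
    warning("no blank samples in manifest; blank-absence rule is vacuous")
  keep <- feature_filter_mask(matrix$values, blanks, params$min_present)
  subset_matrix(matrix, features = keep)
}

# presence mask used both globally and per CV fold: `values` may be a column
# subset (training samples + blanks) of the full matrix
feature_filter_mask <- function(values, is_blank, min_present) {
  present <- !is.na(values)
  n_samp <- rowSums(present[, !is_blank, drop = FALSE])
  n_blank <- if (any(is_blank))
    rowSums(present[, is_blank, drop = FALSE]) else 0L
  n_samp >= min_present & n_blank == 0L
}

#' Impute missing values and log-transform
#'
#' Replaces missing cells with `impute_value` and logs every cell to the
#' configured base. Observed non-positive intensities are an error (they
#' cannot be logged and indicate an upstream defect).
#'
#' @param matrix a `peak_matrix`.
#' @param params a [screen_params()] object.
#' @return the `peak_matrix` with no missing cells, values on the log scale.
#' @export
impute_and_log <- function(matrix, params = screen_params()) {
  stopifnot(inherits(matrix, "peak_matrix"))
  v <- matrix$values
  if (any(v[!is.na(v)] <= 0))
    stop("impute_and_log: observed non-positive intensity")
  v[is.na(v)] <- params$impute_value
  matrix$values <- if (params$log_base == "10") log10(v) else log(v)
  matrix
}

#' Welch t-test on logged intensities
#'
#' Two-sample two-sided Welch (unequal variance) t-test. Degenerate inputs
#' are handled explicitly: if either group has fewer than 2 values the test
#' is undefined and `NA` statistics are returned; if both groups have zero
#' variance the p-value is 0 when the means differ and 1 when they are equal
#' (with t of +/-Inf or 0 accordingly), avoiding NaN propagation.
#'
#' @param values_a,values_b numeric vectors of logged intensities.
#' @return list with `t_stat` and `p_value`.
#' @export
t_test_feature <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    return(list(t_stat = NA_real_, p_value = NA_real_))
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    d <- mean(values_a) - mean(values_b)
    if (d == 0) return(list(t_stat = 0, p_value = 1))
    return(list(t_stat = sign(d) * Inf, p_value = 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), p_value = tt$p.value)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up adjustment: q_(i) = min over j with p_(j) >= p_(i) of
#' p_(j) * m / rank(j), clipped at 1. Missing p-values propagate to missing
#' q-values and do not count towards m.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return vector of q-values, same length and order.
#' @export
bh_correct <- function(p_values) {
  obs <- !is.na(p_values)
  p <- p_values[obs]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[obs] <- stats::p.adjust(p, method = "BH")
  q
}

#' Per-feature differential analysis between authors
#'
#' Imputes and logs the full matrix, then tests every feature between the two
#' author groups (optionally within one substrate stratum) with a Welch
#' t-test and corrects across features with Benjamini-Hochberg. Run this on
#' the unfiltered matrix so the `blank_free` flag (no presence in any solvent
#' blank) is meaningful.
#'
#' @param matrix a `peak_matrix` (raw normalized intensities, NA = missing).
#' @param params a [screen_params()] object.
#' @param stratum "combined" (default), "ink" or "paper": which substrate
#'   samples enter the test.
#' @return data.frame of class `msforge_diff` with columns feature_mz,
#'   n_group_a, n_group_b (non-missing counts), t_stat, p_value, q_value,
#'   blank_free, mean_log_a, mean_log_b.
#' @export
differential_analysis <- function(matrix, params = screen_params(),
                                  stratum = c("combined", "ink", "paper")) {
  stopifnot(inherits(matrix, "peak_matrix"))
  stratum <- match.arg(stratum)
  meta <- matrix$meta
  blank_free <- rowSums(!is.na(matrix$values[, meta$is_blank, drop = FALSE])) == 0
  use <- !meta$is_blank
  if (stratum != "combined") use <- use & meta$substrate == stratum
  authors <- sort(unique(meta$author[use]))
  if (length(authors) != 2)
    stop("differential_analysis: need exactly two author groups, got ",
         length(authors))
  logged <- impute_and_log(subset_matrix(matrix, samples = which(use)), params)
  grp <- logged$meta$author
  va <- logged$values[, grp == authors[1], drop = FALSE]
  vb <- logged$values[, grp == authors[2], drop = FALSE]
  raw <- matrix$values[, use, drop = FALSE]
  n_a <- rowSums(!is.na(raw[, grp == authors[1], drop = FALSE]))
  n_b <- rowSums(!is.na(raw[, grp == authors[2], drop = FALSE]))
  tests <- lapply(seq_along(matrix$mz),
                  function(i) t_test_feature(va[i, ], vb[i, ]))
  res <- data.frame(
    feature_mz = matrix$mz,
    n_group_a = n_a, n_group_b = n_b,
    t_stat = vapply(tests, `[[`, numeric(1), "t_stat"),
    p_value = vapply(tests, `[[`, numeric(1), "p_value"),
    q_value = NA_real_,
    blank_free = blank_free,
    mean_log_a = rowMeans(va), mean_log_b = rowMeans(vb))
  res$q_value <- bh_correct(res$p_value)
  attr(res, "authors") <- authors
  attr(res, "stratum") <- stratum
  class(res) <- c("msforge_diff", "data.frame")
  res
}

#' Select diagnostic features
#'
#' Features significant at the FDR threshold and never detected in any
#' solvent blank, sorted by q-value ascending.
#'
#' @param results an `msforge_diff` data.frame from [differential_analysis()].
#' @param params a [screen_params()] object (supplies `q_threshold`).
#' @return numeric vector of feature m/z values.
#' @export
select_diagnostic <- function(results, params = screen_params()) {
  stopifnot(inherits(results, "msforge_diff"))
  hit <- !is.na(results$q_value) & results$q_value < params$q_threshold &
    results$blank_free
  sel <- results[hit, , drop = FALSE]
  sel$feature_mz[order(sel$q_value)]
}
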