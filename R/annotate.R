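#' @title Formula annotation and ink-signature detection
#' @description Monoisotopic mass computation from molecular formulae,
#'   adduct m/z calculation ([M+H]+ and [M+K]+ in positive mode), ppm
#'   matching of observed diagnostic peaks to formulae, and detection of
#'   historical ink marker ions (iron gall, ivory black).
#' @name annotate
NULL

# pinned monoisotopic masses (Da), CODATA/IUPAC; pinned so tests are
# bit-stable
.element_masses <- c(C = 12.0000000, H = 1.0078250319, N = 14.0030740052,
                     O = 15.9949146221, P = 30.97376151, S = 31.97207069,
                     K = 38.9637069)
.electron_mass <- 0.00054858

#' Supported adducts
#'
#' Positive-mode single-charge adducts: the mass delta is the adduct atom's
#' monoisotopic mass minus the electron mass.
#'
#' @return named numeric vector of adduct m/z deltas (Da) for "M+H" and
#'   "M+K".
#' @export
adduct_deltas <- function() {
  c("M+H" = .element_masses[["H"]] - .electron_mass,
    "M+K" = .element_masses[["K"]] - .electron_mass)
}

#' Parse a Hill-notation molecular formula
#'
#' Accepts strings such as "C11H10O4" over the supported element table
#' (C, H, N, O, P, S, K). No isotopes, no charges.
#'
#' @param formula formula string, or an already-parsed named count vector.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1)
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (!length(toks) || paste(toks, collapse = "") != formula)
      stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", toks)
    n <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
    counts <- c(tapply(n, el, sum))
  }
  unknown <- setdiff(names(counts), names(.element_masses))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  if (sum(counts) == 0) stop("formula is empty")
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times pinned monoisotopic atomic masses.
#'
#' @param formula formula string (Hill notation) or named count vector.
#' @return neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .element_masses[names(counts)])
}

#' m/z of an adduct ion
#'
#' (neutral mass + adduct delta) / charge; the electron mass is already
#' subtracted in the delta. Charge is fixed at +1.
#'
#' @param neutral_mass neutral monoisotopic mass in Da (> 0, 0 allowed as a
#'   limiting case).
#' @param adduct "M+H" or "M+K".
#' @return ion m/z in Th.
#' @export
adduct_mz <- function(neutral_mass, adduct = "M+H") {
  deltas <- adduct_deltas()
  if (!adduct %in% names(deltas)) stop("unknown adduct: ", adduct)
  if (neutral_mass < 0) stop("neutral_mass must be >= 0")
  neutral_mass + deltas[[adduct]]
}

#' Match a formula against observed peaks
#'
#' Computes the theoretical m/z of the formula under each candidate adduct
#' and returns the observed peak / adduct pair with the smallest absolute
#' ppm error among those within `ppm_tol`; `NULL` when no peak qualifies.
#' The result is independent of the order of the peak list.
#'
#' @param peaks numeric vector of observed m/z values.
#' @param formula formula string or named count vector.
#' @param adducts character vector of candidate adducts (default "M+H").
#' @param ppm_tol ppm tolerance (default 5).
#' @return list of class `formula_annotation` with observed_mz, formula,
#'   adduct, theoretical_mz, ppm_error; or `NULL`.
#' @export
match_formula <- function(peaks, formula, adducts = "M+H", ppm_tol = 5) {
  stopifnot(ppm_tol > 0)
  if (!length(peaks)) return(NULL)
  mass <- monoisotopic_mass(formula)
  best <- NULL
  for (ad in adducts) {
    theo <- adduct_mz(mass, ad)
    ppm <- (peaks - theo) / theo * 1e6
    i <- which.min(abs(ppm))
    if (abs(ppm[i]) <= ppm_tol &&
        (is.null(best) || abs(ppm[i]) < abs(best$ppm_error))) {
      best <- structure(list(
        observed_mz = peaks[i],
        formula = if (is.character(formula)) formula else
          paste0(names(formula), ifelse(formula > 1, formula, ""),
                 collapse = ""),
        adduct = ad, theoretical_mz = theo, ppm_error = ppm[i]),
        class = "formula_annotation")
    }
  }
  best
}

#' @export
print.formula_annotation <- function(x, ...) {
  cat(sprintf("%s [%s]+ : theoretical %.4f, observed %.4f (%+.2f ppm)\n",
              x$formula, x$adduct, x$theoretical_mz, x$observed_mz,
              x$ppm_error))
  invisible(x)
}

#' Shipped diagnostic-ion table
#'
#' The embedded table of author-diagnostic ions: observed m/z, suggested
#' compound annotation and predicted formula/adduct where one is available.
#' Two author-specific columns of eight ions each (`in_table = 1`), plus a
#' schematic-figure ion (272.0655, `in_table = 0`) whose relation to the
#' tabulated 273.0289 is unresolved, and a note column marking the possibly
#' inorganic cluster ions; none of those are assigned formulae.
#'
#' @return data.frame with columns author, mz, annotation, formula, adduct,
#'   in_table, note.
#' @export
diagnostic_peaks <- function() {
  path <- system.file("extdata", "diagnostic_peaks.csv", package = "msforge",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(author = "character", mz = "numeric",
                                 annotation = "character",
                                 formula = "character",
                                 adduct = "character", in_table = "integer",
                                 note = "character"))
}

#' Shipped ink-marker table
#'
#' Empirical marker ions for historical ink recipes: iron gall at m/z
#' 90.9479 and ivory black at m/z 130.5259. These are fingerprint m/z
#' values, not assigned formulae (the fractional 130.5259 in particular is
#' treated as an empirical marker).
#'
#' @return data.frame with columns ink_name, marker_mz.
#' @export
ink_markers <- function() {
  path <- system.file("extdata", "ink_markers.csv", package = "msforge",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Detect ink-signature markers in a sample
#'
#' For each marker ion, reports whether some peak of the (normalized) sample
#' lies within `ppm_tol` of the marker m/z. Both markers may fire in one
#' sample — the signature of a mixed ink.
#'
#' @param sample a normalized [sample_peaklist()].
#' @param markers marker table (default [ink_markers()]).
#' @param ppm_tol ppm tolerance (default 5).
#' @return data.frame with columns ink_name, detected, matched_mz (NA when
#'   not detected).
#' @export
detect_ink_signature <- function(sample, markers = ink_markers(),
                                 ppm_tol = 5) {
  stopifnot(inherits(sample, "sample_peaklist"))
  if (!sample$normalized) stop("sample must be normalized first")
  mz <- sample$peaks$mz
  out <- data.frame(ink_name = markers$ink_name, detected = FALSE,
                    matched_mz = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(markers))) {
    if (!length(mz)) break
    ppm <- abs(mz - markers$marker_mz[i]) / markers$marker_mz[i] * 1e6
    j <- which.min(ppm)
    if (ppm[j] <= ppm_tol) {
      out$detected[i] <- TRUE
      out$matched_mz[i] <- mz[j]
    }
  }
  out
}

#' Annotate aligned features with the diagnostic table
#'
#' Matches every formula-bearing row of the diagnostic table against a set
#' of feature m/z values and reports the assignments.
#'
#' @param feature_mz numeric vector of feature m/z values (e.g.
#'   `peak_matrix$mz`).
#' @param table diagnostic table (default [diagnostic_peaks()]).
#' @param ppm_tol ppm tolerance (default 5).
#' @return data.frame with columns annotation_name, author, formula, adduct,
#'   theoretical_mz, observed_mz, ppm_error (only matched rows).
#' @export
annotate_features <- function(feature_mz, table = diagnostic_peaks(),
                              ppm_tol = 5) {
  rows <- table[nzchar(table$formula), , drop = FALSE]
  out <- lapply(seq_len(nrow(rows)), function(i) {
    ann <- match_formula(feature_mz, rows$formula[i],
                         adducts = rows$adduct[i], ppm_tol = ppm_tol)
    if (is.null(ann)) return(NULL)
    data.frame(annotation_name = rows$annotation[i], author = rows$author[i],
               formula = ann$formula, adduct = ann$adduct,
               theoretical_mz = ann$theoretical_mz,
               observed_mz = ann$observed_mz, ppm_error = ann$ppm_error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(annotation_name = character(0), author = character(0),
                      formula = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), observed_mz = numeric(0),
                      ppm_error = numeric(0))
  out
}
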