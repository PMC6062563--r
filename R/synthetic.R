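#' @title Synthetic manuscript corpus generator
#' @description Generates direct-infusion peak-list corpora with the
#'   statistical structure the pipeline assumes: two authors, several
#'   documents each, ink and paper substrates, technical replicates, solvent
#'   blanks, shared background ions, author-diagnostic ions, blank
#'   contaminants, ppm-scale m/z jitter, multiplicative intensity noise and
#'   missingness — so every stage is testable without any download.
#' @name synthetic_data
NULL

#' Corpus configuration
#'
#' Defaults emulate the study design the pipeline targets: 2 authors x 5
#' documents x 2 substrates x 3 technical replicates plus 4 solvent blanks
#' (64 files), ~300 shared background ions, 8 diagnostic ions per author
#' (defaulting to the shipped diagnostic table's two author columns), 20
#' blank contaminants, 1 ppm m/z jitter (well under half the 5 ppm
#' alignment tolerance), lognormal intensity noise of sd 0.5 on the log
#' scale, an 8-fold diagnostic intensity effect and 10% missingness.
#'
#' @param n_documents_per_author documents per author (default 5).
#' @param replicates technical replicates per document x substrate
#'   (default 3).
#' @param substrates substrate labels sampled per document (default ink and
#'   paper).
#' @param n_blanks number of solvent blanks (default 4).
#' @param n_background_features shared background ions (default 300).
#' @param n_diagnostic_per_author diagnostic ions per author (default 8).
#' @param diagnostic_mz_a,diagnostic_mz_b diagnostic m/z values per author;
#'   default the shipped table's author columns. Must be disjoint sets.
#' @param n_blank_contaminants contaminant ions present in blanks
#'   (default 20); half of them are also planted into at least one real
#'   sample so the blank filter is exercised on non-trivial cases.
#' @param mz_jitter_ppm_sd Gaussian m/z jitter, ppm (default 1).
#' @param intensity_lognormal_sd multiplicative intensity noise, sd of the
#'   natural-log scale (default 0.5).
#' @param diagnostic_fold_change diagnostic base intensity relative to the
#'   background baseline (default 8).
#' @param missing_rate per-cell dropout probability for planted
#'   sample-feature pairs (default 0.1).
#' @param n_scans_per_file scans written per file (default 10).
#' @param seed integer seed; the corpus is a deterministic function of it.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(n_documents_per_author = 5, replicates = 3,
                          substrates = c("ink", "paper"), n_blanks = 4,
                          n_background_features = 300,
                          n_diagnostic_per_author = 8,
                          diagnostic_mz_a = NULL, diagnostic_mz_b = NULL,
                          n_blank_contaminants = 20, mz_jitter_ppm_sd = 1.0,
                          intensity_lognormal_sd = 0.5,
                          diagnostic_fold_change = 8.0, missing_rate = 0.1,
                          n_scans_per_file = 10, seed = 1) {
  if (is.null(diagnostic_mz_a) || is.null(diagnostic_mz_b)) {
    dp <- diagnostic_peaks()
    dp <- dp[dp$in_table == 1L, ]
    if (is.null(diagnostic_mz_a)) diagnostic_mz_a <- dp$mz[dp$author == "A"]
    if (is.null(diagnostic_mz_b)) diagnostic_mz_b <- dp$mz[dp$author == "B"]
  }
  diagnostic_mz_a <- diagnostic_mz_a[seq_len(min(n_diagnostic_per_author,
                                                 length(diagnostic_mz_a)))]
  diagnostic_mz_b <- diagnostic_mz_b[seq_len(min(n_diagnostic_per_author,
                                                 length(diagnostic_mz_b)))]
  counts <- c(n_documents_per_author = n_documents_per_author,
              replicates = replicates, n_blanks = n_blanks,
              n_background_features = n_background_features,
              n_diagnostic_per_author = n_diagnostic_per_author,
              n_blank_contaminants = n_blank_contaminants,
              n_scans_per_file = n_scans_per_file)
  bad <- names(counts)[counts < 1]
  if (length(bad)) stop("config counts must be >= 1: ",
                        paste(bad, collapse = ", "))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (mz_jitter_ppm_sd <= 0) stop("mz_jitter_ppm_sd must be > 0")
  if (intensity_lognormal_sd <= 0) stop("intensity_lognormal_sd must be > 0")
  if (diagnostic_fold_change <= 0) stop("diagnostic_fold_change must be > 0")
  if (length(intersect(diagnostic_mz_a, diagnostic_mz_b)))
    stop("diagnostic m/z sets must be disjoint between authors")
  structure(list(n_documents_per_author = n_documents_per_author,
                 replicates = replicates, substrates = substrates,
                 n_blanks = n_blanks,
                 n_background_features = n_background_features,
                 n_diagnostic_per_author = n_diagnostic_per_author,
                 diagnostic_mz_a = diagnostic_mz_a,
                 diagnostic_mz_b = diagnostic_mz_b,
                 n_blank_contaminants = n_blank_contaminants,
                 mz_jitter_ppm_sd = mz_jitter_ppm_sd,
                 intensity_lognormal_sd = intensity_lognormal_sd,
                 diagnostic_fold_change = diagnostic_fold_change,
                 missing_rate = missing_rate,
                 n_scans_per_file = n_scans_per_file, seed = seed),
            class = "corpus_config")
}

# deterministic 31-bit string hash for per-file RNG substreams, so adding a
# sample never perturbs the draws of another
stable_hash <- function(seed, s) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# m/z values >= 30 ppm apart from each other and from `avoid`
draw_spaced_mz <- function(n, avoid = numeric(0), lo = 70, hi = 700,
                           min_ppm = 30) {
  out <- numeric(0)
  guard <- 0
  while (length(out) < n) {
    guard <- guard + 1
    if (guard > 100 * n) stop("could not place spaced m/z values")
    cand <- stats::runif(1, lo, hi)
    ref <- c(avoid, out)
    if (!length(ref) || min(abs(ref - cand) / cand) * 1e6 >= min_ppm)
      out <- c(out, cand)
  }
  out
}

build_manifest <- function(config, ext) {
  rows <- list()
  for (a in c("A", "B")) for (d in seq_len(config$n_documents_per_author))
    for (s in config$substrates) for (r in seq_len(config$replicates)) {
      id <- sprintf("%s_d%d_%s_r%d", a, d, s, r)
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = id, file = paste0(id, ext),
                   document_id = sprintf("%s_d%d", a, d), author = a,
                   substrate = s, replicate = r, is_blank = 0L,
                   stringsAsFactors = FALSE)
    }
  for (b in seq_len(config$n_blanks)) {
    id <- sprintf("blank_%d", b)
    rows[[length(rows) + 1L]] <-
      data.frame(sample_id = id, file = paste0(id, ext), document_id = "",
                 author = "", substrate = "blank", replicate = b,
                 is_blank = 1L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

generate_corpus_impl <- function(config, dir, format, signal) {
  ext <- if (format == "mzml") ".mzML" else ".tsv"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- build_manifest(config, ext)
  real_ids <- manifest$sample_id[manifest$is_blank == 0L]
  blank_ids <- manifest$sample_id[manifest$is_blank == 1L]

  # global feature layout (backgrounds first so signal and null corpora
  # share the grid under one seed)
  set.seed(config$seed)
  diag_mz <- c(config$diagnostic_mz_a, config$diagnostic_mz_b)
  bg_mz <- draw_spaced_mz(config$n_background_features, avoid = diag_mz)
  cont_mz <- draw_spaced_mz(config$n_blank_contaminants,
                            avoid = c(diag_mz, bg_mz))
  n_bg <- length(bg_mz)
  n_da <- length(config$diagnostic_mz_a)
  n_db <- length(config$diagnostic_mz_b)
  fold <- if (signal) config$diagnostic_fold_change else 1.0
  feat <- data.frame(
    mz = c(bg_mz, config$diagnostic_mz_a, config$diagnostic_mz_b, cont_mz),
    class = c(rep("background", n_bg), rep("author_A", n_da),
              rep("author_B", n_db),
              rep("contaminant", config$n_blank_contaminants)),
    stringsAsFactors = FALSE)
  feat$base <- exp(stats::rnorm(nrow(feat), log(100), 0.8)) *
    ifelse(feat$class %in% c("author_A", "author_B"), fold, 1)

  # presence plan: planted[i, j] over features x samples (incl. blanks)
  ids <- manifest$sample_id
  planted <- matrix(FALSE, nrow(feat), length(ids),
                    dimnames = list(NULL, ids))
  planted[feat$class == "background", real_ids] <- TRUE
  if (signal) {
    a_ids <- manifest$sample_id[manifest$author == "A"]
    b_ids <- manifest$sample_id[manifest$author == "B"]
    planted[feat$class == "author_A", a_ids] <- TRUE
    planted[feat$class == "author_B", b_ids] <- TRUE
  } else {
    planted[feat$class %in% c("author_A", "author_B"), real_ids] <- TRUE
  }
  cont_rows <- which(feat$class == "contaminant")
  planted[cont_rows, blank_ids] <- TRUE
  overlap <- cont_rows[seq_len(floor(length(cont_rows) / 2))]
  for (i in overlap)
    planted[i, sample(real_ids, sample(1:3, 1))] <- TRUE

  # missingness on real samples only; keep every diagnostic in >= 3 samples
  # of its author so planted truth stays detectable by construction
  drop <- matrix(stats::runif(nrow(feat) * length(real_ids)) <
                   config$missing_rate, nrow(feat), length(real_ids))
  keep_classes <- c("background", "author_A", "author_B")
  planted[feat$class %in% keep_classes, real_ids] <-
    planted[feat$class %in% keep_classes, real_ids] &
    !drop[feat$class %in% keep_classes, ]
  if (signal) for (i in which(feat$class %in% c("author_A", "author_B"))) {
    own <- if (feat$class[i] == "author_A")
      manifest$sample_id[manifest$author == "A"]
    else manifest$sample_id[manifest$author == "B"]
    if (sum(planted[i, own]) < 3)
      planted[i, sample(own, 3)] <- TRUE
  }

  # per-file peak lists and scans from a per-sample RNG substream
  jit <- config$mz_jitter_ppm_sd * 1e-6
  isd <- config$intensity_lognormal_sd
  peaklists <- list()
  files <- character(0)
  for (j in seq_along(ids)) {
    id <- ids[j]
    set.seed(stable_hash(config$seed, id))
    rows <- which(planted[, j])
    fmz <- feat$mz[rows] * (1 + stats::rnorm(length(rows), 0, jit))
    fint <- feat$base[rows] * exp(stats::rnorm(length(rows), 0, isd))
    ord <- order(fmz)
    fmz <- fmz[ord]; fint <- fint[ord]
    meta <- as.list(manifest[j, ])
    meta$is_blank <- as.logical(meta$is_blank)
    spl <- sample_peaklist(data.frame(mz = fmz, intensity = fint),
                           meta = meta)
    peaklists[[id]] <- spl
    path <- file.path(dir, manifest$file[j])
    if (format == "mzml") {
      scans <- lapply(seq_len(config$n_scans_per_file), function(s) {
        smz <- fmz * (1 + stats::rnorm(length(fmz), 0, jit))
        sint <- fint * exp(stats::rnorm(length(fmz), 0, isd / 2))
        o <- order(smz)
        cbind(mz = smz[o], intensity = sint[o])
      })
      write_mzml(scans, path)
    } else {
      write_peaklist_tsv(spl, path)
    }
    files <- c(files, path)
  }

  planted_in <- vapply(seq_len(nrow(feat)), function(i)
    paste(ids[planted[i, ]], collapse = ";"), character(1))
  truth <- data.frame(feature_mz = feat$mz, class = feat$class,
                      base_intensity = feat$base, planted_in = planted_in,
                      stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(dir = dir, manifest = manifest, truth = truth,
                 peaklists = peaklists, files = files, config = config))
}

#' Generate a synthetic two-author corpus
#'
#' Writes per-sample peak-list files (TSV by default, mzML via mzR on
#' request), a manifest CSV and a ground-truth table into `dir`. The corpus
#' is a deterministic function of `config$seed`; per-file randomness is
#' drawn from substreams keyed by sample_id, so adding a sample does not
#' perturb the others.
#'
#' @param config a [corpus_config()].
#' @param dir output directory (created if needed).
#' @param format "tsv" (default) or "mzml".
#' @return invisibly, a list with the manifest, truth table, in-memory
#'   (unnormalized) peak lists, file paths and config.
#' @export
generate_corpus <- function(config = corpus_config(), dir,
                            format = c("tsv", "mzml")) {
  format <- match.arg(format)
  generate_corpus_impl(config, dir, format, signal = TRUE)
}

#' Generate a null corpus (no author signal)
#'
#' As [generate_corpus()] but the diagnostic fold change is forced to 1 and
#' class-specific presence is removed: every "diagnostic" ion behaves as a
#' background ion present in all samples, so the author labels carry no
#' signal. The background m/z grid is identical to the signal corpus for
#' the same seed.
#'
#' @inheritParams generate_corpus
#' @return invisibly, same structure as [generate_corpus()].
#' @export
generate_null_corpus <- function(config = corpus_config(), dir,
                                 format = c("tsv", "mzml")) {
  format <- match.arg(format)
  generate_corpus_impl(config, dir, format, signal = FALSE)
}

#' Score selected features against the planted truth
#'
#' Matches a vector of selected feature m/z values against the planted
#' author-diagnostic features by ppm distance.
#'
#' @param truth truth table from [generate_corpus()] (or its CSV re-read).
#' @param selected numeric vector of selected feature m/z values.
#' @param ppm_tol ppm match tolerance (default 5).
#' @return list with `recall` (fraction of planted diagnostics recovered)
#'   and `false_discovery_fraction` (fraction of selections matching no
#'   planted diagnostic).
#' @export
truth_report <- function(truth, selected, ppm_tol = 5) {
  diag_mz <- truth$feature_mz[truth$class %in% c("author_A", "author_B")]
  if (!length(diag_mz)) stop("truth table contains no diagnostic features")
  if (!length(selected))
    return(list(recall = 0, false_discovery_fraction = NA_real_))
  hit <- vapply(diag_mz, function(m)
    any(abs(selected - m) / m * 1e6 <= ppm_tol), logical(1))
  matched <- vapply(selected, function(s)
    any(abs(s - diag_mz) / diag_mz * 1e6 <= ppm_tol), logical(1))
  list(recall = mean(hit), false_discovery_fraction = mean(!matched))
}

#' Write a peak list in the TSV dialect
#'
#' @param sample a [sample_peaklist()].
#' @param path output path.
#' @export
write_peaklist_tsv <- function(sample, path) {
  stopifnot(inherits(sample, "sample_peaklist"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  id <- if (!is.null(sample$meta$sample_id)) sample$meta$sample_id else ""
  lines <- c(sprintf("# sample_id: %s", id), "mz\tintensity",
             sprintf("%.6f\t%.8g", sample$peaks$mz, sample$peaks$intensity))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write scans to a minimal centroided mzML file (via mzR)
#'
#' @param scans list of two-column (mz, intensity) matrices, one per scan.
#' @param path output mzML path.
#' @param ms_levels integer MS level per scan (recycled; default 1).
#' @param centroided logical flag per scan (recycled; default TRUE).
#' @export
write_mzml <- function(scans, path, ms_levels = 1L, centroided = TRUE) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("write_mzml requires the mzR package")
  n <- length(scans)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = rep_len(as.integer(ms_levels), n),
    polarity = 1L, peaksCount = vapply(scans, nrow, integer(1)),
    totIonCurrent = vapply(scans, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = as.numeric(seq_len(n)), basePeakMZ = 0,
    basePeakIntensity = 0, collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = 0, highMZ = 0, precursorScanNum = 0L, precursorMZ = 0,
    precursorCharge = 0L, precursorIntensity = 0, mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep_len(as.logical(centroided), n),
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = 70,
    scanWindowUpperLimit = 700)
  mzR::writeMSData(scans, file = path, header = hdr)
  invisible(path)
}
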