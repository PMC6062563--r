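#' @title End-to-end pipeline and command-line interface
#' @description Orchestrates read -> trace consolidation -> normalization ->
#'   alignment -> dedup -> matrix -> screening -> grouped cross validation ->
#'   ROC -> annotation from a manifest plus a flat key-value (YAML) config,
#'   writing every stage output as CSV and a single JSON run summary.
#' @name pipeline_cli
NULL

run_config_defaults <- function() {
  list(manifest = NULL, data_dir = NULL, out_dir = NULL,
       ppm_tol = 5, min_scan_fraction = 0.5, intensity_summary = "mean",
       min_present = 3, q_threshold = 0.05, impute_value = 1e-5,
       log_base = "10", gamma_mode = "auto", gamma_value = NULL,
       margin_hardness = 1e8, annotation_ppm_tol = 5,
       paper_faithful = FALSE, seed = 1)
}

#' Read a run configuration
#'
#' Flat key-value YAML mirroring the pipeline parameters; unknown keys are
#' an error so typos do not silently fall back to defaults.
#'
#' @param path config file path.
#' @return a validated `run_config` list (defaults filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  validate_run_config(user)
}

#' @rdname read_run_config
#' @param config named list of overrides over the defaults.
#' @export
validate_run_config <- function(config = list()) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (f in c("ppm_tol", "min_scan_fraction", "q_threshold", "impute_value",
              "margin_hardness", "annotation_ppm_tol"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive number")
  if (cfg$min_present < 1) stop("config field 'min_present' must be >= 1")
  if (is.null(cfg$manifest)) stop("config field 'manifest' is required")
  if (is.null(cfg$data_dir)) cfg$data_dir <- dirname(cfg$manifest)
  if (is.null(cfg$out_dir)) stop("config field 'out_dir' is required")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Load, consolidate and normalize a corpus
#'
#' Reads every manifest file (TSV peak lists directly; mzML via
#' [read_mzml()] followed by [consolidate_traces()]) and normalizes each to
#' total usable signal.
#'
#' @param manifest manifest data.frame or path to the manifest CSV.
#' @param data_dir directory holding the per-sample files.
#' @param trace a [trace_params()] object (mzML inputs only).
#' @return list of normalized [sample_peaklist()] objects, manifest order.
#' @export
load_corpus <- function(manifest, data_dir, trace = trace_params()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  samples <- vector("list", nrow(manifest))
  for (j in seq_len(nrow(manifest))) {
    meta <- as.list(manifest[j, ])
    path <- file.path(data_dir, manifest$file[j])
    spl <- if (grepl("\\.mzml$", manifest$file[j], ignore.case = TRUE)) {
      scans <- read_mzml(path)
      sample_peaklist(consolidate_traces(scans, trace), meta = meta)
    } else {
      read_peaklist_tsv(path, meta = meta)
    }
    samples[[j]] <- normalize_tus(spl)
  }
  names(samples) <- manifest$sample_id
  samples
}

#' Run the full authentication pipeline
#'
#' Executes every stage on a corpus and writes peak_matrix.csv,
#' differential.csv, roc.csv, annotations.csv, ink_calls.csv and
#' summary.json into the output directory. Deterministic given the config
#' (including its seed).
#'
#' @param config a `run_config` list (see [read_run_config()] /
#'   [validate_run_config()]), or a path to a YAML config file.
#' @param quiet suppress stage log messages.
#' @return invisibly, the run summary list.
#' @export
run_all <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    config <- validate_run_config(config)
  log <- function(...) if (!quiet) message(sprintf(...))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- run_stage("manifest", read_manifest(config$manifest))
  log("[manifest] %d samples (%d blanks)", nrow(manifest),
      sum(manifest$is_blank))

  trace <- trace_params(config$ppm_tol, config$min_scan_fraction,
                        config$intensity_summary)
  samples <- run_stage("load", load_corpus(manifest, config$data_dir, trace))
  log("[load] read and normalized %d files from %s", length(samples),
      config$data_dir)

  sets <- run_stage("align",
                    align_greedy(samples, align_params(config$ppm_tol)))
  sets <- lapply(sets, dedupe_within_file)
  mat <- run_stage("matrix", build_matrix(sets, manifest))
  write_matrix_csv(mat, file.path(config$out_dir, "peak_matrix.csv"))
  log("[align] %d peaksets at %g ppm", length(sets), config$ppm_tol)

  screen <- screen_params(config$min_present, config$q_threshold,
                          config$impute_value, config$log_base)
  diff <- run_stage("screen", differential_analysis(mat, screen))
  utils::write.csv(diff, file.path(config$out_dir, "differential.csv"),
                   row.names = FALSE)
  diagnostics <- select_diagnostic(diff, screen)
  filtered <- run_stage("filter", filter_features(mat, screen))
  log("[screen] %d/%d features pass the presence/blank filter; %d diagnostic (q < %g, blank-free)",
      length(filtered$mz), length(mat$mz), length(diagnostics),
      config$q_threshold)

  kp <- kernel_params(config$gamma_mode, config$gamma_value,
                      config$margin_hardness)
  plan <- run_stage("folds", make_folds_by_document(manifest))
  cv <- run_stage("crossval",
                  crossval(mat, plan, kp, screen,
                           paper_faithful = isTRUE(config$paper_faithful)))
  roc <- run_stage("roc", roc_auc(cv))
  write_roc_csv(roc, file.path(config$out_dir, "roc.csv"))
  log("[classify] %d folds, pooled AUC %.4f", length(plan$folds), roc$auc)

  ann <- run_stage("annotate",
                   annotate_features(filtered$mz,
                                     ppm_tol = config$annotation_ppm_tol))
  utils::write.csv(ann, file.path(config$out_dir, "annotations.csv"),
                   row.names = FALSE)
  ink <- do.call(rbind, lapply(samples[!manifest$is_blank], function(s) {
    d <- detect_ink_signature(s, ppm_tol = config$annotation_ppm_tol)
    cbind(sample_id = s$meta$sample_id, d)
  }))
  rownames(ink) <- NULL
  utils::write.csv(ink, file.path(config$out_dir, "ink_calls.csv"),
                   row.names = FALSE)
  log("[annotate] %d formula assignments; ink calls for %d samples", nrow(ann),
      length(unique(ink$sample_id)))

  per_fold_acc <- vapply(seq_along(plan$folds), function(k) {
    sel <- cv$fold_of == k
    mean((cv$scores[sel] > 0) == (cv$labels[sel] == cv$positive))
  }, numeric(1))
  summary <- list(
    n_samples = nrow(manifest), n_blanks = sum(manifest$is_blank),
    n_features_pre_filter = length(mat$mz),
    n_features_post_filter = length(filtered$mz),
    n_significant = sum(!is.na(diff$q_value) &
                          diff$q_value < config$q_threshold),
    n_significant_blank_free = length(diagnostics),
    n_folds = length(plan$folds), auc = roc$auc,
    per_fold_accuracy = as.numeric(per_fold_acc),
    n_annotated = nrow(ann),
    n_ink_positive_samples = length(unique(ink$sample_id[ink$detected])),
    paper_faithful = isTRUE(config$paper_faithful),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("[done] summary written to %s", file.path(config$out_dir,
                                                "summary.json"))
  invisible(summary)
}

cli_usage <- function() {
  paste(
    "usage: msforge <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate       generate a synthetic corpus",
    "                   --seed INT --out DIR [--null] [--format tsv|mzml]",
    "  extract-peaks  consolidate one mzML file into a TSV peak list",
    "                   --in FILE --out FILE [--ppm X] [--min-scan-fraction F]",
    "  align          build the aligned feature matrix CSV",
    "                   --manifest FILE --out FILE [--data-dir DIR] [--ppm X]",
    "  screen         differential feature table CSV",
    "                   --manifest FILE --out FILE [--data-dir DIR] [--ppm X]",
    "  classify       grouped CV + ROC; writes roc.csv and summary.json",
    "                   --manifest FILE --out DIR [--data-dir DIR] [--ppm X]",
    "                   [--paper-faithful] [--seed INT]",
    "  annotate       annotate a TSV peak list; writes annotation CSV",
    "                   --in FILE --out FILE [--ppm X]",
    "  run-all        full pipeline from a YAML config",
    "                   --config FILE [--out DIR] [--seed INT]",
    "                   [--paper-faithful]",
    "",
    "exit codes: 0 ok, 2 validation error, 3 runtime stage failure",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (key %in% c("null", "paper-faithful", "help")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " needs a value")
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (!is.finite(v)) stop("flag --", key, " must be numeric")
  v
}

#' Command-line entry point
#'
#' Dispatches the subcommands documented in the usage text (`msforge_cli()`
#' with no arguments, or any subcommand with `--help`). A thin Rscript
#' wrapper around this function ships in `inst/scripts/msforge`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code: 0 success, 2 validation error, 3 runtime
#'   failure.
#' @export
msforge_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "help", "-h")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  known <- c("simulate", "extract-peaks", "align", "screen", "classify",
             "annotate", "run-all")
  if (!sub %in% known) {
    cat(cli_usage(), "\n")
    message("unknown subcommand: ", sub)
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(args[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags))
    cat(cli_usage(), "\n")
    return(invisible(2L))
  }
  if (isTRUE(flags$help)) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  res <- tryCatch({
    cli_dispatch(sub, flags)
    0L
  },
  validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(res)
}

validation_stop <- function(...) {
  stop(structure(list(message = paste0(...), call = NULL),
                 class = c("validation_error", "error", "condition")))
}

need_flag <- function(flags, key) {
  if (is.null(flags[[key]])) validation_stop("missing required flag --", key)
  flags[[key]]
}

check_ppm <- function(ppm) {
  if (!is.finite(ppm) || ppm <= 0)
    validation_stop("ppm tolerance must be > 0 (field: ppm)")
  ppm
}

cli_matrix <- function(flags) {
  manifest_path <- need_flag(flags, "manifest")
  if (!file.exists(manifest_path))
    validation_stop("manifest not found: ", manifest_path)
  data_dir <- if (is.null(flags[["data-dir"]])) dirname(manifest_path)
              else flags[["data-dir"]]
  ppm <- check_ppm(flag_num(flags, "ppm", 5))
  manifest <- read_manifest(manifest_path)
  samples <- load_corpus(manifest, data_dir, trace_params(ppm_tol = ppm))
  sets <- lapply(align_greedy(samples, align_params(ppm)),
                 dedupe_within_file)
  list(manifest = manifest, matrix = build_matrix(sets, manifest),
       samples = samples)
}

cli_dispatch <- function(sub, flags) {
  switch(sub,
    "simulate" = {
      out <- need_flag(flags, "out")
      seed <- as.integer(flag_num(flags, "seed", 1))
      format <- if (is.null(flags$format)) "tsv" else flags$format
      if (!format %in% c("tsv", "mzml"))
        validation_stop("--format must be tsv or mzml (field: format)")
      cfg <- corpus_config(seed = seed)
      if (isTRUE(flags$null)) generate_null_corpus(cfg, out, format)
      else generate_corpus(cfg, out, format)
      message("corpus written to ", out)
    },
    "extract-peaks" = {
      infile <- need_flag(flags, "in")
      out <- need_flag(flags, "out")
      ppm <- check_ppm(flag_num(flags, "ppm", 5))
      msf <- flag_num(flags, "min-scan-fraction", 0.5)
      if (msf <= 0 || msf > 1)
        validation_stop("min-scan-fraction must be in (0,1] ",
                        "(field: min_scan_fraction)")
      peaks <- consolidate_traces(read_mzml(infile),
                                  trace_params(ppm, msf))
      write_peaklist_tsv(sample_peaklist(peaks), out)
    },
    "align" = {
      out <- need_flag(flags, "out")
      write_matrix_csv(cli_matrix(flags)$matrix, out)
    },
    "screen" = {
      out <- need_flag(flags, "out")
      ppm <- check_ppm(flag_num(flags, "ppm", 5))
      m <- cli_matrix(flags)
      diff <- differential_analysis(m$matrix, screen_params())
      utils::write.csv(diff, out, row.names = FALSE)
    },
    "classify" = {
      out <- need_flag(flags, "out")
      seed <- as.integer(flag_num(flags, "seed", 1))
      m <- cli_matrix(flags)
      set.seed(seed)
      plan <- make_folds_by_document(m$manifest)
      cv <- crossval(m$matrix, plan,
                     paper_faithful = isTRUE(flags[["paper-faithful"]]))
      roc <- roc_auc(cv)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_roc_csv(roc, file.path(out, "roc.csv"))
      jsonlite::write_json(
        list(auc = roc$auc, n_folds = length(plan$folds)),
        file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
    },
    "annotate" = {
      infile <- need_flag(flags, "in")
      out <- need_flag(flags, "out")
      ppm <- check_ppm(flag_num(flags, "ppm", 5))
      spl <- normalize_tus(read_peaklist_tsv(infile))
      ann <- annotate_features(spl$peaks$mz, ppm_tol = ppm)
      ink <- detect_ink_signature(spl, ppm_tol = ppm)
      utils::write.csv(cbind(kind = "formula",
                             ann[, c("annotation_name", "formula", "adduct",
                                     "observed_mz", "ppm_error")]),
                       out, row.names = FALSE)
      utils::write.csv(ink, sub("\\.csv$", "_ink.csv", out),
                       row.names = FALSE)
    },
    "run-all" = {
      cfg_path <- need_flag(flags, "config")
      cfg <- tryCatch(read_run_config(cfg_path), error = function(e)
        validation_stop(conditionMessage(e)))
      cfg <- unclass(cfg)
      if (!is.null(flags$out)) cfg$out_dir <- flags$out
      if (!is.null(flags$seed)) cfg$seed <- as.integer(flag_num(flags,
                                                                "seed", 1))
      if (isTRUE(flags[["paper-faithful"]])) cfg$paper_faithful <- TRUE
      run_all(validate_run_config(cfg))
    })
  invisible(NULL)
}
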