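#' @title Document-grouped cross-validated kernel classification
#' @description Hard-margin RBF-kernel SVM classification of authors from
#'   aligned peak intensities, evaluated by leave-one-document-out cross
#'   validation (all technical replicates of a document held out together)
#'   with a pooled ROC curve and AUC.
#' @name classify
NULL

#' Kernel / margin parameters
#'
#' @param gamma_mode "auto" (default) sets the RBF width to
#'   1 / (n_features * var(training values)), the standard scale heuristic;
#'   "fixed" uses `gamma_value`.
#' @param gamma_value positive RBF gamma, used when `gamma_mode = "fixed"`.
#' @param margin_hardness misclassification penalty C (default 1e8). A very
#'   large C emulates a hard-margin SVM while remaining numerically robust
#'   when the data are only quasi-separable.
#' @return a `kernel_params` list.
#' @export
kernel_params <- function(gamma_mode = c("auto", "fixed"), gamma_value = NULL,
                          margin_hardness = 1e8) {
  gamma_mode <- match.arg(gamma_mode)
  if (gamma_mode == "fixed" &&
      (!is.numeric(gamma_value) || gamma_value <= 0))
    stop("gamma_value must be > 0 when gamma_mode is 'fixed'")
  if (margin_hardness <= 0) stop("margin_hardness must be > 0")
  structure(list(gamma_mode = gamma_mode, gamma_value = gamma_value,
                 margin_hardness = margin_hardness),
            class = "kernel_params")
}

#' Leave-one-document-out fold plan
#'
#' One cross-validation fold per document: all technical replicates (and both
#' substrates) of that document form the test set, every other non-blank
#' sample the training set, so replicates of one document are never split
#' across training and test. Blanks are excluded throughout.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @return object of class `fold_plan`: list of folds, each with `train` and
#'   `test` character vectors of sample_ids, plus the grouping key.
#' @export
make_folds_by_document <- function(manifest) {
  manifest$is_blank <- as.logical(manifest$is_blank)
  m <- manifest[!manifest$is_blank, , drop = FALSE]
  if (!nrow(m)) stop("make_folds_by_document: no non-blank samples")
  docs <- unique(m$document_id)
  doc_author <- vapply(docs, function(d)
    unique(m$author[m$document_id == d])[1], character(1))
  for (a in unique(m$author))
    if (sum(doc_author == a) < 2)
      stop("make_folds_by_document: author '", a, "' has fewer than 2 ",
           "documents; every training fold needs both classes")
  folds <- lapply(docs, function(d) {
    list(test = m$sample_id[m$document_id == d],
         train = m$sample_id[m$document_id != d])
  })
  names(folds) <- docs
  structure(list(folds = folds, grouping_key = "document_id"),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d leave-one-document-out folds (test sizes %s)\n",
              length(x$folds),
              paste(range(lengths(lapply(x$folds, `[[`, "test"))),
                    collapse = "-")))
  invisible(x)
}

#' Train a hard-margin RBF classifier
#'
#' Fits a C-classification SVM with an RBF kernel and a very large penalty
#' (see [kernel_params()]) on a samples-by-features matrix of logged
#' intensities. The returned model scores new samples with a real-valued
#' decision function oriented so that larger values favour the second author
#' level (sorted order).
#'
#' @param x numeric matrix, samples in rows, features in columns (no NAs).
#' @param labels author label per row (two classes).
#' @param params a [kernel_params()] object.
#' @return object of class `margin_classifier`.
#' @export
train_margin_classifier <- function(x, labels, params = kernel_params()) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stop("need exactly two classes, got ", length(lev))
  v <- stats::var(as.vector(x))
  if (!is.finite(v) || v == 0)
    stop("degenerate training matrix: zero overall variance")
  gamma <- if (params$gamma_mode == "auto") 1 / (ncol(x) * v)
           else params$gamma_value
  y <- factor(as.character(labels), levels = lev)
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = params$margin_hardness,
                    scale = FALSE)
  # e1071 decision values are positive towards the class named first in the
  # "A/B" column label; flip so positive always means lev[2]
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  first_named <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  structure(list(fit = fit, levels = lev, gamma = gamma,
                 flip = identical(first_named, lev[2])),
            class = "margin_classifier")
}

#' @export
predict.margin_classifier <- function(object, newdata, ...) {
  dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv)
  if (!object$flip) s <- -s
  names(s) <- rownames(newdata)
  s
}

#' Document-grouped cross validation
#'
#' For each fold of the plan: select features on the training portion only
#' (present in at least `screen$min_present` training spectra and absent in
#' all blank spectra), impute and log, fit the hard-margin classifier on the
#' training samples and score the held-out document. Out-of-fold decision
#' scores are pooled over folds, one score per non-blank sample.
#'
#' By default the training documents of each fold are balanced between the
#' two classes: holding one document out leaves its class under-represented,
#' and a hard-margin classifier fit to such skewed training data scores the
#' held-out document systematically towards the over-represented class (an
#' anti-learning artifact that drags a null pooled AUC far below 0.5).
#' Balancing drops just enough documents of the over-represented class,
#' chosen by a stable hash of the fold's test document so the whole
#' procedure is deterministic without consuming random numbers.
#'
#' With `paper_faithful = TRUE`, features are instead filtered once on the
#' full matrix before cross validation (presence counted over all samples)
#' and training folds are left unbalanced.
#'
#' @param matrix a `peak_matrix` of raw normalized intensities (blanks
#'   included; they inform the blank-absence rule but are never scored).
#' @param plan a [make_folds_by_document()] plan.
#' @param params a [kernel_params()] object.
#' @param screen a [screen_params()] object (filtering and imputation).
#' @param paper_faithful logical; see above.
#' @param balance_training logical; default `!paper_faithful`. See above.
#' @return object of class `msforge_cv`: pooled `scores`, true `labels`,
#'   `fold_of` (fold index per sample), `positive` class, and per-fold
#'   feature counts.
#' @export
crossval <- function(matrix, plan, params = kernel_params(),
                     screen = screen_params(), paper_faithful = FALSE,
                     balance_training = !paper_faithful) {
  stopifnot(inherits(matrix, "peak_matrix"), inherits(plan, "fold_plan"))
  meta <- matrix$meta
  blank_ids <- meta$sample_id[meta$is_blank]
  if (paper_faithful)
    matrix <- filter_features(matrix, screen)
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  scores <- stats::setNames(rep(NA_real_, length(all_test)), all_test)
  fold_of <- stats::setNames(rep(NA_integer_, length(all_test)), all_test)
  n_feat <- integer(length(plan$folds))
  lev <- sort(unique(meta$author[!meta$is_blank]))
  for (k in seq_along(plan$folds)) {
    f <- plan$folds[[k]]
    train <- f$train
    if (balance_training)
      train <- balance_train_docs(train, f$test, meta)
    fm <- matrix
    if (!paper_faithful) {
      keep <- feature_filter_mask(
        fm$values[, c(train, blank_ids), drop = FALSE],
        c(rep(FALSE, length(train)), rep(TRUE, length(blank_ids))),
        screen$min_present)
      fm <- subset_matrix(fm, features = keep)
    }
    n_feat[k] <- length(fm$mz)
    if (n_feat[k] == 0)
      stop("crossval: no features survive filtering in fold ", k)
    logged <- impute_and_log(fm, screen)
    xtr <- t(logged$values[, train, drop = FALSE])
    xte <- t(logged$values[, f$test, drop = FALSE])
    ytr <- meta$author[match(train, meta$sample_id)]
    model <- train_margin_classifier(xtr, ytr, params)
    scores[f$test] <- predict(model, xte)
    fold_of[f$test] <- k
  }
  labels <- meta$author[match(names(scores), meta$sample_id)]
  structure(list(scores = scores, labels = labels, fold_of = fold_of,
                 positive = lev[2], n_features = n_feat),
            class = "msforge_cv")
}

# drop documents of the over-represented class (lowest stable hash keyed by
# the test document first) until training document counts per class match
balance_train_docs <- function(train, test, meta) {
  tr_doc <- meta$document_id[match(train, meta$sample_id)]
  te_doc <- meta$document_id[match(test[1], meta$sample_id)]
  docs <- unique(tr_doc)
  doc_author <- meta$author[match(docs, meta$document_id)]
  tab <- table(doc_author)
  while (length(tab) == 2 && tab[1] != tab[2]) {
    major <- names(tab)[which.max(tab)]
    cand <- sort(docs[doc_author == major])
    hashes <- vapply(cand, function(d) stable_hash(0L, paste0(te_doc, d)),
                     integer(1))
    drop_doc <- cand[which.min(hashes)]
    keep <- docs != drop_doc
    docs <- docs[keep]
    doc_author <- doc_author[keep]
    train <- train[tr_doc != drop_doc]
    tr_doc <- tr_doc[tr_doc != drop_doc]
    tab <- table(doc_author)
  }
  train
}

#' @export
print.msforge_cv <- function(x, ...) {
  cat(sprintf("msforge_cv: %d samples over %d folds; positive class '%s'\n",
              length(x$scores), max(x$fold_of), x$positive))
  cat(sprintf("  features per fold: %s\n",
              paste(range(x$n_features), collapse = "-")))
  invisible(x)
}

#' Pooled ROC curve and AUC
#'
#' Thresholds the pooled out-of-fold decision scores (tied scores grouped at
#' one threshold) to trace the ROC from (0,0) to (1,1). The AUC is the
#' trapezoidal area, which with this construction equals the tie-corrected
#' Mann-Whitney statistic U / (n_pos * n_neg).
#'
#' @param result an `msforge_cv` object, or a list with numeric `scores` and
#'   `labels` where a label equal to `positive` marks the positive class.
#' @param positive positive class label; defaults to `result$positive` or the
#'   second sorted label.
#' @return object of class `msforge_roc`: data.frame `points` with columns
#'   threshold, fpr, tpr; scalar `auc`.
#' @export
roc_auc <- function(result, positive = NULL) {
  scores <- result$scores
  labels <- as.character(result$labels)
  if (is.null(positive))
    positive <- if (!is.null(result$positive)) result$positive
                else sort(unique(labels))[2]
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("roc_auc: both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc, positive = positive),
            class = "msforge_roc")
}

#' @export
print.msforge_roc <- function(x, ...) {
  cat(sprintf("msforge_roc: AUC %.4f (positive class '%s', %d points)\n",
              x$auc, x$positive, nrow(x$points)))
  invisible(x)
}

#' @export
plot.msforge_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Export a ROC curve as CSV
#'
#' Columns threshold, fpr, tpr.
#'
#' @param x an `msforge_roc`.
#' @param path output CSV path.
#' @export
write_roc_csv <- function(x, path) {
  stopifnot(inherits(x, "msforge_roc"))
  utils::write.csv(x$points, path, row.names = FALSE)
  invisible(path)
}
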