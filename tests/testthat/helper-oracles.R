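# Independent brute-force oracles. These deliberately re-derive each
# quantity with a naive formulation so the package implementation is checked
# against a second, independent route.

# naive greedy running-mean ppm clustering: recompute the mean with mean()
# at every step instead of carrying a running sum
oracle_greedy_cluster <- function(mz, ppm_tol) {
  n <- length(mz)
  if (n == 0) return(integer(0))
  cl <- integer(n)
  members <- mz[1]
  cur <- 1L
  cl[1] <- 1L
  for (i in seq_len(n)[-1]) {
    m <- mean(members)
    if (abs(mz[i] - m) / m * 1e6 <= ppm_tol) {
      members <- c(members, mz[i])
    } else {
      cur <- cur + 1L
      members <- mz[i]
    }
    cl[i] <- cur
  }
  cl
}

# textbook step-up BH: q_(i) = min_{j: rank_j >= rank_i} p_(j) * m / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# rank-statistic AUC: fraction of concordant positive-negative pairs, ties
# counted half
oracle_rank_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# small corpus for fast unit tests (not the acceptance-scale default)
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_documents_per_author = 3, replicates = 2, n_blanks = 2,
         n_background_features = 40, n_blank_contaminants = 6,
         seed = seed),
    list(...))
  do.call(corpus_config, args)
}

# one shared small corpus per test run, generated lazily
.shared <- new.env(parent = emptyenv())
shared_small_corpus <- function() {
  if (is.null(.shared$corpus)) {
    dir <- file.path(tempdir(), "msforge-shared-corpus")
    .shared$corpus <- generate_corpus(small_config(seed = 42), dir)
  }
  .shared$corpus
}

# aligned matrix for an on-disk corpus
corpus_matrix <- function(gen, ppm_tol = 5) {
  samples <- load_corpus(gen$manifest, gen$dir)
  sets <- lapply(align_greedy(samples, align_params(ppm_tol)),
                 dedupe_within_file)
  build_matrix(sets, gen$manifest)
}

# hand-built peak_matrix from a values matrix (features x samples)
toy_matrix <- function(values, mz = NULL, authors = NULL, blanks = 0,
                       substrate = "ink") {
  n <- ncol(values)
  nb <- n - blanks
  if (is.null(mz)) mz <- 100 + seq_len(nrow(values))
  if (is.null(authors)) authors <- rep(c("A", "B"), length.out = nb)
  meta <- data.frame(
    sample_id = c(sprintf("S%d", seq_len(nb)),
                  if (blanks) sprintf("blank_%d", seq_len(blanks))),
    file = "", document_id = c(sprintf("D%d", seq_len(nb)),
                               rep("", blanks)),
    author = c(rep_len(authors, nb), rep("", blanks)),
    substrate = c(rep_len(substrate, nb), rep("blank", blanks)),
    replicate = 1L, is_blank = c(rep(FALSE, nb), rep(TRUE, blanks)),
    stringsAsFactors = FALSE)
  colnames(values) <- meta$sample_id
  structure(list(mz = mz, values = values, meta = meta),
            class = "peak_matrix")
}
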