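norm_list <- function(...) {
  # build normalized single-file peak lists: norm_list(A = c(mz...), ...)
  args <- list(...)
  lapply(names(args), function(id) {
    spl <- sample_peaklist(data.frame(mz = args[[id]],
                                      intensity = rep(1, length(args[[id]]))),
                           meta = list(sample_id = id))
    normalize_tus(spl)
  })
}

test_that("greedy alignment groups peaks by ppm distance to the running mean", {
  # 3 ppm apart -> one peakset with the arithmetic mean m/z
  one <- align_greedy(norm_list(A = 100.0000, B = 100.0003))
  expect_length(one, 1)
  expect_equal(one[[1]]$mean_mz, 100.00015, tolerance = 1e-9)

  # 10 ppm apart -> two peaksets
  two <- align_greedy(norm_list(A = 100.0000, B = 100.0010))
  expect_length(two, 2)

  # running-mean rule: 100.0008 is ~6 ppm from mean(100.0000, 100.0004)
  sizes <- lengths(lapply(
    align_greedy(norm_list(A = c(100.0000, 100.0008), B = 100.0004)),
    function(s) s$members$mz))
  expect_equal(sizes, c(2, 1))
})

test_that("alignment requires normalized input", {
  raw <- sample_peaklist(data.frame(mz = 100, intensity = 1),
                         meta = list(sample_id = "A"))
  expect_error(align_greedy(list(raw)), "normalized")
  expect_error(align_greedy(list()), "no samples")
})

test_that("single-file alignment of well-separated peaks is one peakset per peak", {
  mzs <- 100 * (1 + (0:19) * 20e-6)  # 20 ppm spacing
  sets <- align_greedy(norm_list(A = mzs))
  expect_length(sets, 20)
})

test_that("within-file dedup keeps the most intense peak, low-mz on ties", {
  ps <- msforge:::new_peakset(data.frame(
    sample_id = c("S1", "S1", "S2"),
    mz = c(100.0000, 100.0003, 100.0001),
    intensity = c(5, 9, 4)))
  dd <- dedupe_within_file(ps)
  expect_equal(nrow(dd$members), 2)
  expect_equal(dd$members$intensity[dd$members$sample_id == "S1"], 9)
  expect_equal(dd$mean_mz, mean(c(100.0003, 100.0001)))

  tie <- msforge:::new_peakset(data.frame(
    sample_id = c("S1", "S1"), mz = c(100.0004, 100.0000),
    intensity = c(5, 5)))
  expect_equal(dedupe_within_file(tie)$members$mz, 100.0000)

  nodup <- msforge:::new_peakset(data.frame(
    sample_id = c("S1", "S2"), mz = c(100, 100.0002), intensity = c(1, 2)))
  expect_identical(dedupe_within_file(nodup), nodup)
})

test_that("every pooled peak lands in exactly one peakset", {
  set.seed(31)
  for (rep in 1:20) {
    lists <- lapply(1:4, function(i)
      sort(runif(sample(3:15, 1), 100, 102)))
    names(lists) <- paste0("S", 1:4)
    samples <- do.call(norm_list, lists)
    sets <- align_greedy(samples)
    got <- sort(unlist(lapply(sets, function(s) s$members$mz)))
    expect_equal(got, unname(sort(unlist(lists))))
  }
})

test_that("deduped peakset ppm spread stays within twice the tolerance", {
  # true features >= 25 ppm apart, per-file jitter ~1 ppm: in this regime
  # every member sits within the tolerance of the running mean and the
  # pairwise spread is bounded by twice the tolerance
  set.seed(37)
  for (rep in 1:20) {
    true_mz <- 100 * (1 + (0:14) * 25e-6)
    lists <- lapply(1:5, function(i)
      sort(true_mz * (1 + rnorm(15, 0, 1e-6))))
    names(lists) <- paste0("S", 1:5)
    sets <- lapply(align_greedy(do.call(norm_list, lists)),
                   dedupe_within_file)
    for (s in sets) {
      mz <- s$members$mz
      spread <- (max(mz) - min(mz)) / mean(mz) * 1e6
      expect_lte(spread, 2 * 5 + 1e-9)
    }
  }
})

test_that("greedy alignment matches an independent naive reimplementation", {
  set.seed(41)
  for (rep in 1:100) {
    n_files <- sample(1:5, 1)
    lists <- lapply(seq_len(n_files), function(i)
      sort(runif(sample(1:10, 1), 100, 100.5)))
    names(lists) <- paste0("S", seq_len(n_files))
    samples <- do.call(norm_list, lists)
    sets <- align_greedy(samples)

    pooled <- do.call(rbind, lapply(samples, function(s)
      data.frame(sample_id = s$meta$sample_id, mz = s$peaks$mz,
                 intensity = s$peaks$intensity)))
    pooled <- pooled[order(pooled$mz, pooled$sample_id,
                           -pooled$intensity), ]
    cl <- oracle_greedy_cluster(pooled$mz, 5)
    want_means <- sort(as.numeric(tapply(pooled$mz, cl, mean)))
    got_means <- vapply(sets, `[[`, numeric(1), "mean_mz")
    expect_equal(got_means, want_means)
  }
})

test_that("matrix construction places members and missing cells correctly", {
  manifest <- data.frame(
    sample_id = c("S1", "S2", "S3"), file = "", document_id = "d",
    author = "A", substrate = "ink", replicate = 1,
    is_blank = FALSE)
  ps1 <- msforge:::new_peakset(data.frame(
    sample_id = c("S1", "S2", "S3"), mz = c(100, 100.0001, 100.0002),
    intensity = c(1, 2, 3)))
  ps2 <- msforge:::new_peakset(data.frame(
    sample_id = "S2", mz = 200, intensity = 9))
  mat <- build_matrix(list(ps2, ps1), manifest)  # order by mean mz
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(mat$mz, c(mean(c(100, 100.0001, 100.0002)), 200))
  expect_equal(sum(is.na(mat$values)), 2)
  expect_equal(unname(mat$values[2, "S2"]), 9)

  empty <- build_matrix(list(), manifest)
  expect_equal(dim(empty), c(0L, 3L))

  bad <- msforge:::new_peakset(data.frame(sample_id = "SX", mz = 1,
                                          intensity = 1))
  expect_error(build_matrix(list(bad), manifest), "not in manifest")
  dup <- msforge:::new_peakset(data.frame(sample_id = c("S1", "S1"),
                                          mz = c(1, 1.0001),
                                          intensity = c(1, 2)))
  expect_error(build_matrix(list(dup), manifest), "dedup")
})

test_that("restricting a matrix to non-blank samples is a column projection", {
  gen <- shared_small_corpus()
  mat <- corpus_matrix(gen)
  keep <- !mat$meta$is_blank
  sub <- subset_matrix(mat, samples = which(keep))
  expect_equal(sub$values, mat$values[, keep])
  expect_equal(sub$meta$sample_id, mat$meta$sample_id[keep])
  expect_equal(sub$mz, mat$mz)
})

test_that("matrix CSV export writes mz at 6 decimals and empty missing cells", {
  mat <- toy_matrix(matrix(c(1, NA, 2, 3), nrow = 2), mz = c(100.1234567,
                                                             200.7654321))
  f <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(mat, f)
  got <- read.csv(f, colClasses = c(feature_mz = "character"))
  expect_equal(got$feature_mz, c("100.123457", "200.765432"))
  expect_true(is.na(got$S1[2]))
})
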