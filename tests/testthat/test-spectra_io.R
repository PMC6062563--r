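test_that("TSV peak lists read correctly across dialect variations", {
  base <- "mz\tintensity\n100.0\t5.0\n200.0\t15.0"
  variants <- list(lf = paste0(base, "\n"),
                   bare = base,
                   crlf = gsub("\n", "\r\n", paste0(base, "\n")),
                   comment = paste0("# a comment\n", base, "\n"))
  got <- lapply(variants, function(txt) {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeChar(txt, f, eos = NULL)
    read_peaklist_tsv(f)$peaks
  })
  expect_equal(got$lf, data.frame(mz = c(100, 200), intensity = c(5, 15)))
  for (v in got[-1]) expect_equal(v, got$lf)
})

test_that("TSV reader rejects malformed input with a line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mz\tintensity", "100.0\t5.0", "oops"), f)
  expect_error(read_peaklist_tsv(f), "line 3")
  writeLines(c("mz\tintensity", "100.0\tfoo"), f)
  expect_error(read_peaklist_tsv(f), "line 2")
  writeLines(c("mz\tintensity", "100.0\t-2"), f)
  expect_error(read_peaklist_tsv(f), "negative intensity")
  writeLines(c("mass\tintensity", "100.0\t5"), f)
  expect_error(read_peaklist_tsv(f), "header")
  expect_error(read_peaklist_tsv("no/such/file.tsv"), "not found")
})

test_that("empty TSV body yields an empty peak list with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mz\tintensity", f)
  expect_warning(spl <- read_peaklist_tsv(f), "no data rows")
  expect_s3_class(spl, "sample_peaklist")
  expect_equal(nrow(spl$peaks), 0)
})

test_that("total-usable-signal normalization scales to 1000 and guards misuse", {
  spl <- sample_peaklist(data.frame(mz = c(100, 200), intensity = c(2, 3)))
  norm <- normalize_tus(spl)
  expect_equal(norm$peaks$intensity, c(400, 600))
  expect_true(norm$normalized)
  expect_error(normalize_tus(norm), "already normalized")

  one <- normalize_tus(sample_peaklist(data.frame(mz = 150, intensity = 7)))
  expect_equal(one$peaks$intensity, 1000)

  zero <- sample_peaklist(data.frame(mz = c(1, 2), intensity = c(0, 0)))
  expect_error(normalize_tus(zero), "total usable signal")

  empty <- sample_peaklist(data.frame(mz = numeric(0),
                                      intensity = numeric(0)))
  expect_warning(e <- normalize_tus(empty), "empty")
  expect_true(e$normalized)
})

test_that("normalized sums are conserved at 1000 for random peak lists", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    spl <- sample_peaklist(data.frame(mz = sort(runif(n, 70, 700)),
                                      intensity = rexp(n, 1 / 50)))
    expect_equal(sum(normalize_tus(spl)$peaks$intensity), 1000,
                 tolerance = 1e-9)
  }
})

test_that("trace consolidation keeps consistent ions and drops rare ones", {
  mk_scan <- function(i, mz, int = 10) list(scan_index = i - 1L,
    peaks = data.frame(mz = mz, intensity = int))
  # one ion within +-0.5 ppm over 10 scans -> retained at the mean
  set.seed(1)
  scans <- lapply(1:10, function(i)
    mk_scan(i, 100 * (1 + runif(1, -0.5, 0.5) * 1e-6)))
  tr <- consolidate_traces(scans)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mz, 100, tolerance = 1e-6)

  # an ion in only 2 of 10 scans is dropped at min_scan_fraction 0.5
  scans2 <- lapply(1:10, function(i)
    mk_scan(i, if (i <= 2) c(100, 400) else 100))
  tr2 <- consolidate_traces(scans2)
  expect_equal(nrow(tr2), 1)
  expect_lt(abs(tr2$mz - 100), 0.001)

  expect_error(consolidate_traces(list()), "empty")
})

test_that("trace admission follows the running-mean ppm rule", {
  # scans at 100.0000, 100.0003, 100.0020: third is ~17 ppm from the running
  # mean 100.00015, starts its own trace with fraction 1/3 and is dropped
  scans <- lapply(c(100.0000, 100.0003, 100.0020), function(m)
    list(scan_index = 0L, peaks = data.frame(mz = m, intensity = 1)))
  tr <- consolidate_traces(scans)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$mz, 100.00015, tolerance = 1e-9)
})

test_that("trace count never increases with min_scan_fraction", {
  set.seed(11)
  scans <- lapply(1:8, function(i) {
    mz <- sort(sample(seq(100, 200, by = 5), sample(5:15, 1)) *
                 (1 + rnorm(1, 0, 1e-6)))
    list(scan_index = i - 1L, peaks = data.frame(mz = mz, intensity = 1))
  })
  counts <- vapply(c(0.1, 0.3, 0.5, 0.8, 1), function(f)
    nrow(consolidate_traces(scans, trace_params(min_scan_fraction = f))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trace consolidation matches the brute-force clustering oracle", {
  set.seed(23)
  for (rep in 1:50) {
    n_scans <- sample(2:5, 1)
    scans <- lapply(seq_len(n_scans), function(i) {
      n <- sample(1:6, 1)
      list(scan_index = i - 1L,
           peaks = data.frame(mz = sort(runif(n, 100, 101)),
                              intensity = rexp(n)))
    })
    pooled <- do.call(rbind, lapply(seq_along(scans), function(k)
      cbind(scans[[k]]$peaks, scan = k)))
    pooled <- pooled[order(pooled$mz, pooled$scan, -pooled$intensity), ]
    cl <- oracle_greedy_cluster(pooled$mz, 5)
    keep <- tapply(pooled$scan, cl, function(s) length(unique(s))) /
      n_scans >= 0.5
    want_mz <- sort(as.numeric(tapply(pooled$mz, cl, mean)[keep]))
    got <- consolidate_traces(scans)
    expect_equal(got$mz, want_mz)
  }
})

test_that("mzML written scans read back identically, MS2 skipped, profile rejected", {
  skip_if_not_installed("mzR")
  f <- withr::local_tempfile(fileext = ".mzML")
  scans <- list(cbind(mz = c(100.0001, 250.5), intensity = c(10, 20)),
                cbind(mz = c(100.0002, 300.1), intensity = c(5, 7)),
                cbind(mz = c(100.0003, 410.9), intensity = c(2, 9)))
  write_mzml(scans, f)
  got <- read_mzml(f)
  expect_length(got, 3)
  expect_equal(got[[1]]$scan_index, 0L)
  for (i in 1:3) {
    expect_equal(got[[i]]$peaks$mz, scans[[i]][, "mz"], tolerance = 1e-10)
    expect_equal(got[[i]]$peaks$intensity, scans[[i]][, "intensity"],
                 tolerance = 1e-10)
  }

  f2 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(scans, f2, ms_levels = c(1L, 2L, 1L))
  got2 <- read_mzml(f2)
  expect_length(got2, 2)
  expect_equal(got2[[2]]$peaks$mz, scans[[3]][, "mz"], tolerance = 1e-10)

  f3 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(scans, f3, centroided = FALSE)
  expect_error(read_mzml(f3), "centroided input required")

  f4 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(scans, f4, ms_levels = 2L)
  expect_error(read_mzml(f4), "no MS1")

  expect_error(read_mzml("no/such.mzML"), "not found")
})

test_that("manifest reader validates structure and blank consistency", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,file,document_id,author,substrate,replicate,is_blank",
               "s1,s1.tsv,d1,A,ink,1,0",
               "b1,b1.tsv,,,blank,1,1"), f)
  m <- read_manifest(f)
  expect_identical(m$is_blank, c(FALSE, TRUE))

  writeLines(c("sample_id,file,document_id,author,substrate,replicate,is_blank",
               "s1,s1.tsv,d1,A,ink,1,1"), f)
  expect_error(read_manifest(f), "inconsistent")
  writeLines(c("sample_id,file,document_id,author,substrate,replicate,is_blank",
               "s1,s1.tsv,d1,A,ink,1,0",
               "s1,s2.tsv,d1,A,ink,2,0"), f)
  expect_error(read_manifest(f), "duplicate")
})

test_that("reading generator-written files reproduces its in-memory peak lists", {
  gen <- shared_small_corpus()
  for (id in gen$manifest$sample_id[c(1, 7, nrow(gen$manifest))]) {
    path <- file.path(gen$dir, paste0(id, ".tsv"))
    got <- read_peaklist_tsv(path)
    want <- gen$peaklists[[id]]
    expect_equal(got$peaks$mz, want$peaks$mz, tolerance = 1e-8)
    expect_equal(got$peaks$intensity, want$peaks$intensity,
                 tolerance = 1e-7)
  }
})
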