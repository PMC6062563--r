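test_that("default design yields the expected manifest layout", {
  cfg <- corpus_config()
  d <- withr::local_tempdir()
  gen <- generate_corpus(cfg, d)
  # 2 authors x 5 docs x 2 substrates x 3 replicates + 4 blanks
  expect_equal(nrow(gen$manifest), 64)
  expect_equal(sum(gen$manifest$is_blank), 4)
  expect_equal(length(unique(gen$manifest$document_id[
    gen$manifest$is_blank == 0])), 10)
  expect_true(all(file.exists(gen$files)))
  # 300 background + 8 + 8 diagnostics + 20 contaminants
  expect_equal(nrow(gen$truth), 336)
  expect_equal(table(gen$truth$class)[["contaminant"]], 20)
})

test_that("config invariants are enforced before anything is written", {
  expect_error(corpus_config(missing_rate = 1), "missing_rate")
  expect_error(corpus_config(n_blanks = 0), "counts")
  expect_error(corpus_config(diagnostic_mz_a = c(100, 200),
                             diagnostic_mz_b = c(200, 300)), "disjoint")
  expect_error(corpus_config(mz_jitter_ppm_sd = 0), "jitter")
})

test_that("identical seeds give byte-identical corpora", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpus(small_config(seed = 5), d1)
  generate_corpus(small_config(seed = 5), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_corpus(small_config(seed = 6), d3)
  h3 <- unname(tools::md5sum(file.path(d3, sort(list.files(d3)))))
  expect_false(identical(h1, h3))
})

test_that("per-file substreams are stable when a sample is added", {
  base <- generate_corpus(small_config(seed = 8), withr::local_tempdir())
  bigger <- generate_corpus(small_config(seed = 8, n_blanks = 3),
                            withr::local_tempdir())
  id <- "A_d1_ink_r1"
  expect_equal(base$peaklists[[id]]$peaks, bigger$peaklists[[id]]$peaks)
})

test_that("planted diagnostics each map to exactly one aligned peakset", {
  gen <- shared_small_corpus()
  samples <- load_corpus(gen$manifest, gen$dir)
  sets <- align_greedy(samples)
  means <- vapply(sets, `[[`, numeric(1), "mean_mz")
  diag_mz <- gen$truth$feature_mz[gen$truth$class %in%
                                    c("author_A", "author_B")]
  for (m in diag_mz)
    expect_equal(sum(abs(means - m) / m * 1e6 <= 5), 1)
})

test_that("the blank filter removes every planted contaminant", {
  gen <- shared_small_corpus()
  mat <- corpus_matrix(gen)
  kept <- filter_features(mat)$mz
  cont <- gen$truth$feature_mz[gen$truth$class == "contaminant"]
  for (m in cont)
    expect_false(any(abs(kept - m) / m * 1e6 <= 5))
})

test_that("null corpora share the background m/z grid and carry no signal", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sig <- generate_corpus(small_config(seed = 21), d1)
  nul <- generate_null_corpus(small_config(seed = 21), d2)
  bg <- function(g) g$truth$feature_mz[g$truth$class == "background"]
  expect_identical(bg(sig), bg(nul))
  # diagnostic rows lose class-specific presence: planted everywhere
  nb <- nul$manifest$sample_id[nul$manifest$is_blank == 0]
  planted <- strsplit(nul$truth$planted_in[
    nul$truth$class == "author_A"][1], ";")[[1]]
  expect_gt(length(intersect(planted,
                             nul$manifest$sample_id[
                               nul$manifest$author == "B"])), 0)
})

test_that("truth_report scores selections against the planted diagnostics", {
  gen <- shared_small_corpus()
  diag_mz <- gen$truth$feature_mz[gen$truth$class %in%
                                    c("author_A", "author_B")]
  exact <- truth_report(gen$truth, diag_mz)
  expect_equal(exact$recall, 1)
  expect_equal(exact$false_discovery_fraction, 0)
  none <- truth_report(gen$truth, numeric(0))
  expect_equal(none$recall, 0)
  mixed <- truth_report(gen$truth, c(diag_mz[1], 500.0))
  expect_equal(mixed$false_discovery_fraction, 0.5)
})

test_that("m/z jitter beyond the alignment tolerance degrades recall", {
  recalls <- vapply(c(1, 10, 30), function(j) {
    d <- withr::local_tempdir()
    gen <- generate_corpus(small_config(seed = 17, mz_jitter_ppm_sd = j,
                                        n_background_features = 30), d)
    mat <- corpus_matrix(gen)
    sel <- select_diagnostic(differential_analysis(mat))
    truth_report(gen$truth, sel)$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_lt(recalls[3], recalls[1])
})

test_that("mzML corpora round-trip through trace consolidation", {
  skip_if_not_installed("mzR")
  d <- withr::local_tempdir()
  gen <- generate_corpus(small_config(seed = 12,
                                      n_background_features = 15,
                                      n_blank_contaminants = 3), d,
                         format = "mzml")
  id <- gen$manifest$sample_id[1]
  scans <- read_mzml(file.path(d, gen$manifest$file[1]))
  expect_length(scans, small_config()$n_scans_per_file)
  traces <- consolidate_traces(scans)
  want <- gen$peaklists[[id]]$peaks
  expect_equal(nrow(traces), nrow(want))
  expect_equal(traces$mz, want$mz, tolerance = 1e-5)
})
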