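test_that("read_probes round-trips a well-formed TSV and applies the NA policy", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tintensity\tallele_ratio",
               "1\t100\t2.1\t0.49",
               "1\t200\t1.9\t0.51",
               "17\t300\t4.2\t0.25"), tsv)
  ps <- read_probes(tsv, sample_id = "s1")
  expect_s3_class(ps, "probe_set")
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$intensity, c(2.1, 1.9, 4.2))
  expect_equal(attr(ps, "sample_id"), "s1")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_probes(ps, out)
  expect_equal(as.data.frame(read_probes(out, sample_id = "s1")),
               as.data.frame(ps))

  # allele_ratio column optional
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tintensity", "1\t100\t2", "1\t200\t2"), tsv2)
  ps2 <- read_probes(tsv2)
  expect_true(all(is.na(ps2$allele_ratio)))

  # NA intensity rows dropped with a message
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tintensity", "1\t100\t2", "1\t200\tNA", "1\t300\t2.2"),
             tsv3)
  expect_message(ps3 <- read_probes(tsv3), "dropped 1 probe")
  expect_equal(nrow(ps3), 2L)

  # malformed numeric names the line
  tsv4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tintensity", "1\t100\t2", "1\t200\tbogus"), tsv4)
  expect_error(suppressWarnings(read_probes(tsv4)), "line 3")
})

test_that("probe_set validates and sorts", {
  df <- data.frame(chrom = c("2", "1"), pos = c(5, 10), intensity = c(1, 2))
  expect_message(ps <- probe_set(df), "sorting")
  expect_equal(ps$chrom, c("1", "2"))
  expect_error(probe_set(data.frame(chrom = "1", pos = 0, intensity = 1)), ">= 1")
  expect_error(probe_set(data.frame(chrom = "1", pos = 1, intensity = -1)), ">= 0")
  expect_error(probe_set(data.frame(chrom = "1", pos = 1, intensity = 1,
                                    allele_ratio = 1.2)), "\\[0, 1\\]")
  expect_error(probe_set(data.frame(chrom = "1", pos = c(1, 1),
                                    intensity = c(1, 1))), "duplicate")
})

test_that("normalize_baseline2 sets the genome mean to 2 and only rescales", {
  expect_equal(mean(normalize_baseline2(toy_probes(rep(4, 10)))$intensity), 2,
               tolerance = 1e-12)
  ps <- toy_probes(c(1, 2, 3))
  expect_equal(normalize_baseline2(ps)$intensity, c(1, 2, 3)) # mean already 2
  ps2 <- toy_probes(c(2, 4, 6))
  expect_equal(normalize_baseline2(ps2)$intensity, c(1, 2, 3))
  # uniformly tetraploid is indistinguishable from diploid after normalization
  expect_equal(normalize_baseline2(toy_probes(rep(4, 50)))$intensity,
               rep(2, 50))
  expect_error(normalize_baseline2(toy_probes(rep(0, 5))), "not positive")
})

test_that("normalize_baseline2 is idempotent and scale-invariant", {
  withr::local_seed(42)
  for (rep_i in 1:5) {
    x <- runif(200, 0.5, 6)
    ps <- toy_probes(x)
    once <- normalize_baseline2(ps)
    expect_equal(normalize_baseline2(once)$intensity, once$intensity,
                 tolerance = 1e-9)
    k <- runif(1, 0.1, 10)
    expect_equal(normalize_baseline2(toy_probes(k * x))$intensity,
                 once$intensity, tolerance = 1e-9)
  }
})

test_that("SEG writer validates, round-trips, and emits header-only for empty input", {
  seg <- data.frame(chrom = "17", start_pos = 1, end_pos = 100, n_probes = 10,
                    mean_intensity = 2.35)
  f <- withr::local_tempfile(fileext = ".seg")
  write_segments_seg(seg, f, sample_id = "s")
  back <- read_segments_seg(f)
  expect_equal(back$mean_intensity, 2.35)
  expect_equal(back$start_pos, 1)
  expect_equal(attr(back, "sample_id"), "s")

  empty <- seg[0, ]
  f2 <- withr::local_tempfile(fileext = ".seg")
  write_segments_seg(empty, f2)
  expect_equal(length(readLines(f2)), 1L) # header only

  overlap <- rbind(seg, data.frame(chrom = "17", start_pos = 50, end_pos = 150,
                                   n_probes = 5, mean_intensity = 2))
  expect_error(write_segments_seg(overlap, f2), "overlapping")

  # round-trip at printed precision for a full segmentation
  withr::local_seed(7)
  segs <- segment_sample(toy_probes(rnorm(300, 2, 0.1)))
  f3 <- withr::local_tempfile(fileext = ".seg")
  write_segments_seg(segs, f3)
  back3 <- read_segments_seg(f3)
  expect_equal(back3$mean_intensity, segs$mean_intensity, tolerance = 1e-4)
  expect_equal(back3$n_probes, segs$n_probes)
})

test_that("table 1 fixture matches the published per-sample values", {
  t1 <- load_table1()
  expect_equal(nrow(t1), 65L)
  r1 <- t1[t1$sample == 1, ]
  expect_equal(r1$ihc, 0)
  expect_true(is.na(r1$fish))
  expect_equal(r1$snp_cn, 1.98)
  expect_equal(r1$relation, "balance")
  expect_equal(r1$status, "normal")
  r49 <- t1[t1$sample == 49, ]
  expect_equal(r49$ihc, 2)
  expect_equal(r49$fish, 0.93)
  expect_equal(r49$ihc_revised, 3)
  expect_equal(r49$fish_revised, 8.8)
  expect_equal(r49$snp_cn, 11.10)
  r65 <- t1[t1$sample == 65, ]
  expect_equal(r65$ihc, 3)
  expect_equal(r65$fish, 1.35)
  expect_equal(r65$snp_cn, 3.75)
  expect_equal(r65$relation, "HER2plus")
  expect_equal(r65$status, "amp")
  # cohort IHC composition
  expect_equal(as.integer(table(t1$ihc)), c(12L, 15L, 32L, 6L))
})

test_that("table 2 fixture matches the published polyploidy summary", {
  t2 <- load_table2()
  expect_equal(nrow(t2), 65L)
  expect_equal(sum(t2$polyploid), 45L)
  expect_equal(t2$her2_estimate[t2$sample == 45], "8+")
  expect_equal(t2$fish_3d[t2$sample == 45], "8")
  expect_equal(t2$her2_estimate[t2$sample == 43], "UPD(2) or amp")
  expect_equal(sum(!is.na(t2$fish_3d)), 9L)
})
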