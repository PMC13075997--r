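test_that("per-base coverage counts covering fragments", {
  fs <- fragment_set(data.frame(chrom = "c", start = c(0, 2), end = c(4, 6)))
  tr <- coverage_from_fragments(fs, c(c = 8))
  expect_equal(as.numeric(tr$values$c), c(1, 1, 2, 2, 1, 1, 0, 0))
  expect_equal(tr$mode, "raw")

  empty <- fragment_set(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()))
  expect_equal(as.numeric(coverage_from_fragments(empty, c(c = 5))$values$c),
               rep(0, 5))
  one <- fragment_set(data.frame(chrom = "c", start = 0, end = 7))
  expect_equal(as.numeric(coverage_from_fragments(one, c(c = 7))$values$c),
               rep(1, 7))
})

test_that("out-of-bounds fragments are rejected with the offending record", {
  fs <- fragment_set(data.frame(chrom = "c", start = 5, end = 12))
  expect_error(coverage_from_fragments(fs, c(c = 10)), "c:5-12")
  fs2 <- fragment_set(data.frame(chrom = "weird", start = 0, end = 5))
  expect_error(coverage_from_fragments(fs2, c(c = 10)), "weird")
})

test_that("normalization is fraction-of-counts scaled by genome size", {
  # uniform raw coverage maps every base to exactly 1
  fs <- fragment_set(data.frame(chrom = "c", start = rep(0, 3), end = rep(10, 3)))
  norm <- normalize_coverage(coverage_from_fragments(fs, c(c = 10)))
  expect_identical(unique(as.numeric(norm$values$c)), 1)
  expect_equal(norm$mode, "coverage_normalized")

  fs2 <- fragment_set(data.frame(chrom = "c", start = c(0, 3), end = c(1, 4)))
  norm2 <- normalize_coverage(coverage_from_fragments(fs2, c(c = 4)))
  expect_equal(as.numeric(norm2$values$c), c(2, 0, 0, 2))

  # conservation: normalized values sum to G
  set.seed(4)
  fs3 <- fragment_set(random_frags(40, 500))
  norm3 <- normalize_coverage(coverage_from_fragments(fs3, c(c = 500)))
  expect_equal(track_sum(norm3), 500, tolerance = 1e-6)
})

test_that("normalization is invariant to scaling all raw counts", {
  set.seed(7)
  d <- random_frags(25, 300)
  t1 <- normalize_coverage(coverage_from_fragments(fragment_set(d), c(c = 300)))
  d3 <- do.call(rbind, list(d, d, d))
  t3 <- normalize_coverage(coverage_from_fragments(fragment_set(d3), c(c = 300)))
  expect_equal(as.numeric(t1$values$c), as.numeric(t3$values$c))
})

test_that("an empty track cannot be normalized", {
  empty <- coverage_from_fragments(
    fragment_set(data.frame(chrom = character(), start = numeric(), end = numeric())),
    c(c = 10))
  expect_error(normalize_coverage(empty), "empty track")
})

test_that("spike scale factor is 10,000 over the spike-in count", {
  expect_equal(spike_scale_factor(10000), 1)
  expect_equal(spike_scale_factor(2000), 5)
  expect_error(spike_scale_factor(0), "spike")
})

test_that("calibration is linear multiplication of raw counts", {
  fs <- fragment_set(data.frame(chrom = "c", start = c(0, 1, 1), end = c(3, 4, 2)))
  raw <- coverage_from_fragments(fs, c(c = 6))
  cal <- calibrate_track(raw, 5)
  expect_equal(max(as.numeric(cal$values$c)), max(as.numeric(raw$values$c)) * 5)
  expect_equal(cal$mode, "spike_calibrated")
  expect_equal(as.numeric(calibrate_track(raw, 1)$values$c),
               as.numeric(raw$values$c))
  # composing factors equals calibrating with the product
  ab <- calibrate_track(raw, 2 * 3)$values$c
  expect_equal(as.numeric(ab), as.numeric(raw$values$c) * 6)
  # doubling the spike-in count halves all values
  half <- calibrate_track(raw, spike_scale_factor(4000))
  full <- calibrate_track(raw, spike_scale_factor(2000))
  expect_equal(as.numeric(half$values$c) * 2, as.numeric(full$values$c))
})

test_that("tracks round-trip through bedGraph with metadata", {
  set.seed(11)
  fs <- fragment_set(random_frags(30, 400))
  tr <- normalize_coverage(coverage_from_fragments(fs, c(c = 400, c2 = 50)))
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_track(tr, p)
  back <- read_track(p)
  expect_equal(back$mode, tr$mode)
  expect_equal(back$genome_size, tr$genome_size)
  expect_equal(as.numeric(back$values$c), as.numeric(tr$values$c), tolerance = 1e-7)
  expect_equal(as.numeric(back$values$c2), rep(0, 50))
})

test_that("bedGraph omits zero runs and merges equal-value runs", {
  tr <- splicechrom:::new_coverage_track(
    list(c = S4Vectors::Rle(c(1, 1, 2), c(1, 1, 1))), "raw", 3)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_track(tr, p)
  body <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_length(body, 2) # [0,2)=1 and [2,3)=2
  zero <- splicechrom:::new_coverage_track(list(c = S4Vectors::Rle(0, 5)), "raw", 5)
  write_track(zero, p)
  expect_length(grep("^#", readLines(p), invert = TRUE, value = TRUE), 0)
})

test_that("unsorted bedGraph input is rejected", {
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("# splicechrom_track mode=raw genome_size=10",
               "# chrom_lengths c:10",
               "c\t5\t7\t1", "c\t0\t2\t1"), p)
  expect_error(read_track(p), "unsorted")
})

test_that("pooling fragment sets concatenates fragments and sums spike-ins", {
  a <- fragment_set(data.frame(chrom = "c", start = 0, end = 5), "a", 100)
  b <- fragment_set(data.frame(chrom = "c", start = 2, end = 9), "b", 250)
  pooled <- pool_fragments(a, b)
  expect_equal(n_fragments(pooled), 2)
  expect_equal(pooled$spike_in_count, 350)
})

test_that("sample sheets are validated", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tfragments_path\tspike_in_count\ns1\tx.bed\t100", p)
  expect_equal(read_sample_sheet(p)$spike_in_count, 100)
  writeLines("sample\tpath\ns1\tx.bed", p)
  expect_error(read_sample_sheet(p), "missing column")
})
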