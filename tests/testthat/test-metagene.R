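const_track <- function(value, len) {
  splicechrom:::new_coverage_track(list(c = S4Vectors::Rle(value, len)), "raw", len)
}

test_that("reference-point rows are bin means around the oriented anchor", {
  # constant track -> every cell equals the constant
  tr <- const_track(3.5, 10000)
  g <- gene_model("g", "c", 5000, 6000, "+", 5000, 6000)
  m <- metagene_reference_point(tr, list(g), "TSS", 1000, 1000, 50)
  expect_equal(dim(m), c(1L, 40L))
  expect_true(all(m == 3.5))

  # step track: 0 upstream of the TSS, 1 downstream, plus gene
  step <- splicechrom:::new_coverage_track(
    list(c = S4Vectors::Rle(c(0, 1), c(5000, 5000))), "raw", 10000)
  ms <- metagene_reference_point(step, list(g), "TSS", 1000, 1000, 100)
  expect_equal(as.numeric(ms[1, ]), c(rep(0, 10), rep(1, 10)))
})

test_that("minus-strand windows are mirrored so left = upstream", {
  step <- splicechrom:::new_coverage_track(
    list(c = S4Vectors::Rle(c(0, 1), c(5000, 5000))), "raw", 10000)
  # minus-strand gene whose TSS sits at coordinate 5000: upstream (in
  # transcription direction) is the high-coordinate side with value 1... the
  # step is 0 below 5000, so upstream bins read 1 and downstream bins read 0
  gm <- gene_model("gm", "c", 4000, 5000, "-", 4000, 5000)
  m <- metagene_reference_point(step, list(gm), "TSS", 1000, 1000, 100)
  expect_equal(as.numeric(m[1, ]), c(rep(1, 10), rep(0, 10)))
})

test_that("a plus gene and its mirrored minus twin give identical rows", {
  set.seed(31)
  len <- 4000
  vals <- rpois(len, 2)
  tr <- splicechrom:::new_coverage_track(list(c = S4Vectors::Rle(vals)), "raw", len)
  trm <- splicechrom:::new_coverage_track(list(c = S4Vectors::Rle(rev(vals))), "raw", len)
  gp <- gene_model("gp", "c", 1500, 2500, "+", c(1500, 2100), c(1700, 2500))
  gm <- gene_model("gm", "c", len - 2500, len - 1500, "-",
                   len - c(2500, 1700), len - c(2100, 1500))
  for (anchor in c("TSS", "TES")) {
    mp <- metagene_reference_point(tr, list(gp), anchor, 500, 500, 50)
    mm <- metagene_reference_point(trm, list(gm), anchor, 500, 500, 50)
    expect_equal(as.numeric(mp), as.numeric(mm))
  }
  sp <- metagene_scale_regions(tr, list(gp), 500, 500, 20, 50)
  sm <- metagene_scale_regions(trm, list(gm), 500, 500, 20, 50)
  expect_equal(as.numeric(sp), as.numeric(sm))
})

test_that("bin means match the brute-force oracle on random tracks", {
  set.seed(33)
  for (i in 1:30) {
    len <- sample(2000:6000, 1)
    vals <- sample(0:5, len, replace = TRUE)
    tr <- splicechrom:::new_coverage_track(list(c = S4Vectors::Rle(vals)), "raw", len)
    a <- sample(600:(len - 600), 1)
    strand <- sample(c("+", "-"), 1)
    g <- gene_model("g", "c", a, a + 500, strand, a, a + 500)
    bs <- sample(c(20, 50, 100), 1)
    m <- metagene_reference_point(tr, list(g), "TSS", 500, 500, bs)
    anchor <- if (strand == "-") a + 500 else a
    win <- if (strand == "-") rev(vals[(anchor - 500 + 1):(anchor + 500)])
           else vals[(anchor - 500 + 1):(anchor + 500)]
    expect_equal(as.numeric(m[1, ]), oracle_bin_means(win, bs))
  }
})

test_that("out-of-chromosome bins are missing, not zero", {
  tr <- const_track(2, 1000)
  g <- gene_model("g", "c", 100, 300, "+", 100, 300)
  m <- metagene_reference_point(tr, list(g), "TSS", 500, 500, 100)
  expect_true(all(is.na(m[1, 1:4]))) # window starts at -400
  expect_true(all(m[1, 5:10] == 2))
  prof <- column_mean_profile(m)
  expect_true(all(is.na(prof[1:4])))
})

test_that("scale-regions is invariant to gene length for constant signal", {
  tr <- const_track(1.25, 50000)
  g1 <- gene_model("a", "c", 10000, 13000, "+", 10000, 13000)
  g2 <- gene_model("b", "c", 20000, 29000, "-", 20000, 29000)
  m <- metagene_scale_regions(tr, list(g1, g2), 1000, 1000, 100, 50)
  expect_equal(dim(m), c(2L, 140L))
  expect_equal(as.numeric(m[1, ]), as.numeric(m[2, ]))
  expect_true(all(m == 1.25))
})

test_that("scale-regions spreads the remainder over leftmost bins", {
  len <- 103 # 3 bins of 35,34,34 for body_bins = 3
  vals <- seq_len(len)
  tr <- splicechrom:::new_coverage_track(
    list(c = S4Vectors::Rle(c(rep(0, 1000), vals, rep(0, 1000)))), "raw", len + 2000)
  g <- gene_model("g", "c", 1000, 1000 + len, "+", 1000, 1000 + len)
  m <- metagene_scale_regions(tr, list(g), 0, 0, 3, 50)
  expect_equal(as.numeric(m[1, ]),
               c(mean(vals[1:35]), mean(vals[36:69]), mean(vals[70:103])))
})

test_that("genes shorter than body_bins are dropped with a warning", {
  tr <- const_track(1, 10000)
  short <- gene_model("tiny", "c", 5000, 5050, "+", 5000, 5050)
  ok <- gene_model("ok", "c", 6000, 7000, "+", 6000, 7000)
  expect_warning(m <- metagene_scale_regions(tr, list(short, ok), 100, 100, 100, 50),
                 "tiny")
  expect_equal(rownames(m), "ok")
  expect_equal(attr(m, "dropped"), "tiny")
})

test_that("column mean profile behaves as the average plot", {
  m <- splicechrom:::new_metagene_matrix(
    matrix(c(0, 2, 0, 2, 0, 2), nrow = 2), "reference-point TSS", 1, 1, 2)
  rownames(m) <- c("a", "b")
  expect_equal(column_mean_profile(m), c(1, 1, 1))
  expect_equal(column_mean_profile(m[2:1, ]), c(1, 1, 1)) # row-permutation invariant
  single <- m[1, , drop = FALSE]
  expect_equal(column_mean_profile(single), as.numeric(m[1, ]))
  expect_error(column_mean_profile(m[0, , drop = FALSE]), "empty")
})

test_that("metagene matrices are invariant to fragment input order", {
  set.seed(35)
  d <- random_frags(80, 5000)
  g <- gene_model("g", "c", 2000, 3000, "+", 2000, 3000)
  t1 <- coverage_from_fragments(fragment_set(d), c(c = 5000))
  t2 <- coverage_from_fragments(fragment_set(d[sample(nrow(d)), ]), c(c = 5000))
  expect_equal(
    as.numeric(metagene_reference_point(t1, list(g), "TSS", 500, 500, 50)),
    as.numeric(metagene_reference_point(t2, list(g), "TSS", 500, 500, 50)))
})

test_that("metagene matrices round-trip through gzip TSV", {
  tr <- const_track(2, 20000)
  g <- list(gene_model("a", "c", 5000, 8000, "+", 5000, 8000),
            gene_model("b", "c", 12000, 15000, "-", 12000, 15000))
  m <- metagene_scale_regions(tr, g, 1000, 1000, 50, 50)
  p <- withr::local_tempfile(fileext = ".tsv.gz")
  write_metagene_matrix(m, p)
  back <- read_metagene_matrix(p)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-9)
  expect_equal(attr(back, "anchor"), attr(m, "anchor"))
  expect_equal(attr(back, "body_bins"), attr(m, "body_bins"))
})
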