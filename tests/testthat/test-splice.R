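ev <- function(gene, type, dpsi, p) {
  data.frame(gene_id = gene, event_type = type, delta_psi = dpsi, p_value = p,
             stringsAsFactors = FALSE)
}

test_that("significance is strict at the threshold", {
  expect_true(is_significant(0.049))
  expect_false(is_significant(0.05))
  expect_false(is_significant(1))
  expect_false(is_significant(NA_real_))
})

test_that("event types map to error categories", {
  expect_equal(error_type("SE"), "exon_inclusion")
  expect_equal(error_type("MXE"), "exon_inclusion")
  expect_equal(error_type("RI"), "intron_removal")
  expect_equal(error_type(c("A5SS", "A3SS")), rep("splice_site", 2))
  expect_error(error_type("XX"), "unknown")
})

test_that("gene exon classes follow sign, significance, and precedence", {
  expect_equal(classify_gene_exon(ev("g", "SE", 0.3, 0.01)), "skipped")
  expect_equal(classify_gene_exon(ev("g", "SE", -0.3, 0.01)), "included")
  expect_equal(classify_gene_exon(ev("g", "MXE", 0.2, 0.001)), "MXE")
  expect_equal(classify_gene_exon(ev("g", "SE", 0.5, 0.2)), "unchanged")
  expect_equal(classify_gene_exon(ev("g", "RI", 0.5, 0.001)), "untested")
  # precedence: skipped beats included beats MXE
  multi <- rbind(ev("g", "SE", 0.4, 0.01), ev("g", "SE", -0.4, 0.001),
                 ev("g", "MXE", 0.2, 0.001))
  expect_equal(classify_gene_exon(multi), "skipped")
  expect_equal(classify_gene_exon(multi, precedence = c("included", "skipped", "MXE")),
               "included")
  expect_equal(classify_gene_exon(rbind(ev("g", "SE", 0.4, 0.8),
                                        ev("g", "MXE", 0.1, 0.01))), "MXE")
})

test_that("gene intron classes use the WT-minus-KD sign convention", {
  expect_equal(classify_gene_intron(ev("g", "RI", -0.4, 0.001)), "retained")
  expect_equal(classify_gene_intron(ev("g", "RI", 0.4, 0.001)), "removed")
  expect_equal(classify_gene_intron(ev("g", "RI", 0.4, 0.5)), "unchanged")
  expect_equal(classify_gene_intron(ev("g", "SE", 0.4, 0.001)), "untested")
})

test_that("event tables validate bounds and orientation flips on read", {
  expect_error(splice_events(ev("g", "SE", 1.5, 0.1)), "delta_psi")
  expect_error(splice_events(ev("g", "SE", 0.5, 1.2)), "p_value")
  expect_error(splice_events(ev("g", "ZZ", 0.5, 0.2)), "unknown")
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tevent_type\tIncLevelDifference\tPValue",
               "g1\tSE\t0.4\t0.01"), p)
  expect_equal(read_splice_events(p)$delta_psi, 0.4)
  expect_equal(read_splice_events(p, orientation = "kd_minus_wt")$delta_psi, -0.4)
})

test_that("raw rMATS layouts convert by column name", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste("ID", "GeneID", "geneSymbol", "PValue", "FDR",
                     "IncLevelDifference", sep = "\t"),
               paste("1", '"g9"', "G9", "0.003", "0.01", "0.25", sep = "\t")), p)
  e <- rmats_to_events(p, "SE")
  expect_equal(e$gene_id, "g9")
  expect_equal(e$delta_psi, 0.25)
  expect_equal(e$event_type, "SE")
  expect_error(rmats_to_events(p, "QQ"), "unknown")
})

test_that("class summaries count, partition, and round as printed", {
  events <- rbind(ev("a", "SE", 0.4, 0.01),   # skipped
                  ev("b", "SE", -0.4, 0.01),  # included
                  ev("c", "SE", 0.1, 0.9),    # unchanged
                  ev("c", "RI", -0.5, 0.01),  # retained
                  ev("d", "A5SS", 0.3, 0.01)) # splice-site only -> untested exon
  cls <- classify_splice_genes(events)
  expect_equal(nrow(cls), 4)
  expect_equal(cls$exon_class[cls$gene_id == "d"], "untested")
  s <- summarize_splice_classes(cls)
  expect_equal(s$n_exon_tested, 3)
  expect_equal(s$error_genes, 2)
  expect_equal(s$error_percent, 67)
  expect_equal(sum(s$exon$count), s$n_exon_tested)
  expect_equal(s$intron$count[s$intron$class == "retained"], 1)
  # 1 of 3 rounds to 33
  one_of_three <- data.frame(gene_id = c("x", "y", "z"),
                             exon_class = c("skipped", "unchanged", "unchanged"),
                             intron_class = "untested")
  expect_equal(summarize_splice_classes(one_of_three)$error_percent, 33)
})

test_that("event-level error breakdown covers significant events only", {
  events <- rbind(ev("a", "SE", 0.4, 0.01), ev("a", "MXE", 0.4, 0.04),
                  ev("b", "RI", -0.3, 0.002), ev("c", "A3SS", 0.2, 0.01),
                  ev("c", "SE", 0.2, 0.99))
  b <- summarize_error_types(events)
  expect_equal(attr(b, "n_significant"), 4)
  expect_equal(b$count[b$error_type == "exon_inclusion"], 2)
  expect_equal(b$percent[b$error_type == "exon_inclusion"], 50)
})

test_that("concordance over shared tested genes matches its definition", {
  a <- data.frame(gene_id = c("a", "b", "c", "d"),
                  exon_class = c("skipped", "included", "unchanged", "unchanged"),
                  intron_class = "untested")
  expect_equal(splice_concordance(a, a)$error_to_error_percent, 100)
  expect_equal(splice_concordance(a, a)$noerror_to_noerror_percent, 100)
  b <- a; b$exon_class <- c("skipped", "unchanged", "unchanged", "MXE")
  cc <- splice_concordance(a, b)
  expect_equal(cc$n_error_concordant, 1)
  expect_equal(cc$error_to_error_percent, 50)
  expect_equal(cc$noerror_to_noerror_percent, 50)
  other <- data.frame(gene_id = "zz", exon_class = "skipped", intron_class = "untested")
  expect_error(splice_concordance(a, other), "shared")
})

test_that("decile report recovers a planted expression-linked skip trend", {
  set.seed(91)
  n <- 600
  fpkm <- data.frame(gene_id = paste0("g", 1:n), fpkm = sort(rlnorm(n, 2, 1)))
  # skip probability rises deterministically with the expression decile
  dec <- quantile_split(fpkm$fpkm, 10)
  skipped <- runif(n) < 0.05 + 0.06 * dec
  classes <- data.frame(gene_id = fpkm$gene_id,
                        exon_class = ifelse(skipped, "skipped", "unchanged"),
                        intron_class = "untested")
  occ <- data.frame(gene_id = fpkm$gene_id,
                    occupancy_class = rep(c("U2AF2_high", "U2AF2_low"), n / 2))
  rep <- decile_report(classes, fpkm, occ, q = 10)
  pooled <- tapply(rep$table$percent_skipped * rep$table$n, rep$table$decile, sum) /
    tapply(rep$table$n, rep$table$decile, sum)
  expect_gt(cor(seq_len(10), pooled, method = "spearman"), 0.9)
  # identical class composition -> rank-sum p near 1 is not guaranteed per
  # decile, but permuting gene order must leave the report unchanged
  o <- sample(n)
  rep2 <- decile_report(classes[o, ], fpkm, occ, q = 10)
  expect_equal(rep$table, rep2$table)
  expect_equal(rep$tests$p_value, rep2$tests$p_value)
})

test_that("decile expression comparisons flag no difference for matched classes", {
  set.seed(93)
  n <- 400
  fpkm <- data.frame(gene_id = paste0("g", 1:n), fpkm = rlnorm(n, 2, 1))
  classes <- data.frame(gene_id = fpkm$gene_id, exon_class = "unchanged",
                        intron_class = "untested")
  occ <- data.frame(gene_id = fpkm$gene_id,
                    occupancy_class = sample(rep(c("U2AF2_high", "U2AF2_low"), n / 2)))
  rep <- decile_report(classes, fpkm, occ, q = 5)
  # expression is independent of the occupancy label: no decile significant
  # at the Bonferroni-corrected 0.01 threshold
  expect_true(all(rep$tests$p_adjusted > 0.01, na.rm = TRUE))
})
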