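test_that("the generators are byte-deterministic under a fixed seed", {
  cfg <- mini_config(seed = 17)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome$seq), as.character(b$genome$seq))
  expect_identical(a$truth, b$truth)
  fa <- simulate_fragments(cfg, a$genes, a$truth, "U2AF2", "control", 1)
  fb <- simulate_fragments(cfg, b$genes, b$truth, "U2AF2", "control", 1)
  expect_identical(fa$fragments, fb$fragments)
  expect_identical(fa$spike_in_count, fb$spike_in_count)
  ea <- simulate_psi_table(cfg, a$truth)
  eb <- simulate_psi_table(cfg, b$truth)
  expect_identical(ea, eb)
  # different seeds diverge
  expect_false(identical(as.character(simulate_genome(mini_config(seed = 18))$genome$seq),
                         as.character(a$genome$seq)))
})

test_that("planted bookkeeping matches the configuration", {
  cfg <- mini_config(seed = 19, n_genes = 50, intronless_fraction = 0.1)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 50)
  expect_equal(sum(sim$truth$intronless), 5)
  expect_true(all(vapply(sim$genes[sim$truth$intronless], n_exons, integer(1)) == 1))
  # gene models are valid and non-overlapping along the chromosome
  spans <- t(vapply(sim$genes, function(g) c(g$span$start, g$span$end), numeric(2)))
  expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  # truth classes only from the configured set; high genes are never intronless
  expect_true(all(sim$truth$class %in% names(cfg$class_props)))
  expect_false(any(sim$truth$intronless & sim$truth$class == "U2AF2_high_active"))
})

test_that("exon GC probability is realized in the simulated sequence", {
  cfg <- mini_config(seed = 23)
  sim <- simulate_genome(cfg)
  ic <- which(!sim$truth$intronless)
  exon_gc <- unlist(lapply(sim$genes[ic[1:20]], function(g)
    vapply(seq_len(n_exons(g)), function(k)
      gc_percent(splicechrom:::feature_of(g, "exon", k), sim$genome), numeric(1))))
  intron_gc <- unlist(lapply(sim$genes[ic[1:20]], function(g)
    vapply(seq_len(n_exons(g) - 1L), function(k)
      gc_percent(splicechrom:::feature_of(g, "intron", k), sim$genome), numeric(1))))
  expect_equal(mean(exon_gc), 55, tolerance = 2 / 55) # 55 +/- ~2
  expect_equal(mean(intron_gc), 40, tolerance = 2 / 40)
})

test_that("fragment generation respects rates, enrichment, and RNase effect", {
  cfg <- mini_config(seed = 29, background_per_kb = 0, dispersion = 0.01)
  sim <- simulate_genome(cfg)
  fs <- pool_fragments(lapply(1:3, function(r)
    simulate_fragments(cfg, sim$genes, sim$truth, "U2AF2", "control", r)))
  # inactive genes receive almost nothing when background is off
  occ <- occupancy_table(fs, sim$genes)
  by_class <- tapply(occ$rpk, sim$truth$class, median)
  expect_gt(by_class[["U2AF2_high_active"]], 5 * by_class[["U2AF2_low_active"]])
  # planted inactive:low rate ratio is 1:5
  expect_lt(by_class[["inactive"]], 0.35 * by_class[["U2AF2_low_active"]])

  # exon:intron per-kb density ratio approaches the enrichment fold
  hi <- which(sim$truth$class == "U2AF2_high_active" & !sim$truth$intronless)
  dens <- do.call(rbind, lapply(sim$genes[hi], function(g) {
    ex <- sum(vapply(seq_len(n_exons(g)), function(k)
      count_fragments_in(fs, splicechrom:::feature_of(g, "exon", k)), integer(1)))
    ix <- sum(vapply(seq_len(n_exons(g) - 1L), function(k)
      count_fragments_in(fs, splicechrom:::feature_of(g, "intron", k)), integer(1)))
    c(ex / sum(g$exon_ends - g$exon_starts),
      ix / (gene_length(g) - sum(g$exon_ends - g$exon_starts)))
  }))
  ratio <- sum(dens[, 1]) / sum(dens[, 2])
  # fragments overlap feature borders, so the realized any-overlap ratio
  # sits below the 3-fold placement enrichment; require a clear enrichment
  expect_gt(ratio, 1.8)

  # RNase condition: sensitive genes drop to ~a quarter of their rate
  sens <- which(sim$truth$rnase_sensitive)
  ctrl <- pool_fragments(lapply(1:3, function(r)
    simulate_fragments(cfg, sim$genes, sim$truth, "U2AF2", "control", r)))
  rna <- pool_fragments(lapply(1:3, function(r)
    simulate_fragments(cfg, sim$genes, sim$truth, "U2AF2", "rnase", r)))
  cs <- sum(occupancy_table(ctrl, sim$genes[sens])$fragment_count)
  rs <- sum(occupancy_table(rna, sim$genes[sens])$fragment_count)
  expect_equal(rs / cs, 0.25, tolerance = 0.35)
  # non-sensitive high genes keep their rates
  keep <- which(sim$truth$class == "U2AF2_high_active" & !sim$truth$rnase_sensitive)
  ck <- sum(occupancy_table(ctrl, sim$genes[keep])$fragment_count)
  rk <- sum(occupancy_table(rna, sim$genes[keep])$fragment_count)
  expect_equal(rk / ck, 1, tolerance = 0.2)
})

test_that("planted PSI events are overwhelmingly significant at depth 200", {
  cfg <- mini_config(seed = 31)
  sim <- simulate_genome(cfg)
  truth <- sim$truth
  truth$exon_class[!truth$intronless] <- "skipped" # plant everywhere for power
  events <- simulate_psi_table(cfg, truth)
  planted <- events[events$event_type == "SE" & events$delta_psi > 0.2, ]
  expect_gt(mean(planted$p_value < 0.05), 0.99)
  expect_true(all(events$delta_psi >= -1 & events$delta_psi <= 1))
})

test_that("null events are calibrated to the nominal significance level", {
  cfg <- simulation_config(seed = 37, n_genes = 760, chrom_length = 9.5e6,
                           n_null_se = 3)
  sim <- simulate_genome(cfg)
  truth <- sim$truth
  truth$exon_class <- "unchanged"; truth$intron_class <- "unchanged"
  events <- simulate_psi_table(cfg, truth)
  nulls <- events[events$event_type == "SE", ]
  expect_gte(nrow(nulls), 2000)
  rate <- mean(nulls$p_value < 0.05)
  tol <- 3.5 * sqrt(0.05 * 0.95 / nrow(nulls))
  expect_lt(abs(rate - 0.05), tol + 0.005) # small allowance for count discreteness
})

test_that("the concordance parameter shapes the second cohort", {
  cfg <- simulation_config(seed = 41, n_genes = 600, chrom_length = 8e6)
  sim <- simulate_genome(cfg)
  t2 <- concordant_truth(cfg, sim$truth)
  err1 <- !sim$truth$exon_class %in% c("unchanged", "untested")
  err2 <- !t2$exon_class %in% c("unchanged", "untested")
  expect_equal(mean(err2[err1]), 0.65, tolerance = 0.12)
  expect_equal(mean(!err2[!err1 & !sim$truth$intronless]), 0.66, tolerance = 0.12)
})

test_that("the fixture bundle is complete and reproducible", {
  cfg <- mini_config(seed = 43)
  d1 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(cfg, d1, force = TRUE)
  need <- c("genome.fa", "genes.bed", "sample_sheet.tsv", "psi_primary.tsv",
            "psi_validation.tsv", "fpkm.tsv", "truth.tsv", "config.yaml",
            "manifest.json")
  expect_true(all(file.exists(file.path(d1, need))))
  truth <- read.delim(file.path(d1, "truth.tsv"))
  expect_equal(nrow(truth), cfg$n_genes)
  # every artifact loads through the corresponding reader
  expect_length(read_annotation(file.path(d1, "genes.bed")), cfg$n_genes)
  expect_s3_class(read_genome(file.path(d1, "genome.fa")), "genome_sequence")
  sheet <- read_sample_sheet(file.path(d1, "sample_sheet.tsv"))
  expect_true(all(file.exists(file.path(d1, sheet$fragments_path))))
  expect_s3_class(read_splice_events(file.path(d1, "psi_primary.tsv")),
                  "splice_events")
  # identical seed -> identical checksums; refusal to clobber without force
  d2 <- withr::local_tempdir()
  m2 <- write_fixture_bundle(cfg, d2, force = TRUE)
  expect_equal(unname(unlist(m1$files)), unname(unlist(m2$files)))
  expect_error(write_fixture_bundle(cfg, d1), "not empty")
})
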