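# Stage orchestration: a YAML run configuration, file-based stages
# (simulate, coverage, occupancy, classify, splice, report), structured log
# lines, and a run manifest with checksums and dropped-gene accounting.

PIPELINE_STAGES <- c("simulate", "coverage", "occupancy", "classify", "splice", "report")

default_params <- function() {
  list(flank = 1000, activity_threshold = 4, k = 3, kmeans_seed = 7,
       alpha = 0.05, lfc_threshold = 1, body_bins = 100, bin_size = 50,
       upstream = 1000, downstream = 1000, quantiles = 10, psi_alpha = 0.05,
       max_ordinal = 10)
}

#' Read and validate a run configuration
#'
#' The configuration is YAML with keys `seed`, `bundle` (fixture/input
#' directory), `outdir`, optional `params` overriding analysis defaults
#' (flank, activity_threshold, k, kmeans_seed, alpha, lfc_threshold,
#' body_bins, bin_size, upstream, downstream, quantiles, psi_alpha,
#' max_ordinal), and optional `simulate` overrides forwarded to
#' [simulation_config()]. Unknown parameter keys and out-of-range values are
#' validation errors.
#'
#' @param path YAML file path, or a list with the same shape.
#' @return A validated run-config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$bundle)) sc_stop("run config: 'bundle' directory is required")
  if (is.null(cfg$outdir)) sc_stop("run config: 'outdir' is required")
  p <- default_params()
  extra <- setdiff(names(cfg$params), names(p))
  if (length(extra)) sc_stop("run config: unknown parameter(s): %s", paste(extra, collapse = ", "))
  p[names(cfg$params)] <- cfg$params
  if (p$activity_threshold < 0 || p$k < 1 || p$alpha <= 0 || p$alpha >= 1 ||
      p$quantiles < 2 || p$flank < 0)
    sc_stop("run config: parameter out of documented range")
  cfg$params <- p
  if (is.null(cfg$simulate)) cfg$simulate <- list()
  cfg
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

append_manifest <- function(outdir, entry) {
  path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::fromJSON(path, simplifyVector = FALSE) else list()
  manifest[[length(manifest) + 1L]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(entry)
}

manifest_entry <- function(outdir, stage, outputs, extra = list()) {
  entry <- c(list(stage = stage, version = as.character(utils::packageVersion("splicechrom")),
                  outputs = as.list(tools::md5sum(file.path(outdir, outputs)))),
             extra)
  names(entry$outputs) <- outputs
  append_manifest(outdir, entry)
}

bundle_inputs <- function(cfg) {
  b <- cfg$bundle
  need <- c("genome.fa", "genes.bed", "sample_sheet.tsv")
  miss <- need[!file.exists(file.path(b, need))]
  if (length(miss))
    sc_stop("bundle '%s' is missing %s; run the simulate stage first (or point 'bundle' at real inputs)",
            b, paste(miss, collapse = ", "))
  invisible(b)
}

read_bundle_sheet <- function(cfg) {
  sheet <- read_sample_sheet(file.path(cfg$bundle, "sample_sheet.tsv"))
  sheet$fragments_path <- file.path(cfg$bundle, sheet$fragments_path)
  bad <- sheet$fragments_path[!file.exists(sheet$fragments_path)]
  if (length(bad)) sc_stop("sample sheet references missing file(s): %s", paste(bad, collapse = ", "))
  sheet
}

load_sample <- function(sheet, i) {
  read_fragments(sheet$fragments_path[i], label = sheet$sample[i],
                 spike_in_count = sheet$spike_in_count[i])
}

pooled_by <- function(sheet, factor, condition) {
  idx <- which(sheet$factor == factor & sheet$condition == condition)
  if (!length(idx)) sc_stop("no samples for %s/%s in the sample sheet", factor, condition)
  pool_fragments(lapply(idx, function(i) load_sample(sheet, i)),
                 label = paste(factor, condition, "pooled", sep = "_"))
}

stage_simulate <- function(cfg) {
  sc <- do.call(simulation_config, c(list(seed = cfg$seed), cfg$simulate))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  man <- write_fixture_bundle(sc, cfg$bundle, force = TRUE)
  log_stage("simulate", "bundle written to %s (%d genes, seed %d)", cfg$bundle,
            sc$n_genes, sc$seed)
  manifest_entry(cfg$outdir, "simulate", character(),
                 list(bundle_hash = man$config_hash))
}

stage_coverage <- function(cfg) {
  bundle_inputs(cfg)
  sheet <- read_bundle_sheet(cfg)
  genome <- read_genome(file.path(cfg$bundle, "genome.fa"))
  dir.create(file.path(cfg$outdir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  outs <- character()
  for (i in seq_len(nrow(sheet))) {
    fs <- load_sample(sheet, i)
    raw <- coverage_from_fragments(fs, genome)
    norm <- normalize_coverage(raw)
    f1 <- file.path("tracks", paste0(sheet$sample[i], ".norm.bedgraph"))
    write_track(norm, file.path(cfg$outdir, f1))
    outs <- c(outs, f1)
    if (fs$spike_in_count > 0) {
      cal <- calibrate_track(raw, spike_scale_factor(fs$spike_in_count))
      f2 <- file.path("tracks", paste0(sheet$sample[i], ".spike.bedgraph"))
      write_track(cal, file.path(cfg$outdir, f2))
      outs <- c(outs, f2)
    }
  }
  # pooled coverage-normalized track of the clustering factor (control)
  pooled <- pooled_by(sheet, "U2AF2", "control")
  ptrack <- normalize_coverage(coverage_from_fragments(pooled, genome))
  fp <- file.path("tracks", "U2AF2_control_pooled.norm.bedgraph")
  write_track(ptrack, file.path(cfg$outdir, fp))
  log_stage("coverage", "%d sample track(s) + pooled track written", nrow(sheet))
  manifest_entry(cfg$outdir, "coverage", c(outs, fp),
                 list(n_samples = nrow(sheet)))
}

stage_occupancy <- function(cfg) {
  bundle_inputs(cfg)
  p <- cfg$params
  sheet <- read_bundle_sheet(cfg)
  genome <- read_genome(file.path(cfg$bundle, "genome.fa"))
  genes <- read_annotation(file.path(cfg$bundle, "genes.bed"))
  ptrack_path <- file.path(cfg$outdir, "tracks", "U2AF2_control_pooled.norm.bedgraph")
  if (!file.exists(ptrack_path))
    sc_stop("missing pooled track; run the coverage stage first")
  ptrack <- read_track(ptrack_path)

  u2 <- pooled_by(sheet, "U2AF2", "control")
  pol <- pooled_by(sheet, "RNAPIIS2P", "control")
  occ_u2 <- occupancy_table(u2, genes, p$flank, genome$lengths)
  occ_pol <- occupancy_table(pol, genes, p$flank, genome$lengths)
  occ <- data.frame(gene_id = occ_u2$gene_id,
                    u2af2_count = occ_u2$fragment_count, u2af2_rpk = occ_u2$rpk,
                    u2af2_density = occ_u2$density,
                    pol_count = occ_pol$fragment_count, pol_rpk = occ_pol$rpk,
                    pol_density = occ_pol$density)
  data.table::fwrite(occ, file.path(cfg$outdir, "occupancy.tsv"), sep = "\t")

  # per-replicate U2AF2 counts for the differential stage
  idx <- which(sheet$factor == "U2AF2")
  cnts <- lapply(idx, function(i) {
    fs <- load_sample(sheet, i)
    data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
               sample = sheet$sample[i], condition = sheet$condition[i],
               count = vapply(genes, function(g)
                 count_fragments_in(fs, flanked_region(g, p$flank, genome$lengths[[g$span$chrom]])),
                 integer(1)))
  })
  data.table::fwrite(data.table::rbindlist(cnts),
                     file.path(cfg$outdir, "u2af2_gene_counts.tsv"), sep = "\t")

  nuc <- tryCatch(pooled_by(sheet, "nucleosome", "control"), error = function(e) NULL)
  feat <- feature_occupancy_table(u2, genes, genome, nuc_frags = nuc,
                                  max_ordinal = p$max_ordinal)
  data.table::fwrite(feat, file.path(cfg$outdir, "features.tsv"), sep = "\t")

  ic <- genes[!vapply(genes, is_intronless, logical(1))]
  mg <- suppressWarnings(metagene_scale_regions(ptrack, ic, p$upstream, p$downstream,
                                                p$body_bins, p$bin_size))
  write_metagene_matrix(mg, file.path(cfg$outdir, "metagene_u2af2.tsv.gz"))
  log_stage("occupancy", "%d genes quantified, %d intron-containing in metagene matrix (%d dropped)",
            length(genes), nrow(mg), length(attr(mg, "dropped")))
  manifest_entry(cfg$outdir, "occupancy",
                 c("occupancy.tsv", "u2af2_gene_counts.tsv", "features.tsv",
                   "metagene_u2af2.tsv.gz"),
                 list(n_genes = length(genes), n_dropped = length(attr(mg, "dropped")),
                      dropped = attr(mg, "dropped")))
}

stage_classify <- function(cfg) {
  p <- cfg$params
  occ_path <- file.path(cfg$outdir, "occupancy.tsv")
  if (!file.exists(occ_path)) sc_stop("missing occupancy outputs; run the occupancy stage first")
  occ <- as.data.frame(data.table::fread(occ_path))
  mg <- read_metagene_matrix(file.path(cfg$outdir, "metagene_u2af2.tsv.gz"))

  activity <- classify_activity(occ$pol_density, p$activity_threshold)
  names(activity) <- occ$gene_id

  # cluster on log-scaled signal: variance stabilization keeps the skewed
  # high-occupancy tier from being split by the squared-error objective
  lmg <- log2(1 + ifelse(is.na(mg), 0, unclass(mg)))
  km <- kmeans_pp(lmg, k = p$k, seed = p$kmeans_seed)
  hl <- assign_high_low(km$cluster, lmg)

  classes <- data.frame(gene_id = occ$gene_id, activity = activity,
                        occupancy_class = NA_character_,
                        stringsAsFactors = FALSE)
  classes$occupancy_class[match(names(hl), classes$gene_id)] <- hl
  classes$gene_class <- ifelse(classes$activity == "inactive", "inactive",
                        ifelse(!is.na(classes$occupancy_class) &
                                 classes$occupancy_class == "U2AF2_high",
                               "U2AF2_high_active", "U2AF2_low_active"))

  # differential enrichment control vs RNase on U2AF2-high genes
  cnts <- as.data.frame(data.table::fread(file.path(cfg$outdir, "u2af2_gene_counts.tsv")))
  high <- classes$gene_id[!is.na(classes$occupancy_class) &
                            classes$occupancy_class == "U2AF2_high"]
  diff <- NULL
  if (length(high) >= 2 && any(cnts$condition == "rnase")) {
    wide <- function(cond) {
      d <- cnts[cnts$condition == cond & cnts$gene_id %in% high, ]
      m <- do.call(cbind, lapply(split(d$count, d$sample), identity))
      rownames(m) <- d$gene_id[d$sample == d$sample[1]]
      m
    }
    diff <- differential_enrichment(wide("control"), wide("rnase"),
                                    p$lfc_threshold, p$alpha)
    data.table::fwrite(diff, file.path(cfg$outdir, "differential.tsv"), sep = "\t")
    classes$rnase_label <- "not_tested"
    classes$rnase_label[match(diff$gene_id, classes$gene_id)] <- diff$label
  } else {
    classes$rnase_label <- "not_tested"
  }

  fpkm_path <- file.path(cfg$bundle, "fpkm.tsv")
  if (file.exists(fpkm_path)) {
    fpkm <- as.data.frame(data.table::fread(fpkm_path))
    m <- match(classes$gene_id, fpkm$gene_id)
    ok <- !is.na(m)
    classes$fpkm_decile <- NA_integer_
    classes$fpkm_decile[ok] <- quantile_split(fpkm$fpkm[m[ok]], p$quantiles)
  }
  data.table::fwrite(classes, file.path(cfg$outdir, "gene_classes.tsv"), sep = "\t")
  log_stage("classify", "%d active / %d inactive; %d U2AF2-high",
            sum(activity == "active"), sum(activity == "inactive"), length(high))
  manifest_entry(cfg$outdir, "classify",
                 c("gene_classes.tsv", if (!is.null(diff)) "differential.tsv"),
                 list(n_active = sum(activity == "active"),
                      n_high = length(high)))
}

stage_splice <- function(cfg) {
  p <- cfg$params
  cls_path <- file.path(cfg$outdir, "gene_classes.tsv")
  if (!file.exists(cls_path)) sc_stop("missing gene classes; run the classify stage first")
  gene_classes <- as.data.frame(data.table::fread(cls_path))
  ev1 <- read_splice_events(file.path(cfg$bundle, "psi_primary.tsv"))
  sp1 <- classify_splice_genes(ev1, p$psi_alpha)
  data.table::fwrite(sp1, file.path(cfg$outdir, "splice_classes_primary.tsv"), sep = "\t")
  outs <- "splice_classes_primary.tsv"
  val_path <- file.path(cfg$bundle, "psi_validation.tsv")
  if (file.exists(val_path)) {
    sp2 <- classify_splice_genes(read_splice_events(val_path), p$psi_alpha)
    data.table::fwrite(sp2, file.path(cfg$outdir, "splice_classes_validation.tsv"), sep = "\t")
    outs <- c(outs, "splice_classes_validation.tsv")
  }
  log_stage("splice", "%d genes classified from primary PSI table", nrow(sp1))
  manifest_entry(cfg$outdir, "splice", outs, list(n_classified = nrow(sp1)))
}

stage_report <- function(cfg) {
  p <- cfg$params
  need <- c("gene_classes.tsv", "splice_classes_primary.tsv")
  miss <- need[!file.exists(file.path(cfg$outdir, need))]
  if (length(miss)) sc_stop("missing %s; run classify and splice stages first",
                            paste(miss, collapse = ", "))
  gene_classes <- as.data.frame(data.table::fread(file.path(cfg$outdir, "gene_classes.tsv")))
  sp1 <- as.data.frame(data.table::fread(file.path(cfg$outdir, "splice_classes_primary.tsv")))
  ev1 <- read_splice_events(file.path(cfg$bundle, "psi_primary.tsv"))

  active <- gene_classes[gene_classes$activity == "active", ]
  sp_active <- sp1[sp1$gene_id %in% active$gene_id, ]
  summ <- summarize_splice_classes(sp_active)
  etypes <- summarize_error_types(ev1[ev1$gene_id %in% active$gene_id, ], p$psi_alpha)

  by_class <- lapply(split(sp_active, gene_classes$gene_class[match(sp_active$gene_id, gene_classes$gene_id)]),
                     function(s) if (nrow(s[s$exon_class != "untested", ])) summarize_splice_classes(s) else NULL)

  conc <- NULL
  val_path <- file.path(cfg$outdir, "splice_classes_validation.tsv")
  if (file.exists(val_path)) {
    sp2 <- as.data.frame(data.table::fread(val_path))
    conc <- splice_concordance(sp_active, sp2[sp2$gene_id %in% active$gene_id, ])
  }

  dec <- NULL
  fpkm_path <- file.path(cfg$bundle, "fpkm.tsv")
  if (file.exists(fpkm_path)) {
    fpkm <- as.data.frame(data.table::fread(fpkm_path))
    occ <- data.frame(gene_id = active$gene_id,
                      occupancy_class = active$occupancy_class)
    occ <- occ[!is.na(occ$occupancy_class), ]
    dec <- suppressMessages(decile_report(sp_active, fpkm, occ, q = p$quantiles))
  }

  report <- list(
    n_genes = nrow(gene_classes),
    class_counts = as.list(table(gene_classes$gene_class)),
    activity_counts = as.list(table(gene_classes$activity)),
    rnase_counts = as.list(table(gene_classes$rnase_label)),
    splice_summary = summ, error_types = etypes, by_class = by_class,
    concordance = conc,
    decile_table = dec$table, decile_tests = dec$tests)
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  flat <- data.frame(metric = c("n_genes", "n_active", "n_u2af2_high",
                                "error_genes", "error_percent"),
                     value = c(nrow(gene_classes),
                               sum(gene_classes$activity == "active"),
                               sum(gene_classes$gene_class == "U2AF2_high_active"),
                               summ$error_genes, summ$error_percent))
  data.table::fwrite(flat, file.path(cfg$outdir, "report.tsv"), sep = "\t")
  log_stage("report", "written report.json / report.tsv (%d error genes of %d tested)",
            summ$error_genes, summ$n_exon_tested)
  manifest_entry(cfg$outdir, "report", c("report.json", "report.tsv"), list())
  invisible(report)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write the synthetic bundle), `coverage` (normalized
#' and spike-calibrated tracks), `occupancy` (gene/feature occupancy tables
#' and the gene-body metagene matrix), `classify` (activity, k-means
#' high/low, RNase differential, expression deciles), `splice` (PSI-based
#' gene classes), `report` (consolidated JSON/TSV). Each stage validates its
#' upstream inputs and appends a manifest entry with output checksums.
#'
#' @param stage Stage name.
#' @param config Run config list or YAML path (see [read_run_config()]).
#' @return The manifest entry (or, for `report`, the report list),
#'   invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  cfg <- read_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = stage_simulate(cfg),
         coverage = stage_coverage(cfg),
         occupancy = stage_occupancy(cfg),
         classify = stage_classify(cfg),
         splice = stage_splice(cfg),
         report = stage_report(cfg))
}

#' Run the full pipeline
#'
#' Runs every stage in order (optionally skipping `simulate` when the bundle
#' already exists and `resimulate = FALSE`).
#'
#' @param config Run config list or YAML path.
#' @param resimulate Regenerate the bundle even if present (default TRUE
#'   when the bundle directory is missing).
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config, resimulate = NULL) {
  cfg <- read_run_config(config)
  if (is.null(resimulate)) resimulate <- !file.exists(file.path(cfg$bundle, "genome.fa"))
  stages <- if (resimulate) PIPELINE_STAGES else setdiff(PIPELINE_STAGES, "simulate")
  out <- NULL
  for (s in stages) out <- run_stage(s, cfg)
  invisible(out)
}
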