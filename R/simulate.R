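# Synthetic-data generator with planted structure: genomes with exon/intron
# GC contrast, gene models with ~145-bp exons, factor fragments proportional
# to planted occupancy classes with exon enrichment, spike-ins, replicate
# noise, and PSI tables with planted significant events per gene class.
#
# All defaults are fixed study conditions (see the methods vignette); a fixed
# seed makes every generator byte-deterministic.

#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator. Defaults
#' define the standard synthetic bundle: one 5-Mb chromosome carrying 400
#' genes with occupancy-class proportions 0.15 / 0.35 / 0.50
#' (U2AF2-high active / U2AF2-low active / inactive), a 6% intronless
#' fraction, ~145-bp exons, longer log-normal introns, exon GC 0.55 vs
#' intron GC 0.40, U2AF2 fragments enriched 3-fold on exons,
#' negative-binomial replicate noise with dispersion 0.1, an RNase condition
#' that multiplies the U2AF2 rate by 0.25 on the planted sensitive genes,
#' and PSI events simulated at read depth 200 with |delta PSI| 0.4.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param ... Overrides for any default listed in the function body.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = 400,
    chrom_name = "chrS",
    chrom_length = 5e6,
    class_props = c(U2AF2_high_active = 0.15, U2AF2_low_active = 0.35,
                    inactive = 0.50),
    intronless_fraction = 0.06,
    # gene structure
    exon_length_mean = 145, exon_length_sd = 20, exon_length_min = 50,
    exon_count_lambda = c(U2AF2_high_active = 9, U2AF2_low_active = 6,
                          inactive = 6),
    exon_count_min = 2,
    intron_meanlog = c(U2AF2_high_active = log(500), U2AF2_low_active = log(800),
                       inactive = log(800)),
    intron_sdlog = 0.5,
    intronless_length_mean = 1000, intronless_length_sd = 200,
    gap_min = 2500, edge_margin = 5000,
    # sequence composition
    gc_exon = 0.55, gc_intron = 0.40, gc_intergenic = 0.40,
    # fragment generation
    replicates = 3,
    dispersion = 0.1,
    flank = 1000,
    rates = list(
      U2AF2 = c(U2AF2_high_active = 40, U2AF2_low_active = 5, inactive = 1),
      RNAPIIS2P = c(U2AF2_high_active = 70, U2AF2_low_active = 50, inactive = 0.3),
      nucleosome = c(U2AF2_high_active = 30, U2AF2_low_active = 30, inactive = 30)),
    exon_enrichment = c(U2AF2 = 3, RNAPIIS2P = 1, nucleosome = 2),
    frag_nuc_prob = c(U2AF2 = 0.6, RNAPIIS2P = 0.6, nucleosome = 0.85),
    frag_nuc_mean = 170, frag_sub_mean = 100, frag_len_sd = 15, frag_len_min = 40,
    background_per_kb = 0.2,
    spike_in_mean = 2000,
    # RNase condition
    rnase_fraction = 0.03, rnase_effect = 0.25,
    # expression
    fpkm_meanlog = c(U2AF2_high_active = log(20), U2AF2_low_active = log(15),
                     inactive = log(0.5)),
    fpkm_sdlog = 1,
    # planted splicing errors
    planted_probs = list(
      U2AF2_high_active = c(skipped = 0.37, included = 0.10, MXE = 0.07),
      U2AF2_low_active = c(skipped = 0.20, included = 0.06, MXE = 0.04),
      inactive = c(skipped = 0.05, included = 0.02, MXE = 0.02)),
    intron_retained_prob = c(U2AF2_high_active = 0.15, U2AF2_low_active = 0.08,
                             inactive = 0.03),
    intron_removed_prob = 0.03,
    expression_skip_coupling = TRUE,
    psi_depth = 200, delta_psi = 0.4,
    null_psi_range = c(0.3, 0.9),
    n_null_se = 2, p_ri = 0.6, p_ss = 0.3,
    psi_alpha = 0.05,
    concordance_error = 0.65, concordance_noerror = 0.66)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) sc_stop("unknown simulation option(s): %s", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (abs(sum(cfg$class_props) - 1) > 1e-8) sc_stop("class proportions must sum to 1")
  if (any(unlist(cfg$rates) < 0)) sc_stop("fragment rates must be non-negative")
  structure(cfg, class = "simulation_config")
}

truncated_norm <- function(n, mean, sd, min) {
  x <- round(stats::rnorm(n, mean, sd))
  pmax(x, min)
}

#' Simulate a genome with planted gene classes
#'
#' Places non-overlapping genes along one synthetic chromosome, draws the
#' sequence with feature-specific GC probability (exons above introns and
#' intergenic background), and records every gene's planted occupancy class,
#' expression, RNase sensitivity, and splice-error class in a truth table.
#'
#' @param config A `simulation_config`.
#' @return A list: `genome` (`genome_sequence`), `genes` (list of
#'   `gene_model`), `truth` (data.frame with columns `gene_id`, `class`,
#'   `intronless`, `rnase_sensitive`, `fpkm`, `exon_class`, `intron_class`,
#'   `n_exons`, `length`).
#' @export
simulate_genome <- function(config) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, "genome"), {
    n <- cfg$n_genes
    n_il <- round(cfg$intronless_fraction * n)
    n_ic <- n - n_il
    # deterministic planted counts so proportions are exact study conditions
    cnt <- round(cfg$class_props * n_ic)
    cnt[length(cnt)] <- n_ic - sum(cnt[-length(cnt)])
    class_ic <- rep(names(cnt), cnt)
    class_il <- rep(c("U2AF2_low_active", "inactive"), length.out = n_il)
    ord <- sample(n)
    cls <- c(class_ic, class_il)[ord]
    intronless <- c(rep(FALSE, n_ic), rep(TRUE, n_il))[ord]

    # draw gene structures first, then lay them out with a guaranteed
    # minimum intergenic gap (remaining free space spread with random
    # exponential weights) so counting flanks of neighbouring genes do not
    # touch and placement always fits or fails deterministically
    structs <- vector("list", n)
    for (i in seq_len(n)) {
      if (intronless[i]) {
        len <- truncated_norm(1, cfg$intronless_length_mean, cfg$intronless_length_sd, 200)
        structs[[i]] <- list(es = 0, ee = len)
      } else {
        ne <- max(cfg$exon_count_min, stats::rpois(1, cfg$exon_count_lambda[[cls[i]]]))
        elens <- truncated_norm(ne, cfg$exon_length_mean, cfg$exon_length_sd,
                                cfg$exon_length_min)
        ilens <- pmax(80, round(stats::rlnorm(ne - 1, cfg$intron_meanlog[[cls[i]]],
                                              cfg$intron_sdlog)))
        es <- cumsum(c(0, elens[-ne] + ilens))
        structs[[i]] <- list(es = es, ee = es + elens)
      }
    }
    total_len <- sum(vapply(structs, function(s) s$ee[length(s$ee)], numeric(1)))
    free <- cfg$chrom_length - 2 * cfg$edge_margin - total_len - n * cfg$gap_min
    if (free < 0)
      sc_stop("genes do not fit in the %d-bp chromosome at %d-bp minimum gaps; increase chrom_length",
              cfg$chrom_length, cfg$gap_min)
    w <- stats::rexp(n)
    gaps <- cfg$gap_min + floor(free * w / sum(w))
    genes <- vector("list", n)
    truth <- vector("list", n)
    pos <- cfg$edge_margin
    for (i in seq_len(n)) {
      id <- sprintf("g%03d", i)
      es <- pos + structs[[i]]$es; ee <- pos + structs[[i]]$ee
      strand <- sample(c("+", "-"), 1)
      genes[[i]] <- gene_model(id, cfg$chrom_name, es[1], ee[length(ee)], strand, es, ee)
      truth[[i]] <- data.frame(gene_id = id, class = cls[i],
                               intronless = intronless[i], stringsAsFactors = FALSE)
      pos <- ee[length(ee)] + gaps[i]
    }
    truth <- do.call(rbind, truth)
    truth$length <- vapply(genes, gene_length, numeric(1))
    truth$n_exons <- vapply(genes, n_exons, integer(1))

    # sequence: per-base GC probability by feature
    gp <- rep(cfg$gc_intergenic, cfg$chrom_length)
    for (g in genes) {
      gp[(g$span$start + 1):g$span$end] <- cfg$gc_intron
      for (k in seq_len(n_exons(g)))
        gp[(g$exon_starts[k] + 1):g$exon_ends[k]] <- cfg$gc_exon
    }
    is_gc <- stats::runif(cfg$chrom_length) < gp
    half <- stats::runif(cfg$chrom_length) < 0.5
    base <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    genome <- genome_sequence(stats::setNames(paste(base, collapse = ""), cfg$chrom_name))

    # planted RNase sensitivity among U2AF2-high genes
    truth$rnase_sensitive <- FALSE
    hi <- which(truth$class == "U2AF2_high_active")
    ns <- max(1L, round(cfg$rnase_fraction * length(hi)))
    truth$rnase_sensitive[sample(hi, ns)] <- TRUE

    # expression
    truth$fpkm <- stats::rlnorm(n, cfg$fpkm_meanlog[truth$class], cfg$fpkm_sdlog)

    # planted splice classes (intron-containing genes only); skip probability
    # optionally rises with expression within the cohort
    truth$exon_class <- "untested"; truth$intron_class <- "untested"
    ic <- !truth$intronless
    u <- rank(truth$fpkm[ic]) / sum(ic)
    mult <- if (isTRUE(cfg$expression_skip_coupling)) 0.4 + 1.2 * u else rep(1, sum(ic))
    pcl <- t(vapply(truth$class[ic], function(cl) cfg$planted_probs[[cl]], numeric(3)))
    pskip <- pmin(0.9, pcl[, 1] * mult)
    draw <- stats::runif(sum(ic))
    ec <- rep("unchanged", sum(ic))
    ec[draw < pskip] <- "skipped"
    ec[draw >= pskip & draw < pskip + pcl[, 2]] <- "included"
    ec[draw >= pskip + pcl[, 2] & draw < pskip + pcl[, 2] + pcl[, 3]] <- "MXE"
    truth$exon_class[ic] <- ec
    pret <- cfg$intron_retained_prob[truth$class[ic]]
    drw <- stats::runif(sum(ic))
    icl <- rep("unchanged", sum(ic))
    icl[drw < pret] <- "retained"
    icl[drw >= pret & drw < pret + cfg$intron_removed_prob] <- "removed"
    truth$intron_class[ic] <- icl
    rownames(truth) <- NULL
    list(genome = genome, genes = genes, truth = truth)
  })
}

sample_fragment_positions <- function(n, g, flank, fold, chrom_len) {
  # segment sampling: exon bases weighted `fold`, the rest of the flanked
  # region weight 1; fragment centers uniform within the chosen segment
  s0 <- max(0, g$span$start - flank); e0 <- min(chrom_len, g$span$end + flank)
  bnd <- sort(unique(c(s0, e0, g$exon_starts, g$exon_ends)))
  seg_s <- bnd[-length(bnd)]; seg_e <- bnd[-1L]
  in_exon <- vapply(seq_along(seg_s), function(j)
    any(g$exon_starts <= seg_s[j] & g$exon_ends >= seg_e[j]), logical(1))
  w <- (seg_e - seg_s) * ifelse(in_exon, fold, 1)
  seg <- sample.int(length(seg_s), n, replace = TRUE, prob = w)
  floor(stats::runif(n, seg_s[seg], seg_e[seg]))
}

#' Simulate a replicate fragment set for one factor and condition
#'
#' Per-gene fragment counts are negative-binomial with class-dependent mean
#' (`rate` per kb of gene length); fragment centers fall in the flanked gene
#' with exon positions oversampled by the factor's enrichment fold; fragment
#' lengths come from a nucleosomal/subnucleosomal mixture; background
#' fragments are scattered genome-wide; the RNase condition multiplies the
#' rate of planted sensitive genes by `rnase_effect`; a spike-in count is
#' attached.
#'
#' @param config A `simulation_config`.
#' @param genes Gene models from [simulate_genome()].
#' @param truth Truth table from [simulate_genome()].
#' @param factor One of `"U2AF2"`, `"RNAPIIS2P"`, `"nucleosome"`.
#' @param condition `"control"` or `"rnase"`.
#' @param replicate Replicate index (1-based).
#' @return A `fragment_set`.
#' @export
simulate_fragments <- function(config, genes, truth,
                               factor = c("U2AF2", "RNAPIIS2P", "nucleosome"),
                               condition = c("control", "rnase"), replicate = 1) {
  factor <- match.arg(factor); condition <- match.arg(condition)
  cfg <- config
  with_seed(derive_seed(cfg$seed, paste(factor, condition, replicate)), {
    rates <- cfg$rates[[factor]]
    fold <- cfg$exon_enrichment[[factor]]
    chrom_len <- cfg$chrom_length
    out <- vector("list", length(genes) + 1L)
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      mu <- rates[[truth$class[i]]] * gene_length(g) / 1000
      if (condition == "rnase" && factor == "U2AF2" && truth$rnase_sensitive[i])
        mu <- mu * cfg$rnase_effect
      cnt <- if (mu > 0) stats::rnbinom(1, mu = mu, size = 1 / cfg$dispersion) else 0L
      if (cnt == 0) next
      ctr <- sample_fragment_positions(cnt, g, cfg$flank, fold, chrom_len)
      nuc <- stats::runif(cnt) < cfg$frag_nuc_prob[[factor]]
      len <- truncated_norm(cnt, ifelse(nuc, cfg$frag_nuc_mean, cfg$frag_sub_mean),
                            cfg$frag_len_sd, cfg$frag_len_min)
      st <- pmax(0, ctr - len %/% 2)
      en <- pmin(chrom_len, st + len)
      out[[i]] <- data.table::data.table(chrom = g$span$chrom, start = st, end = en)
    }
    nbg <- stats::rpois(1, cfg$background_per_kb * chrom_len / 1000)
    if (nbg > 0) {
      ctr <- floor(stats::runif(nbg, 0, chrom_len))
      nuc <- stats::runif(nbg) < cfg$frag_nuc_prob[[factor]]
      len <- truncated_norm(nbg, ifelse(nuc, cfg$frag_nuc_mean, cfg$frag_sub_mean),
                            cfg$frag_len_sd, cfg$frag_len_min)
      st <- pmax(0, ctr - len %/% 2)
      out[[length(genes) + 1L]] <- data.table::data.table(
        chrom = cfg$chrom_name, start = st, end = pmin(chrom_len, st + len))
    }
    frag <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
    data.table::setorder(frag, chrom, start, end)
    fragment_set(frag,
                 label = sprintf("%s_%s_rep%d", factor, condition, replicate),
                 spike_in_count = stats::rpois(1, cfg$spike_in_mean))
  })
}

two_prop_p <- function(x1, x2, d) {
  # two-proportion z-test (unpooled counts pooled variance), no continuity
  # correction; degenerate identical extremes give p = 1
  p1 <- x1 / d; p2 <- x2 / d
  pp <- (x1 + x2) / (2 * d)
  se <- sqrt(pp * (1 - pp) * 2 / d)
  p <- ifelse(se == 0, 1, 2 * stats::pnorm(-abs(p1 - p2) / se))
  pmin(1, p)
}

#' Simulate an rMATS-style PSI event table from a truth table
#'
#' Every planted event draws inclusion counts binomially in WT and KD at the
#' configured depth and delta-PSI; the p-value comes from an explicit
#' two-proportion z-test on those counts, so significance is internally
#' consistent. Null genes receive events with delta-PSI 0 and calibrated
#' null p-values. Recorded delta-PSI is the empirical WT-minus-KD estimate.
#'
#' @param config A `simulation_config`.
#' @param truth Truth table (from [simulate_genome()] or
#'   [concordant_truth()]).
#' @param label Stream label so different cell lines get independent draws.
#' @return A `splice_events` data.frame.
#' @export
simulate_psi_table <- function(config, truth, label = "K562") {
  cfg <- config
  with_seed(derive_seed(cfg$seed, paste("psi", label)), {
    d <- cfg$psi_depth
    rows <- list()
    add <- function(gene_id, type, psi_wt, psi_kd) {
      x1 <- stats::rbinom(1, d, psi_wt); x2 <- stats::rbinom(1, d, psi_kd)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene_id, event_type = type,
        delta_psi = (x1 - x2) / d, p_value = two_prop_p(x1, x2, d),
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(truth))) {
      if (truth$intronless[i]) next
      id <- truth$gene_id[i]
      base <- stats::runif(1, 0.3, 0.55)
      ec <- truth$exon_class[i]
      if (ec == "skipped") add(id, "SE", base + cfg$delta_psi, base)
      if (ec == "included") add(id, "SE", base, base + cfg$delta_psi)
      if (ec == "MXE") {
        if (stats::runif(1) < 0.5) add(id, "MXE", base + cfg$delta_psi, base)
        else add(id, "MXE", base, base + cfg$delta_psi)
      }
      for (k in seq_len(cfg$n_null_se)) {
        p0 <- stats::runif(1, cfg$null_psi_range[1], cfg$null_psi_range[2])
        add(id, "SE", p0, p0)
      }
      icl <- truth$intron_class[i]
      bi <- stats::runif(1, 0.1, 0.4)
      if (icl == "retained") add(id, "RI", bi, bi + cfg$delta_psi)
      else if (icl == "removed") add(id, "RI", bi + cfg$delta_psi, bi)
      else if (stats::runif(1) < cfg$p_ri) add(id, "RI", bi, bi)
      for (type in c("A5SS", "A3SS")) if (stats::runif(1) < cfg$p_ss) {
        p0 <- stats::runif(1, cfg$null_psi_range[1], cfg$null_psi_range[2])
        add(id, type, p0, p0)
      }
    }
    splice_events(do.call(rbind, rows))
  })
}

#' Derive a concordant second-cell-line truth table
#'
#' Planted error status in the derived table agrees with the source truth at
#' the configured rates: an error gene stays an error gene with probability
#' `concordance_error` (keeping its class); a no-error gene stays unchanged
#' with probability `concordance_noerror`, otherwise it gains an error class
#' drawn from its occupancy class's planted probabilities.
#'
#' @param config A `simulation_config`.
#' @param truth Source truth table.
#' @param label Stream label (default `"HepG2"`).
#' @return A truth table of the same shape.
#' @export
concordant_truth <- function(config, truth, label = "HepG2") {
  cfg <- config
  with_seed(derive_seed(cfg$seed, paste("concordance", label)), {
    t2 <- truth
    for (i in seq_len(nrow(t2))) {
      if (t2$intronless[i]) next
      err <- !truth$exon_class[i] %in% c("unchanged", "untested")
      if (err) {
        if (stats::runif(1) > cfg$concordance_error) t2$exon_class[i] <- "unchanged"
      } else if (stats::runif(1) > cfg$concordance_noerror) {
        pr <- cfg$planted_probs[[truth$class[i]]]
        t2$exon_class[i] <- sample(names(pr), 1, prob = pr)
      }
    }
    t2
  })
}

#' Write the full synthetic fixture bundle
#'
#' Writes everything the pipeline consumes: genome FASTA, BED12 annotation,
#' per-replicate fragment BED files for U2AF2 (control and RNase),
#' RNAPIIS2P and nucleosome fragments, a sample sheet with spike-in counts,
#' two PSI event tables (primary cohort plus a concordant validation
#' cohort), an FPKM table, the truth table, the configuration, and a
#' manifest with file checksums. Re-running with the same seed reproduces
#' identical bytes.
#'
#' @param config A `simulation_config`.
#' @param outdir Output directory.
#' @param force Overwrite a non-empty directory (default FALSE: error).
#' @return Invisibly, the manifest list.
#' @export
write_fixture_bundle <- function(config, outdir, force = FALSE) {
  cfg <- config
  if (dir.exists(outdir) && length(list.files(outdir)) && !force)
    sc_stop("output directory '%s' is not empty (use force = TRUE)", outdir)
  dir.create(file.path(outdir, "fragments"), recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(cfg)
  write_genome(sim$genome, file.path(outdir, "genome.fa"))
  write_annotation(sim$genes, file.path(outdir, "genes.bed"))
  sheet <- list()
  specs <- rbind(
    expand.grid(factor = c("U2AF2"), condition = c("control", "rnase"),
                replicate = seq_len(cfg$replicates), stringsAsFactors = FALSE),
    expand.grid(factor = "RNAPIIS2P", condition = "control",
                replicate = seq_len(cfg$replicates), stringsAsFactors = FALSE),
    expand.grid(factor = "nucleosome", condition = "control", replicate = 1L,
                stringsAsFactors = FALSE))
  for (i in seq_len(nrow(specs))) {
    fs <- simulate_fragments(cfg, sim$genes, sim$truth, specs$factor[i],
                             specs$condition[i], specs$replicate[i])
    rel <- file.path("fragments", paste0(fs$label, ".bed"))
    write_fragments(fs, file.path(outdir, rel))
    sheet[[i]] <- data.frame(sample = fs$label, fragments_path = rel,
                             spike_in_count = fs$spike_in_count,
                             factor = specs$factor[i], condition = specs$condition[i],
                             replicate = specs$replicate[i], stringsAsFactors = FALSE)
  }
  data.table::fwrite(data.table::rbindlist(sheet),
                     file.path(outdir, "sample_sheet.tsv"), sep = "\t")
  ev1 <- simulate_psi_table(cfg, sim$truth, "K562")
  truth2 <- concordant_truth(cfg, sim$truth, "HepG2")
  ev2 <- simulate_psi_table(cfg, truth2, "HepG2")
  data.table::fwrite(ev1, file.path(outdir, "psi_primary.tsv"), sep = "\t")
  data.table::fwrite(ev2, file.path(outdir, "psi_validation.tsv"), sep = "\t")
  data.table::fwrite(sim$truth[, c("gene_id", "fpkm")],
                     file.path(outdir, "fpkm.tsv"), sep = "\t")
  data.table::fwrite(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t")
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(config_hash = hash_object(unclass(cfg)),
                   n_genes = cfg$n_genes, seed = cfg$seed,
                   files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
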