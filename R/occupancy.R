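# Per-gene and per-feature occupancy quantification: fragment counting, RPK
# and density, nucleosome occupancy, eCLIP fold change, expression score.

#' Count fragments overlapping a region
#'
#' Any-overlap rule: a fragment counts if it overlaps the region by at least
#' one base (bedtools intersect -c semantics); half-open abutment does not
#' count.
#'
#' @param frags A `fragment_set`.
#' @param region A `genomic_interval`.
#' @return Integer fragment count.
#' @export
count_fragments_in <- function(frags, region) {
  ir <- frags$by_chrom[[region$chrom]]
  if (is.null(ir)) return(0L)
  sum(IRanges::countOverlaps(
    IRanges::IRanges(region$start + 1L, region$end), ir))
}

#' Per-gene occupancy record (RPK and density)
#'
#' Fragments are counted over the gene extended by `flank` bp on each side,
#' but RPK divides by the gene length alone: RPK = count / (gene length in
#' kb); density = log2(1 + RPK).
#'
#' @param frags A `fragment_set`.
#' @param gene A `gene_model`.
#' @param flank Flank in bp added to the counting region (default 1000).
#' @param chrom_length Optional chromosome length for clipping the flank.
#' @return A one-row data.frame: `gene_id`, `fragment_count`, `rpk`,
#'   `density`.
#' @export
gene_rpk <- function(frags, gene, flank = 1000, chrom_length = NULL) {
  len <- gene_length(gene)
  if (len <= 0) sc_stop("gene '%s' has zero length", gene$gene_id)
  cnt <- count_fragments_in(frags, flanked_region(gene, flank, chrom_length))
  rpk <- cnt / (len / 1000)
  data.frame(gene_id = gene$gene_id, fragment_count = cnt, rpk = rpk,
             density = log2(1 + rpk), stringsAsFactors = FALSE)
}

#' Occupancy table over many genes
#'
#' Vectorized [gene_rpk()] over a gene list.
#'
#' @param frags A `fragment_set`.
#' @param genes List of `gene_model`.
#' @param flank Flank in bp (default 1000).
#' @param chrom_lengths Optional named chromosome lengths for clipping.
#' @return A data.frame with one row per gene.
#' @export
occupancy_table <- function(frags, genes, flank = 1000, chrom_lengths = NULL) {
  rows <- lapply(genes, function(g)
    gene_rpk(frags, g, flank,
             if (is.null(chrom_lengths)) NULL else chrom_lengths[[g$span$chrom]]))
  do.call(rbind, rows)
}

#' Per-feature RPK (exon or intron)
#'
#' Any-overlap fragment count over the feature divided by the feature length
#' in kilobases. Sub-gene features take no flank. Ordinals are 1-based in
#' transcription direction.
#'
#' @param frags A `fragment_set`.
#' @param gene A `gene_model`.
#' @param which `"exon"` or `"intron"`.
#' @param ordinal 1-based feature ordinal (5' to 3').
#' @return Numeric RPK.
#' @export
feature_rpk <- function(frags, gene, which = c("exon", "intron"), ordinal) {
  feat <- feature_of(gene, which, ordinal)
  count_fragments_in(frags, feat) / (interval_length(feat) / 1000)
}

#' Nucleosome occupancy of a region
#'
#' Counts fragments of nucleosomal size (length >= `min_length`, default
#' 150 bp) overlapping the region, divided either by the region length in kb
#' (`per = "kb"`) or by the region's GC base count in thousands
#' (`per = "kGC"`).
#'
#' @param frags A `fragment_set` (e.g. MNase-seq fragments).
#' @param region A `genomic_interval`.
#' @param genome A `genome_sequence` (required for `per = "kGC"`).
#' @param per `"kb"` or `"kGC"`.
#' @param min_length Minimum fragment length retained (default 150).
#' @return Numeric occupancy.
#' @export
nucleosome_occupancy <- function(frags, region, genome = NULL,
                                 per = c("kb", "kGC"), min_length = 150) {
  per <- match.arg(per)
  ir <- frags$by_chrom[[region$chrom]]
  cnt <- if (is.null(ir)) 0L else {
    keep <- ir[IRanges::width(ir) >= min_length]
    sum(IRanges::countOverlaps(IRanges::IRanges(region$start + 1L, region$end), keep))
  }
  if (per == "kb") return(cnt / (interval_length(region) / 1000))
  if (is.null(genome)) sc_stop("per='kGC' requires a genome sequence")
  gc <- gc_bases(region, genome)
  if (gc == 0) sc_stop("per='kGC' undefined: region has zero GC bases")
  cnt / (gc / 1000)
}

#' eCLIP IP/input fold change
#'
#' @param ip_count IP fragment count on a feature.
#' @param input_count Size-matched input fragment count (> 0).
#' @return `ip_count / input_count`.
#' @export
eclip_fold_change <- function(ip_count, input_count) {
  if (any(input_count <= 0)) sc_stop("eCLIP fold change undefined: input count must be > 0")
  ip_count / input_count
}

#' Expression score from FPKM
#'
#' `log2(1 + FPKM)`.
#'
#' @param fpkm Non-negative FPKM value(s).
#' @return Numeric expression score(s).
#' @export
log_expression <- function(fpkm) {
  if (any(fpkm < 0)) sc_stop("FPKM must be non-negative")
  log2(1 + fpkm)
}

#' Exon/intron feature occupancy table
#'
#' Per-feature metrics for the first `max_ordinal` exons and introns of each
#' gene (ordinals in transcription direction): factor RPK, GC percent, and
#' nucleosome occupancy per kb and per kGC from a nucleosome fragment set.
#'
#' @param frags A `fragment_set` of the profiled factor.
#' @param genes List of `gene_model`.
#' @param genome A `genome_sequence`.
#' @param nuc_frags Optional `fragment_set` of nucleosome (MNase) fragments.
#' @param max_ordinal Number of leading exons/introns to report (default 10).
#' @return A data.frame: `gene_id`, `feature` (exon/intron), `ordinal`,
#'   `length`, `rpk`, `gc_percent`, `nuc_per_kb`, `nuc_per_kgc`.
#' @export
feature_occupancy_table <- function(frags, genes, genome, nuc_frags = NULL,
                                    max_ordinal = 10) {
  rows <- list()
  for (g in genes) {
    for (kind in c("exon", "intron")) {
      nfeat <- if (kind == "exon") n_exons(g) else n_exons(g) - 1L
      for (k in seq_len(min(nfeat, max_ordinal))) {
        feat <- feature_of(g, kind, k)
        gcb <- gc_bases(feat, genome)
        nkb <- nkgc <- NA_real_
        if (!is.null(nuc_frags)) {
          nkb <- nucleosome_occupancy(nuc_frags, feat, per = "kb")
          nkgc <- if (gcb > 0) nucleosome_occupancy(nuc_frags, feat, genome, per = "kGC") else NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, feature = kind, ordinal = k,
          length = interval_length(feat),
          rpk = count_fragments_in(frags, feat) / (interval_length(feat) / 1000),
          gc_percent = gcb / interval_length(feat) * 100,
          nuc_per_kb = nkb, nuc_per_kgc = nkgc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
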