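# Gene annotation data model and interval arithmetic.
#
# Coordinates are 0-based half-open throughout ([start, end)), the native BED
# convention. GTF input is converted on read (1-based starts shifted down).

#' Create a genomic interval
#'
#' A genomic interval is a 0-based half-open span on a named chromosome with
#' an optional strand.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based start coordinate.
#' @param end End coordinate (exclusive); must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 100, 200, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    sc_stop("interval chromosome must be a non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    sc_stop("invalid interval [%s, %s): need 0 <= start < end", start, end)
  if (!strand %in% c("+", "-", "*"))
    sc_stop("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$chrom, x$start, x$end, x$strand))
  invisible(x)
}

interval_length <- function(x) x$end - x$start

#' Create a gene model
#'
#' A gene model is a gene span plus its ordered exon blocks (genomic
#' coordinates, sorted by start). Introns are the gaps between consecutive
#' exons; a single-exon gene is intronless. One transcript model per gene.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param start,end Gene span, 0-based half-open.
#' @param strand `"+"` or `"-"` (defines the transcription direction used for
#'   TSS/TES anchors and exon/intron ordinals).
#' @param exon_starts,exon_ends Integer vectors of exon block coordinates,
#'   sorted, disjoint, contained in the span; first exon must start at `start`
#'   and last exon must end at `end`.
#' @param category Optional free-text label (e.g. `"splicing_factor"`).
#' @return An object of class `gene_model`.
#' @examples
#' g <- gene_model("g1", "chr1", 0, 300, "+", c(0, 200), c(100, 300))
#' introns_of(g)
#' @export
gene_model <- function(gene_id, chrom, start, end, strand = "+",
                       exon_starts, exon_ends, category = NA_character_) {
  span <- genomic_interval(chrom, start, end,
                           if (strand %in% c("+", "-")) strand else "*")
  exon_starts <- as.numeric(exon_starts); exon_ends <- as.numeric(exon_ends)
  n <- length(exon_starts)
  if (n == 0L || length(exon_ends) != n)
    sc_stop("gene '%s': exon start/end vectors must be non-empty and equal length", gene_id)
  if (any(exon_ends <= exon_starts))
    sc_stop("gene '%s': exon with non-positive length", gene_id)
  if (is.unsorted(exon_starts, strictly = TRUE))
    sc_stop("gene '%s': exon blocks not sorted by start", gene_id)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n]))
    sc_stop("gene '%s': overlapping exon blocks", gene_id)
  if (exon_starts[1L] < start || exon_ends[n] > end)
    sc_stop("gene '%s': exon blocks outside gene span", gene_id)
  structure(list(gene_id = as.character(gene_id), span = span,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 category = category),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s) %d exon(s)\n", x$gene_id,
              x$span$chrom, x$span$start, x$span$end, x$span$strand,
              n_exons(x)))
  invisible(x)
}

#' Number of exons of a gene model
#' @param gene A `gene_model`.
#' @return Integer exon count.
#' @export
n_exons <- function(gene) length(gene$exon_starts)

#' Gene span length in base pairs
#' @param gene A `gene_model`.
#' @return Numeric length.
#' @export
gene_length <- function(gene) interval_length(gene$span)

#' Is a gene intronless?
#' @param gene A `gene_model`.
#' @return `TRUE` when the model has a single exon.
#' @export
is_intronless <- function(gene) n_exons(gene) == 1L

#' Transcription start / end site of a gene
#'
#' The TSS is the span start on the plus strand and the span end on the minus
#' strand; the TES is symmetric. Coordinates are 0-based positions.
#'
#' @param gene A `gene_model`.
#' @return Numeric coordinate.
#' @export
tss <- function(gene) if (gene$span$strand == "-") gene$span$end else gene$span$start

#' @rdname tss
#' @export
tes <- function(gene) if (gene$span$strand == "-") gene$span$start else gene$span$end

#' Introns of a gene model
#'
#' Introns are the gaps between consecutive exons, inheriting the gene's
#' strand; an intronless gene yields an empty list. The union of exons and
#' introns tiles the span exactly.
#'
#' @param gene A `gene_model`.
#' @return List of `genomic_interval`, in genomic order.
#' @export
introns_of <- function(gene) {
  n <- n_exons(gene)
  if (n < 2L) return(list())
  lapply(seq_len(n - 1L), function(i) {
    genomic_interval(gene$span$chrom, gene$exon_ends[i], gene$exon_starts[i + 1L],
                     gene$span$strand)
  })
}

#' Exons of a gene model as intervals
#' @param gene A `gene_model`.
#' @return List of `genomic_interval` in genomic order.
#' @export
exons_of <- function(gene) {
  lapply(seq_len(n_exons(gene)), function(i) {
    genomic_interval(gene$span$chrom, gene$exon_starts[i], gene$exon_ends[i],
                     gene$span$strand)
  })
}

# Feature (exon or intron) by 1-based ordinal in transcription direction.
feature_of <- function(gene, which = c("exon", "intron"), ordinal) {
  which <- match.arg(which)
  feats <- if (which == "exon") exons_of(gene) else introns_of(gene)
  if (gene$span$strand == "-") feats <- rev(feats)
  if (ordinal < 1L || ordinal > length(feats))
    sc_stop("gene '%s' has no %s with ordinal %d", gene$gene_id, which, ordinal)
  feats[[ordinal]]
}

#' Exon density of a gene
#'
#' Exon density is the total exon number divided by the gene length in
#' kilobases.
#'
#' @param gene A `gene_model`.
#' @return Exons per kilobase.
#' @examples
#' g <- gene_model("g", "c", 0, 5000, "+", c(0, 1000, 4900), c(100, 1100, 5000))
#' exon_density(g) # 0.6
#' @export
exon_density <- function(gene) {
  len <- gene_length(gene)
  if (len <= 0) sc_stop("gene '%s' has zero-length span", gene$gene_id)
  n_exons(gene) / (len / 1000)
}

#' Gene span extended by flanking sequence
#'
#' Returns the gene span extended by `flank` bp on both sides, clipped to the
#' chromosome bounds when `chrom_length` is supplied (clipping is silent).
#'
#' @param gene A `gene_model`.
#' @param flank Flank size in bp (default 1000).
#' @param chrom_length Optional chromosome length used to clip the extension.
#' @return A `genomic_interval`.
#' @export
flanked_region <- function(gene, flank = 1000, chrom_length = NULL) {
  stopifnot(flank >= 0)
  s <- max(0, gene$span$start - flank)
  e <- gene$span$end + flank
  if (!is.null(chrom_length)) e <- min(e, chrom_length)
  genomic_interval(gene$span$chrom, s, e, gene$span$strand)
}

#' Read a gene annotation
#'
#' Reads gene models from BED12 or minimal GTF (gene/exon features). BED
#' coordinates are used natively; GTF 1-based starts are shifted to 0-based.
#' Malformed lines raise an error naming the offending line number;
#' overlapping or unsorted exon blocks raise a validation error.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bed12"`, or `"gtf"`.
#' @return A list of `gene_model` objects in input order.
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "bed12"
  }
  if (format == "bed12") read_bed12(path) else read_minimal_gtf(path)
}

read_bed12 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      sc_stop("%s line %d: expected 12 BED fields, got %d", path, i, length(f))
    start <- suppressWarnings(as.numeric(f[2L])); end <- suppressWarnings(as.numeric(f[3L]))
    nblock <- suppressWarnings(as.integer(f[10L]))
    if (anyNA(c(start, end, nblock)))
      sc_stop("%s line %d: non-numeric coordinates", path, i)
    sizes <- suppressWarnings(as.numeric(strsplit(f[11L], ",")[[1L]]))
    offs <- suppressWarnings(as.numeric(strsplit(f[12L], ",")[[1L]]))
    if (anyNA(sizes) || anyNA(offs) || length(sizes) != nblock || length(offs) != nblock)
      sc_stop("%s line %d: blockSizes/blockStarts do not match blockCount", path, i)
    if (is.unsorted(offs, strictly = TRUE))
      sc_stop("%s line %d: blockStarts not sorted", path, i)
    strand <- f[6L]
    if (!strand %in% c("+", "-")) strand <- "+"
    j <- j + 1L
    out[[j]] <- tryCatch(
      gene_model(f[4L], f[1L], start, end, strand,
                 start + offs, start + offs + sizes),
      error = function(e) sc_stop("%s line %d: %s", path, i, conditionMessage(e)))
  }
  out[seq_len(j)]
}

read_minimal_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  recs <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      sc_stop("%s line %d: expected 9 GTF fields, got %d", path, i, length(f))
    type <- f[3L]
    if (!type %in% c("gene", "exon")) next
    m <- regmatches(f[9L], regexec('gene_id[ ]+"?([^";]+)"?', f[9L]))[[1L]]
    if (length(m) < 2L)
      sc_stop("%s line %d: missing gene_id attribute", path, i)
    start <- suppressWarnings(as.numeric(f[4L])) - 1  # to 0-based
    end <- suppressWarnings(as.numeric(f[5L]))
    if (anyNA(c(start, end)))
      sc_stop("%s line %d: non-numeric coordinates", path, i)
    recs[[length(recs) + 1L]] <- list(gene = m[2L], chrom = f[1L], type = type,
                                      start = start, end = end, strand = f[7L],
                                      line = i)
  }
  ids <- unique(vapply(recs, `[[`, "", "gene"))
  lapply(ids, function(id) {
    rs <- Filter(function(r) r$gene == id, recs)
    ex <- Filter(function(r) r$type == "exon", rs)
    if (length(ex) == 0L) sc_stop("%s: gene '%s' has no exon features", path, id)
    gn <- Filter(function(r) r$type == "gene", rs)
    o <- order(vapply(ex, `[[`, 0, "start"))
    ex <- ex[o]
    es <- vapply(ex, `[[`, 0, "start"); ee <- vapply(ex, `[[`, 0, "end")
    span_s <- if (length(gn)) gn[[1L]]$start else min(es)
    span_e <- if (length(gn)) gn[[1L]]$end else max(ee)
    gene_model(id, ex[[1L]]$chrom, span_s, span_e, ex[[1L]]$strand, es, ee)
  })
}

#' Write gene models as BED12
#'
#' Round-trips through [read_annotation()] losslessly (identifier, span,
#' strand, and exon blocks).
#'
#' @param genes List of `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  rows <- vapply(genes, function(g) {
    sizes <- paste(format(g$exon_ends - g$exon_starts, scientific = FALSE, trim = TRUE),
                   collapse = ",")
    offs <- paste(format(g$exon_starts - g$span$start, scientific = FALSE, trim = TRUE),
                  collapse = ",")
    paste(g$span$chrom,
          format(g$span$start, scientific = FALSE, trim = TRUE),
          format(g$span$end, scientific = FALSE, trim = TRUE),
          g$gene_id, 0L, g$span$strand,
          format(g$span$start, scientific = FALSE, trim = TRUE),
          format(g$span$end, scientific = FALSE, trim = TRUE),
          "0", n_exons(g), sizes, offs, sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
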