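# Genome sequence data model: per-chromosome DNA strings with exact lengths.

#' Create a genome sequence object
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences over the alphabet A, C, G, T, N.
#' @return An object of class `genome_sequence` with fields `seq`
#'   (`DNAStringSet`), `lengths` (named integer) and `size` (total bp).
#' @export
genome_sequence <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      sc_stop("chromosome sequences must be named")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (!methods::is(seqs, "DNAStringSet")) sc_stop("seqs must be a DNAStringSet or named character")
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  structure(list(seq = seqs, lengths = lens, size = sum(as.numeric(lens))),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d chromosome(s), %s bp total\n",
              length(x$lengths), format(x$size, big.mark = ",")))
  invisible(x)
}

#' Total genome size in base pairs
#' @param genome A `genome_sequence`.
#' @return Numeric total size.
#' @export
genome_size <- function(genome) genome$size

#' Read / write a genome FASTA
#'
#' @param path FASTA file path.
#' @return `read_genome` returns a `genome_sequence`; `write_genome` returns
#'   `path` invisibly.
#' @export
read_genome <- function(path) genome_sequence(Biostrings::readDNAStringSet(path))

#' @rdname read_genome
#' @param genome A `genome_sequence`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

check_interval_bounds <- function(interval, genome) {
  len <- genome$lengths[interval$chrom]
  if (is.na(len))
    sc_stop("chromosome '%s' not present in genome (have: %s)", interval$chrom,
            paste(names(genome$lengths), collapse = ", "))
  if (interval$start < 0 || interval$end > len)
    sc_stop("interval [%d, %d) out of bounds for %s (length %d)",
            interval$start, interval$end, interval$chrom, len)
  invisible(TRUE)
}

#' GC percentage of a genomic interval
#'
#' 100 times the number of G or C bases divided by the interval length in
#' base pairs. N bases count toward the length but not toward GC.
#'
#' @param interval A `genomic_interval` (or a `gene_model`, whose span is
#'   used).
#' @param genome A `genome_sequence`.
#' @return Percent GC in `[0, 100]`.
#' @export
gc_percent <- function(interval, genome) {
  if (inherits(interval, "gene_model")) interval <- interval$span
  check_interval_bounds(interval, genome)
  gc_bases(interval, genome) / interval_length(interval) * 100
}

# Count of G+C bases in an interval (0-based half-open coordinates).
gc_bases <- function(interval, genome) {
  if (inherits(interval, "gene_model")) interval <- interval$span
  check_interval_bounds(interval, genome)
  s <- Biostrings::subseq(genome$seq[[interval$chrom]],
                          start = interval$start + 1L, end = interval$end)
  sum(Biostrings::letterFrequency(s, c("G", "C")))
}
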