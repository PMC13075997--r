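# Fragment ingestion, per-base coverage, coverage normalization, spike-in
# calibration, and bedGraph track I/O.
#
# Tracks hold one numeric Rle per chromosome plus the normalization mode and
# the genome size used for scaling.

#' Create a fragment set
#'
#' A fragment set holds the mapped, unstranded paired-end fragments of one
#' antibody/condition/replicate together with its spike-in fragment count.
#'
#' @param fragments A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). All fragments must have positive length.
#' @param label Sample label (antibody/condition/replicate).
#' @param spike_in_count Number of fragments mapped to the spike-in genome
#'   (non-negative).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, label = "sample", spike_in_count = 0L) {
  fragments <- data.table::as.data.table(fragments)[, c("chrom", "start", "end")]
  fragments[, `:=`(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end))]
  if (nrow(fragments) && any(fragments$end <= fragments$start))
    sc_stop("fragment set '%s': fragments must have positive length", label)
  if (spike_in_count < 0) sc_stop("spike_in_count must be non-negative")
  by_chrom <- if (nrow(fragments)) {
    lapply(split(fragments, by = "chrom", keep.by = FALSE), function(d)
      IRanges::IRanges(start = d$start + 1L, end = d$end))
  } else list()
  structure(list(fragments = fragments, by_chrom = by_chrom,
                 label = label, spike_in_count = as.numeric(spike_in_count)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s': %d fragments, spike-in %d\n",
              x$label, nrow(x$fragments), x$spike_in_count))
  invisible(x)
}

#' Number of fragments in a fragment set
#' @param frags A `fragment_set`.
#' @return Integer count.
#' @export
n_fragments <- function(frags) nrow(frags$fragments)

#' Read fragments from a BED3 file
#'
#' @param path BED3 file (chrom, start, end; tab-separated, no header).
#' @param label Sample label.
#' @param spike_in_count Spike-in fragment count for this sample.
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path, label = basename(path), spike_in_count = 0L) {
  d <- data.table::fread(path, header = FALSE, select = 1:3,
                         col.names = c("chrom", "start", "end"))
  fragment_set(d, label = label, spike_in_count = spike_in_count)
}

#' Write fragments to a BED3 file
#' @param frags A `fragment_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  data.table::fwrite(frags$fragments, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with at least the columns `sample`,
#' `fragments_path` and `spike_in_count`; extra columns (factor, condition,
#' replicate) are carried through.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  need <- c("sample", "fragments_path", "spike_in_count")
  miss <- setdiff(need, names(d))
  if (length(miss))
    sc_stop("sample sheet '%s' missing column(s): %s", path, paste(miss, collapse = ", "))
  if (any(is.na(d$spike_in_count)) || any(d$spike_in_count < 0))
    sc_stop("sample sheet '%s': spike_in_count must be non-negative", path)
  d
}

new_coverage_track <- function(values, mode, genome_size) {
  structure(list(values = values, mode = mode, genome_size = genome_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track [%s]: %d chromosome(s), genome size %s\n",
              x$mode, length(x$values), format(x$genome_size, big.mark = ",")))
  invisible(x)
}

#' Per-base raw coverage from fragments
#'
#' The value at base `b` is the number of fragments whose interval covers
#' `b` (bedtools genomecov semantics).
#'
#' @param frags A `fragment_set`.
#' @param genome A `genome_sequence`, or a named vector of chromosome lengths.
#' @return A `coverage_track` with mode `"raw"`.
#' @export
coverage_from_fragments <- function(frags, genome) {
  lens <- if (inherits(genome, "genome_sequence")) genome$lengths else genome
  bad_chrom <- setdiff(unique(frags$fragments$chrom), names(lens))
  if (length(bad_chrom))
    sc_stop("fragments on chromosome(s) absent from genome: %s",
            paste(bad_chrom, collapse = ", "))
  if (nrow(frags$fragments)) {
    over <- frags$fragments[end > lens[chrom] | start < 0]
    if (nrow(over))
      sc_stop("fragment beyond chromosome bounds: %s:%d-%d",
              over$chrom[1L], over$start[1L], over$end[1L])
  }
  vals <- lapply(stats::setNames(names(lens), names(lens)), function(ch) {
    ir <- frags$by_chrom[[ch]]
    if (is.null(ir)) ir <- IRanges::IRanges()
    methods::as(IRanges::coverage(ir, width = lens[[ch]]), "Rle")
  })
  new_coverage_track(vals, "raw", sum(as.numeric(lens)))
}

#' Total per-base count sum of a track
#' @param track A `coverage_track`.
#' @return Numeric sum over all bases of the genome.
#' @export
track_sum <- function(track) sum(vapply(track$values, function(v) sum(as.numeric(S4Vectors::runValue(v)) * S4Vectors::runLength(v)), numeric(1)))

#' Coverage normalization (fraction of counts scaled by genome size)
#'
#' Each base's value becomes `count_b / T * G`, where `T` is the sum of raw
#' per-base counts over the whole genome and `G` the genome size. Uniform raw
#' coverage therefore maps every base to exactly 1, and the normalized track
#' sums to `G`.
#'
#' @param track A `coverage_track` with mode `"raw"`.
#' @return A `coverage_track` with mode `"coverage_normalized"`.
#' @export
normalize_coverage <- function(track) {
  if (track$mode != "raw") sc_stop("normalize_coverage expects a raw track, got '%s'", track$mode)
  T <- track_sum(track)
  if (T <= 0) sc_stop("cannot normalize an empty track (total count 0)")
  G <- track$genome_size
  # (v * G) / T rather than v * (G / T): keeps the uniform case exactly 1.
  vals <- lapply(track$values, function(v) (v * G) / T)
  new_coverage_track(vals, "coverage_normalized", G)
}

#' Spike-in scale factor
#'
#' The calibration factor is 10,000 divided by the number of fragments mapped
#' to the spike-in (E. coli) genome.
#'
#' @param spike_in_count Positive spike-in fragment count.
#' @return Numeric scale factor.
#' @export
spike_scale_factor <- function(spike_in_count) {
  if (is.na(spike_in_count) || spike_in_count <= 0)
    sc_stop("spike-in calibration impossible: spike_in_count must be > 0")
  10000 / spike_in_count
}

#' Spike-in calibrate a raw track
#'
#' Multiplies every per-base value by the scale factor. Calibration applies
#' to raw counts (not to coverage-normalized values); the two normalized
#' track types are kept separate.
#'
#' @param track A `coverage_track` with mode `"raw"`.
#' @param factor Positive scale factor, e.g. from [spike_scale_factor()].
#' @return A `coverage_track` with mode `"spike_calibrated"`.
#' @export
calibrate_track <- function(track, factor) {
  if (!is.numeric(factor) || factor <= 0) sc_stop("scale factor must be > 0")
  if (track$mode != "raw") sc_stop("calibrate_track expects a raw track, got '%s'", track$mode)
  new_coverage_track(lapply(track$values, function(v) v * factor),
                     "spike_calibrated", track$genome_size)
}

#' Per-base values of a track over a window
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window. Positions outside the
#'   chromosome are returned as `NA`.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) sc_stop("track has no chromosome '%s'", chrom)
  len <- length(v)
  out <- rep(NA_real_, end - start)
  s <- max(start, 0); e <- min(end, len)
  if (s < e) out[(s - start + 1):(e - start)] <- as.numeric(v[(s + 1):e])
  out
}

#' Write / read a coverage track as bedGraph
#'
#' The bedGraph dialect is 0-based half-open with equal-value runs merged and
#' zero-valued runs omitted. Two `#` header lines carry the track metadata
#' (mode, genome size, chromosome lengths) so the round-trip is lossless.
#' Reading an unsorted bedGraph raises an error.
#'
#' @param track A `coverage_track`.
#' @param path Output path (plain text).
#' @return `write_track` returns `path` invisibly; `read_track` returns a
#'   `coverage_track`.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lens <- vapply(track$values, length, integer(1))
  writeLines(c(sprintf("# splicechrom_track mode=%s genome_size=%s",
                       track$mode, format(track$genome_size, scientific = FALSE)),
               sprintf("# chrom_lengths %s",
                       paste(sprintf("%s:%d", names(lens), lens), collapse = ","))),
             con)
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    rl <- S4Vectors::runLength(v); rv <- as.numeric(S4Vectors::runValue(v))
    ends <- cumsum(rl); starts <- ends - rl
    keep <- rv != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                         formatC(rv[keep], format = "g", digits = 10)), con)
  }
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  meta <- hdr[grepl("splicechrom_track", hdr)]
  if (!length(meta)) sc_stop("'%s' is not a splicechrom bedGraph (missing header)", path)
  mode <- sub(".*mode=([^ ]+).*", "\\1", meta[1L])
  gsize <- as.numeric(sub(".*genome_size=([0-9]+).*", "\\1", meta[1L]))
  lens_line <- hdr[grepl("chrom_lengths", hdr)]
  if (!length(lens_line)) sc_stop("'%s' missing chrom_lengths header", path)
  pairs <- strsplit(strsplit(sub("# chrom_lengths ", "", lens_line[1L]), ",")[[1L]], ":")
  lens <- stats::setNames(vapply(pairs, function(p) as.numeric(p[2L]), numeric(1)),
                          vapply(pairs, `[[`, "", 1L))
  d <- if (length(body)) {
    data.table::fread(text = body, header = FALSE,
                      col.names = c("chrom", "start", "end", "value"))
  } else data.table::data.table(chrom = character(), start = numeric(),
                                end = numeric(), value = numeric())
  vals <- lapply(stats::setNames(names(lens), names(lens)), function(ch) {
    di <- d[chrom == ch]
    len <- lens[[ch]]
    if (!nrow(di)) return(S4Vectors::Rle(0, len))
    if (is.unsorted(di$start, strictly = TRUE) || any(di$start[-1L] < di$end[-nrow(di)]))
      sc_stop("unsorted or overlapping bedGraph intervals on %s in '%s'", ch, path)
    if (di$end[nrow(di)] > len) sc_stop("bedGraph interval beyond %s length in '%s'", ch, path)
    rl <- numeric(0); rv <- numeric(0)
    prev <- 0
    for (i in seq_len(nrow(di))) {
      if (di$start[i] > prev) { rl <- c(rl, di$start[i] - prev); rv <- c(rv, 0) }
      rl <- c(rl, di$end[i] - di$start[i]); rv <- c(rv, di$value[i])
      prev <- di$end[i]
    }
    if (prev < len) { rl <- c(rl, len - prev); rv <- c(rv, 0) }
    S4Vectors::Rle(rv, rl)
  })
  new_coverage_track(vals, mode, gsize)
}

#' Pool several fragment sets into one
#'
#' Concatenates fragments and sums spike-in counts (used to merge replicates
#' before track building).
#'
#' @param ... `fragment_set` objects, or a single list of them.
#' @param label Label of the pooled set.
#' @return A `fragment_set`.
#' @export
pool_fragments <- function(..., label = "pooled") {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "fragment_set")) fs <- fs[[1L]]
  fragment_set(data.table::rbindlist(lapply(fs, `[[`, "fragments")),
               label = label,
               spike_in_count = sum(vapply(fs, `[[`, numeric(1), "spike_in_count")))
}
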