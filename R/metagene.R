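# Metagene matrices: genes x bins summaries of a coverage track around an
# anchor (TSS/TES) or over length-scaled gene bodies. Rows are strand-flipped
# so the left edge is always upstream in transcription direction; the bin
# statistic is the mean of per-base values. Out-of-chromosome bases are
# missing and excluded from bin and column means.

new_metagene_matrix <- function(mat, anchor, bin_size, upstream, downstream,
                                body_bins = NULL, dropped = character()) {
  structure(mat, class = c("metagene_matrix", "matrix"),
            anchor = anchor, bin_size = bin_size, upstream = upstream,
            downstream = downstream, body_bins = body_bins, dropped = dropped)
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix [%s]: %d gene(s) x %d bin(s)%s\n",
              attr(x, "anchor"), nrow(x), ncol(x),
              if (length(attr(x, "dropped"))) sprintf(" (%d dropped)", length(attr(x, "dropped"))) else ""))
  invisible(x)
}

bin_means <- function(vals, bin_size) {
  m <- matrix(vals, nrow = bin_size)
  out <- colMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

# Oriented per-base values for a window; minus-strand windows are reversed so
# index 1 is the most upstream base in transcription direction.
oriented_window <- function(track, chrom, start, end, strand) {
  v <- track_values(track, chrom, start, end)
  if (strand == "-") rev(v) else v
}

#' Metagene matrix anchored at a reference point
#'
#' One row per gene: per-bin means of the track over the window
#' `[anchor - upstream, anchor + downstream)` oriented in transcription
#' direction (minus-strand windows are mirrored).
#'
#' @param track A `coverage_track`.
#' @param genes List of `gene_model`.
#' @param anchor `"TSS"` or `"TES"`.
#' @param upstream,downstream Window extents in bp.
#' @param bin_size Bin width in bp; must divide `upstream + downstream`.
#' @return A `metagene_matrix` (genes x bins) with gene ids as row names.
#' @export
metagene_reference_point <- function(track, genes, anchor = c("TSS", "TES"),
                                     upstream = 1000, downstream = 1000,
                                     bin_size = 50) {
  anchor <- match.arg(anchor)
  if ((upstream + downstream) %% bin_size != 0)
    sc_stop("bin_size must divide upstream + downstream")
  nb <- (upstream + downstream) / bin_size
  mat <- matrix(NA_real_, length(genes), nb)
  rownames(mat) <- vapply(genes, `[[`, "", "gene_id")
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    a <- if (anchor == "TSS") tss(g) else tes(g)
    st <- g$span$strand
    win <- if (st == "-") c(a - downstream, a + upstream) else c(a - upstream, a + downstream)
    mat[i, ] <- bin_means(oriented_window(track, g$span$chrom, win[1], win[2], st), bin_size)
  }
  new_metagene_matrix(mat, paste0("reference-point ", anchor), bin_size,
                      upstream, downstream)
}

#' Metagene matrix over length-scaled gene bodies
#'
#' The gene body is partitioned into `body_bins` near-equal spans (the
#' remainder is spread over the leftmost, most-upstream bins); flanks of
#' `upstream`/`downstream` bp are binned at `bin_size` as in reference-point
#' mode. Genes shorter than `body_bins` bp are dropped with a warning and
#' recorded in the `dropped` attribute.
#'
#' @param track A `coverage_track`.
#' @param genes List of `gene_model`.
#' @param upstream,downstream Flank extents in bp.
#' @param body_bins Number of gene-body bins (>= 1).
#' @param bin_size Flank bin width in bp; must divide both flanks.
#' @return A `metagene_matrix` with
#'   `upstream/bin_size + body_bins + downstream/bin_size` columns.
#' @export
metagene_scale_regions <- function(track, genes, upstream = 1000,
                                   downstream = 1000, body_bins = 100,
                                   bin_size = 50) {
  stopifnot(body_bins >= 1)
  if (upstream %% bin_size != 0 || downstream %% bin_size != 0)
    sc_stop("bin_size must divide upstream and downstream")
  nb_up <- upstream / bin_size; nb_dn <- downstream / bin_size
  keep <- vapply(genes, function(g) gene_length(g) >= body_bins, logical(1))
  dropped <- vapply(genes[!keep], `[[`, "", "gene_id")
  if (length(dropped))
    warning(sprintf("%d gene(s) shorter than body_bins dropped: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  genes <- genes[keep]
  mat <- matrix(NA_real_, length(genes), nb_up + body_bins + nb_dn)
  rownames(mat) <- vapply(genes, `[[`, "", "gene_id")
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    st <- g$span$strand
    full <- oriented_window(track, g$span$chrom,
                            g$span$start - if (st == "-") downstream else upstream,
                            g$span$end + if (st == "-") upstream else downstream, st)
    upv <- full[seq_len(upstream)]
    body <- full[upstream + seq_len(gene_length(g))]
    dnv <- full[upstream + gene_length(g) + seq_len(downstream)]
    L <- length(body)
    w <- rep(L %/% body_bins, body_bins)
    r <- L %% body_bins
    if (r > 0) w[seq_len(r)] <- w[seq_len(r)] + 1L
    idx <- factor(rep(seq_len(body_bins), times = w), levels = seq_len(body_bins))
    bsum <- tapply(body, idx, function(x) mean(x, na.rm = TRUE))
    bsum[!is.finite(bsum)] <- NA_real_
    mat[i, ] <- c(if (nb_up) bin_means(upv, bin_size),
                  as.numeric(bsum),
                  if (nb_dn) bin_means(dnv, bin_size))
  }
  new_metagene_matrix(mat, "scale-regions", bin_size, upstream, downstream,
                      body_bins = body_bins, dropped = dropped)
}

#' Per-bin mean profile of a metagene matrix (the "average plot")
#'
#' Column means ignoring missing cells; an all-missing column yields `NA`.
#'
#' @param matrix A `metagene_matrix` (or plain matrix) with at least one row.
#' @return Numeric vector of per-bin means.
#' @export
column_mean_profile <- function(matrix) {
  if (!nrow(matrix)) sc_stop("metagene matrix is empty")
  out <- colMeans(matrix, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Write / read a metagene matrix (gzip TSV with a JSON header line)
#'
#' @param mat A `metagene_matrix`.
#' @param path Output path (`.tsv.gz` recommended).
#' @return `write_metagene_matrix` returns `path` invisibly;
#'   `read_metagene_matrix` returns a `metagene_matrix`.
#' @export
write_metagene_matrix <- function(mat, path) {
  con <- gzfile(path, "w")
  on.exit(close(con))
  hdr <- list(anchor = attr(mat, "anchor"), bin_size = attr(mat, "bin_size"),
              upstream = attr(mat, "upstream"), downstream = attr(mat, "downstream"),
              body_bins = attr(mat, "body_bins"), n_genes = nrow(mat),
              dropped = attr(mat, "dropped"))
  writeLines(paste0("#", jsonlite::toJSON(hdr, auto_unbox = TRUE, null = "null")), con)
  utils::write.table(cbind(gene_id = rownames(mat), as.data.frame(unclass(mat))),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metagene_matrix
#' @export
read_metagene_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  d <- utils::read.table(text = lines[-1L], sep = "\t", header = TRUE,
                         check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  dimnames(m) <- list(d[[1L]], NULL)
  new_metagene_matrix(m, hdr$anchor, hdr$bin_size, hdr$upstream, hdr$downstream,
                      body_bins = hdr$body_bins,
                      dropped = if (is.null(hdr$dropped)) character() else hdr$dropped)
}
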