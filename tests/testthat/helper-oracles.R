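# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and IRanges): coverage and overlap checks are per-base
# membership loops, the exact rank-sum p enumerates combinations directly.

# Per-base coverage by explicit membership test.
oracle_coverage <- function(frags, chrom_len) {
  vapply(seq_len(chrom_len) - 1L, function(b)
    sum(frags$start <= b & frags$end > b), numeric(1))
}

# Any-overlap fragment count by pairwise comparison.
oracle_count <- function(frags, start, end) {
  sum(frags$start < end & frags$end > start)
}

# Mean of per-base values per bin, NA-aware.
oracle_bin_means <- function(vals, bin_size) {
  nb <- length(vals) / bin_size
  out <- vapply(seq_len(nb), function(j) {
    x <- vals[((j - 1) * bin_size + 1):(j * bin_size)]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  out
}

# Exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled observations to group x.
oracle_mw_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_low <- mean(Us <= U_obs)
  p_high <- mean(Us >= U_obs)
  min(1, 2 * min(p_low, p_high))
}

# Random fragment table on a single chromosome.
random_frags <- function(n, chrom_len, chrom = "c", max_len = 200) {
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  start <- sample.int(chrom_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = pmin(start + len, chrom_len))
}

# A tiny deterministic gene for reuse in tests.
toy_gene <- function(strand = "+") {
  gene_model("toy", "c", 100, 700, strand,
             exon_starts = c(100, 300, 600), exon_ends = c(200, 400, 700))
}

# Small simulation config for fast generator tests.
mini_config <- function(seed = 5, ...) {
  simulation_config(seed = seed, n_genes = 40, chrom_length = 6e5, ...)
}
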