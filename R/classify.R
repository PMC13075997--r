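# Gene-class assignment: activity thresholding, differential enrichment
# after RNase A treatment (a defined simplified test), and quantile splits.

#' Classify genes as active or inactive by signal density
#'
#' A gene is active when its elongating-polymerase density
#' (`log2(1 + RPK)`) is at or above the threshold (inclusive; the default
#' threshold is 4, i.e. RPK 15).
#'
#' @param density Non-negative density value(s).
#' @param threshold Density threshold (default 4).
#' @return Character vector, `"active"` or `"inactive"`.
#' @export
classify_activity <- function(density, threshold = 4) {
  stopifnot(all(density >= 0, na.rm = TRUE))
  ifelse(density >= threshold, "active", "inactive")
}

#' Differential enrichment between two count conditions
#'
#' A fully specified, reproducible differential test for per-gene fragment
#' counts across replicates:
#' 1. size factors by median-of-ratios (per-sample median over reference
#'    genes of count / geometric-mean row; genes with any zero count are
#'    excluded from the reference);
#' 2. per-gene log2 fold change
#'    `log2((mean normalized treated + 0.5) / (mean normalized control + 0.5))`;
#' 3. p-value from a two-sided Welch t-test on `log2(normalized + 0.5)`
#'    across replicates (degenerate zero-variance rows: p = 1 when the
#'    group means are equal, else the t-test result);
#' 4. Benjamini-Hochberg adjustment;
#' 5. a gene is labelled sensitive (signal decreases on treatment) when
#'    `log2FC <= -lfc_threshold` and adjusted p < `alpha`.
#'
#' All-zero genes are excluded from the size-factor reference and reported
#' with p = 1.
#'
#' @param counts_control,counts_treated Non-negative integer matrices,
#'   genes x replicates (>= 2 replicates each); row names are gene ids.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param sensitive_label,insensitive_label Labels to emit.
#' @return A data.frame: `gene_id`, `base_mean` (mean normalized count),
#'   `log2fc`, `pvalue`, `padj`, `label`.
#' @export
differential_enrichment <- function(counts_control, counts_treated,
                                    lfc_threshold = 1, alpha = 0.05,
                                    sensitive_label = "rnase_sensitive",
                                    insensitive_label = "chromatin_bound") {
  counts_control <- as.matrix(counts_control)
  counts_treated <- as.matrix(counts_treated)
  if (ncol(counts_control) < 2 || ncol(counts_treated) < 2)
    sc_stop("differential_enrichment requires >= 2 replicates per condition")
  if (nrow(counts_control) != nrow(counts_treated))
    sc_stop("conditions must have the same genes")
  if (any(counts_control < 0) || any(counts_treated < 0))
    sc_stop("counts must be non-negative")
  cnt <- cbind(counts_control, counts_treated)
  ids <- rownames(cnt)
  if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(cnt)))
  nc <- ncol(counts_control)
  ctrl_idx <- seq_len(nc); trt_idx <- nc + seq_len(ncol(counts_treated))

  ref <- rowSums(cnt == 0) == 0
  if (!any(ref)) sc_stop("no reference genes for size factors (every gene has a zero count)")
  geo <- exp(rowMeans(log(cnt[ref, , drop = FALSE])))
  sf <- apply(cnt[ref, , drop = FALSE], 2, function(cc) stats::median(cc / geo))
  norm <- sweep(cnt, 2, sf, "/")

  mean_c <- rowMeans(norm[, ctrl_idx, drop = FALSE])
  mean_t <- rowMeans(norm[, trt_idx, drop = FALSE])
  log2fc <- log2((mean_t + 0.5) / (mean_c + 0.5))
  lognorm <- log2(norm + 0.5)
  all_zero <- rowSums(cnt) == 0
  pvalue <- vapply(seq_len(nrow(cnt)), function(i) {
    if (all_zero[i]) return(1)
    a <- lognorm[i, trt_idx]; b <- lognorm[i, ctrl_idx]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b)$p.value
  }, numeric(1))
  padj <- benjamini_hochberg(pvalue)
  label <- ifelse(log2fc <= -lfc_threshold & padj < alpha,
                  sensitive_label, insensitive_label)
  data.frame(gene_id = ids, base_mean = rowMeans(norm), log2fc = log2fc,
             pvalue = pvalue, padj = padj, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split values into quantile groups
#'
#' Genes are ranked and split into `q` groups at empirical quantile
#' boundaries; tied values share the lower group. With distinct values the
#' group sizes are within one of `n/q`. Degenerate splits (a group would be
#' empty, e.g. constant values) are an error.
#'
#' @param values Numeric vector (e.g. a per-gene metric).
#' @param q Number of groups (>= 2, <= number of values).
#' @return Integer group index per value (1 = lowest).
#' @examples
#' quantile_split(1:8, 4) # 1 1 2 2 3 3 4 4
#' @export
quantile_split <- function(values, q) {
  n <- length(values)
  if (q < 2) sc_stop("q must be >= 2")
  if (q > n) sc_stop("q = %d exceeds the number of values (%d)", q, n)
  grp <- as.integer(ceiling(rank(values, ties.method = "min") * q / n))
  if (length(unique(grp)) < q)
    sc_stop("degenerate quantiles: %d of %d groups would be empty (tied values)",
            q - length(unique(grp)), q)
  grp
}
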