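# rMATS-style PSI event tables: parsing, event-level error types, gene-level
# splice classes, and the summary / concordance / decile reports.
#
# Delta-PSI orientation is WT minus KD throughout: a positive value means
# higher inclusion in WT, i.e. the exon is skipped upon knockdown.

EVENT_TYPES <- c("SE", "MXE", "RI", "A5SS", "A3SS")
EXON_CLASSES <- c("unchanged", "skipped", "included", "MXE", "untested")
INTRON_CLASSES <- c("unchanged", "retained", "removed", "untested")

#' Validate a splice event table
#'
#' @param events A data.frame with columns `gene_id`, `event_type` (one of
#'   SE, MXE, RI, A5SS, A3SS), `delta_psi` (WT minus KD, in `[-1, 1]`), and
#'   `p_value` (in `[0, 1]`).
#' @return The validated data.frame (class `splice_events`).
#' @export
splice_events <- function(events) {
  events <- as.data.frame(events)
  need <- c("gene_id", "event_type", "delta_psi", "p_value")
  miss <- setdiff(need, names(events))
  if (length(miss)) sc_stop("event table missing column(s): %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad)) sc_stop("unknown event type(s): %s", paste(bad, collapse = ", "))
  ok_psi <- is.na(events$delta_psi) | (events$delta_psi >= -1 & events$delta_psi <= 1)
  ok_p <- is.na(events$p_value) | (events$p_value >= 0 & events$p_value <= 1)
  if (!all(ok_psi)) sc_stop("delta_psi outside [-1, 1] at row %d", which(!ok_psi)[1L])
  if (!all(ok_p)) sc_stop("p_value outside [0, 1] at row %d", which(!ok_p)[1L])
  class(events) <- c("splice_events", "data.frame")
  events
}

#' Read a splice event TSV
#'
#' Expects a header with columns `gene_id`, `event_type`,
#' `IncLevelDifference` (or `delta_psi`) and `PValue` (or `p_value`). The
#' table's delta-PSI orientation must be declared: `"wt_minus_kd"` (the
#' package convention, default) or `"kd_minus_wt"` (flipped on read).
#'
#' @param path TSV path.
#' @param orientation Orientation of the IncLevelDifference column.
#' @return A `splice_events` data.frame (delta_psi in WT-minus-KD
#'   orientation).
#' @export
read_splice_events <- function(path, orientation = c("wt_minus_kd", "kd_minus_wt")) {
  orientation <- match.arg(orientation)
  d <- as.data.frame(data.table::fread(path))
  ren <- c(IncLevelDifference = "delta_psi", PValue = "p_value")
  for (nm in names(ren)) if (nm %in% names(d)) names(d)[names(d) == nm] <- ren[[nm]]
  ev <- splice_events(d)
  if (orientation == "kd_minus_wt") ev$delta_psi <- -ev$delta_psi
  ev
}

#' Convert a raw rMATS table to the package event schema
#'
#' Reads one `*.MATS.JC.txt`-style table (columns located by name, not
#' position: `GeneID`, `IncLevelDifference`, `PValue`), attaching the given
#' event type.
#'
#' @param path rMATS output table.
#' @param event_type The table's event type (SE, MXE, RI, A5SS, A3SS).
#' @param orientation Delta-PSI orientation of the table (rMATS prints
#'   sample1 minus sample2).
#' @return A `splice_events` data.frame.
#' @export
rmats_to_events <- function(path, event_type,
                            orientation = c("wt_minus_kd", "kd_minus_wt")) {
  orientation <- match.arg(orientation)
  if (!event_type %in% EVENT_TYPES) sc_stop("unknown event type '%s'", event_type)
  d <- as.data.frame(data.table::fread(path))
  need <- c("GeneID", "IncLevelDifference", "PValue")
  miss <- setdiff(need, names(d))
  if (length(miss)) sc_stop("rMATS table missing column(s): %s", paste(miss, collapse = ", "))
  ev <- splice_events(data.frame(gene_id = gsub('"', "", d$GeneID),
                                 event_type = event_type,
                                 delta_psi = d$IncLevelDifference,
                                 p_value = d$PValue, stringsAsFactors = FALSE))
  if (orientation == "kd_minus_wt") ev$delta_psi <- -ev$delta_psi
  ev
}

#' Is a splice event significant?
#'
#' Strict threshold: `p_value < alpha`.
#'
#' @param event A `splice_events` row/data.frame or a numeric p-value vector.
#' @param alpha Significance level (default 0.05).
#' @return Logical vector.
#' @export
is_significant <- function(event, alpha = 0.05) {
  p <- if (is.data.frame(event)) event$p_value else event
  !is.na(p) & p < alpha
}

#' Error type of a splice event
#'
#' SE and MXE events are exon inclusion errors, RI events are intron removal
#' errors, and A5SS/A3SS events are splice-site errors.
#'
#' @param event_type Event type string(s).
#' @return One of `"exon_inclusion"`, `"intron_removal"`, `"splice_site"`.
#' @export
error_type <- function(event_type) {
  bad <- setdiff(unique(event_type), EVENT_TYPES)
  if (length(bad)) sc_stop("unknown event type(s): %s", paste(bad, collapse = ", "))
  out <- rep("splice_site", length(event_type))
  out[event_type %in% c("SE", "MXE")] <- "exon_inclusion"
  out[event_type == "RI"] <- "intron_removal"
  out
}

#' Gene-level exon class from its events
#'
#' Among a gene's significant events: any SE with positive delta-PSI (higher
#' inclusion in WT, exon skipped upon KD) makes the gene skipped; otherwise
#' any SE with negative delta-PSI makes it included; otherwise any
#' significant MXE makes it MXE; otherwise unchanged. A gene with no
#' exon-type (SE/MXE) events at all is untested. The precedence order is
#' configurable.
#'
#' @param events Events of one gene (`splice_events` rows).
#' @param alpha Significance level (default 0.05).
#' @param precedence Order in which competing significant classes win.
#' @return One of `"skipped"`, `"included"`, `"MXE"`, `"unchanged"`,
#'   `"untested"`.
#' @export
classify_gene_exon <- function(events, alpha = 0.05,
                               precedence = c("skipped", "included", "MXE")) {
  stopifnot(setequal(precedence, c("skipped", "included", "MXE")))
  ex <- events[events$event_type %in% c("SE", "MXE"), , drop = FALSE]
  if (!nrow(ex)) return("untested")
  sig <- ex[is_significant(ex, alpha), , drop = FALSE]
  hit <- c(skipped = any(sig$event_type == "SE" & sig$delta_psi > 0),
           included = any(sig$event_type == "SE" & sig$delta_psi < 0),
           MXE = any(sig$event_type == "MXE"))
  for (cl in precedence) if (hit[[cl]]) return(cl)
  "unchanged"
}

#' Gene-level intron class from its events
#'
#' Among a gene's significant RI events (delta-PSI is the WT-minus-KD intron
#' inclusion level): negative delta-PSI means the intron stays in KD
#' transcripts (retained); positive means removed. No significant RI events:
#' unchanged; no RI events at all: untested.
#'
#' @inheritParams classify_gene_exon
#' @return One of `"retained"`, `"removed"`, `"unchanged"`, `"untested"`.
#' @export
classify_gene_intron <- function(events, alpha = 0.05) {
  ri <- events[events$event_type == "RI", , drop = FALSE]
  if (!nrow(ri)) return("untested")
  sig <- ri[is_significant(ri, alpha), , drop = FALSE]
  if (any(sig$delta_psi < 0)) return("retained")
  if (any(sig$delta_psi > 0)) return("removed")
  "unchanged"
}

#' Classify every gene in an event table
#'
#' @param events A `splice_events` data.frame (possibly many genes).
#' @param alpha Significance level.
#' @param precedence Exon-class precedence (see [classify_gene_exon()]).
#' @return A data.frame: `gene_id`, `exon_class`, `intron_class`.
#' @export
classify_splice_genes <- function(events, alpha = 0.05,
                                  precedence = c("skipped", "included", "MXE")) {
  events <- splice_events(events)
  ids <- unique(events$gene_id)
  sp <- split(events, factor(events$gene_id, levels = ids))
  data.frame(
    gene_id = ids,
    exon_class = vapply(sp, classify_gene_exon, "", alpha = alpha, precedence = precedence),
    intron_class = vapply(sp, classify_gene_intron, "", alpha = alpha),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize gene splice classes
#'
#' Counts and integer percentages (rounded half away from zero, see
#' [percent_round()]) of unchanged / skipped / included / MXE genes over the
#' exon-tested genes, the combined error-gene count (skipped + included +
#' MXE), and the same breakdown for intron classes over intron-tested genes.
#'
#' @param classes Output of [classify_splice_genes()].
#' @return A list with `exon` and `intron` data.frames (class, count,
#'   percent), `n_exon_tested`, `n_intron_tested`, `error_genes`,
#'   `error_percent`.
#' @export
summarize_splice_classes <- function(classes) {
  if (!nrow(classes)) sc_stop("empty class table")
  tested <- classes[classes$exon_class != "untested", , drop = FALSE]
  n <- nrow(tested)
  exon <- data.frame(class = setdiff(EXON_CLASSES, "untested"))
  exon$count <- vapply(exon$class, function(cl) sum(tested$exon_class == cl), integer(1))
  exon$percent <- if (n) percent_round(exon$count, n) else NA_integer_
  err <- sum(exon$count[exon$class != "unchanged"])
  itested <- classes[classes$intron_class != "untested", , drop = FALSE]
  ni <- nrow(itested)
  intron <- data.frame(class = setdiff(INTRON_CLASSES, "untested"))
  intron$count <- vapply(intron$class, function(cl) sum(itested$intron_class == cl), integer(1))
  intron$percent <- if (ni) percent_round(intron$count, ni) else NA_integer_
  list(exon = exon, intron = intron, n_exon_tested = n, n_intron_tested = ni,
       error_genes = err,
       error_percent = if (n) percent_round(err, n) else NA_integer_)
}

#' Event-level error-type breakdown
#'
#' Among significant events, the count and integer percentage of exon
#' inclusion, intron removal and splice-site errors.
#'
#' @param events A `splice_events` data.frame.
#' @param alpha Significance level.
#' @return A data.frame: `error_type`, `count`, `percent`; attribute
#'   `n_significant`.
#' @export
summarize_error_types <- function(events, alpha = 0.05) {
  sig <- events[is_significant(events, alpha), , drop = FALSE]
  et <- factor(error_type(sig$event_type),
               levels = c("exon_inclusion", "intron_removal", "splice_site"))
  cnt <- as.integer(table(et))
  out <- data.frame(error_type = levels(et), count = cnt,
                    percent = if (nrow(sig)) percent_round(cnt, nrow(sig)) else NA_integer_)
  attr(out, "n_significant") <- nrow(sig)
  out
}

#' Concordance of error status between two class tables
#'
#' Over genes exon-tested in both tables: among table-A error genes, the
#' percentage that are also error genes in B; among A genes without errors,
#' the percentage without errors in B. An error gene is one classed skipped,
#' included or MXE.
#'
#' @param classes_a,classes_b Outputs of [classify_splice_genes()].
#' @return A list: `error_to_error_percent`, `noerror_to_noerror_percent`,
#'   plus the underlying counts.
#' @export
splice_concordance <- function(classes_a, classes_b) {
  a <- classes_a[classes_a$exon_class != "untested", c("gene_id", "exon_class")]
  b <- classes_b[classes_b$exon_class != "untested", c("gene_id", "exon_class")]
  m <- merge(a, b, by = "gene_id", suffixes = c("_a", "_b"))
  if (!nrow(m)) sc_stop("no shared tested genes between the two class tables")
  err_a <- m$exon_class_a != "unchanged"
  err_b <- m$exon_class_b != "unchanged"
  n_err <- sum(err_a); n_noerr <- sum(!err_a)
  list(error_to_error_percent = if (n_err) percent_round(sum(err_a & err_b), n_err) else NA_integer_,
       noerror_to_noerror_percent = if (n_noerr) percent_round(sum(!err_a & !err_b), n_noerr) else NA_integer_,
       n_shared = nrow(m), n_error_a = n_err,
       n_error_concordant = sum(err_a & err_b),
       n_noerror_a = n_noerr, n_noerror_concordant = sum(!err_a & !err_b))
}

#' Expression-decile report of splice classes and occupancy groups
#'
#' Genes are split into `q` expression groups by FPKM quantiles. Within each
#' decile and occupancy class, the report gives the gene count, the
#' percentage of skipped genes, and the median expression score
#' `log2(1 + FPKM)`; per decile, expression medians of the two occupancy
#' classes are compared with the rank-sum test, Bonferroni-corrected over
#' deciles (adjusted threshold 0.01 by convention).
#'
#' @param classes Output of [classify_splice_genes()].
#' @param fpkm data.frame with columns `gene_id`, `fpkm`.
#' @param occupancy data.frame with columns `gene_id`, `occupancy_class`
#'   (e.g. `"U2AF2_high"` / `"U2AF2_low"`).
#' @param q Number of expression groups (default 10).
#' @param min_n Minimum genes per class per decile for the rank-sum
#'   comparison (default 2; smaller cells are skipped with a message).
#' @return A list: `table` (decile x occupancy class summary) and `tests`
#'   (per-decile rank-sum p and Bonferroni-adjusted p).
#' @export
decile_report <- function(classes, fpkm, occupancy, q = 10, min_n = 2) {
  d <- merge(merge(classes[classes$exon_class != "untested", ], fpkm, by = "gene_id"),
             occupancy, by = "gene_id")
  if (!nrow(d)) sc_stop("no overlap between class, FPKM and occupancy tables")
  d$decile <- quantile_split(d$fpkm, q)
  d$expr <- log_expression(d$fpkm)
  labs <- sort(unique(d$occupancy_class))
  cells <- expand.grid(decile = seq_len(q), occupancy_class = labs,
                       stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- d[d$decile == cells$decile[i] & d$occupancy_class == cells$occupancy_class[i], ]
    data.frame(decile = cells$decile[i], occupancy_class = cells$occupancy_class[i],
               n = nrow(s),
               percent_skipped = if (nrow(s)) percent_round(sum(s$exon_class == "skipped"), nrow(s)) else NA_integer_,
               median_expr = if (nrow(s)) stats::median(s$expr) else NA_real_)
  }))
  tests <- NULL
  if (length(labs) == 2) {
    p <- rep(NA_real_, q)
    for (dec in seq_len(q)) {
      x <- d$expr[d$decile == dec & d$occupancy_class == labs[1]]
      y <- d$expr[d$decile == dec & d$occupancy_class == labs[2]]
      if (length(x) < min_n || length(y) < min_n) {
        message(sprintf("decile %d: fewer than %d genes in a class; comparison skipped", dec, min_n))
        next
      }
      p[dec] <- mann_whitney(x, y)$p.value
    }
    tests <- data.frame(decile = seq_len(q), p_value = p,
                        p_adjusted = bonferroni(p, m = q))
  }
  list(table = tab, tests = tests)
}
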