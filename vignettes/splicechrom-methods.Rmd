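---
title: "splicechrom: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splicechrom: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Antibody-tethered chromatin profiling (CUT&RUN / CUT&Tag) yields mapped
paired-end fragments for a target protein. For splicing factors such as
U2AF2, the scientific questions are quantitative: how much signal sits on
each gene body relative to a genome-wide expectation, which genes carry
high occupancy, whether that occupancy sits on exons or introns, whether it
survives RNase treatment (i.e. is chromatin-bound rather than RNA-tethered),
and whether genes with high chromatin occupancy accumulate splicing errors —
skipped or spuriously included exons, retained introns — when the factor is
knocked down. `splicechrom` implements that analysis chain end to end, from
fragment BED files to gene classes and splicing-error reports, together with
a synthetic-data generator that plants every effect so the chain can be
validated without external downloads.

## Coverage model

Raw coverage at base $b$ is the number of fragments covering $b$ (half-open
intervals; bedtools `genomecov` semantics). Two normalizations are kept
strictly separate:

* **Coverage normalization** expresses each base as a fraction of the
  genome-wide count total, scaled by the genome size $G$:
  $v_b = \frac{c_b}{T}\,G$, where $T=\sum_b c_b$. Uniformly distributed
  counts therefore give $v_b = 1$ everywhere, which is the property that
  makes enrichment legible. Numerically we evaluate $(c_b \cdot G)/T$ rather
  than $c_b \cdot (G/T)$: when coverage is uniform the numerator and
  denominator are the identical floating-point number and the quotient is
  exactly 1.0, not 1 up to rounding.
* **Spike-in calibration** multiplies raw counts by $10{,}000 / s$, where
  $s$ is the number of fragments mapped to the spike-in (E. coli) genome.
  Calibration applies to raw counts only; it is the scale that permits
  cross-condition comparisons (e.g. drug treatments), whereas coverage
  normalization serves within-sample enrichment. Whether calibrated tracks
  should additionally be length-normalized is left open by the source
  protocols; we do not do so.

Tracks are run-length encoded per chromosome and serialized as bedGraph
(0-based half-open, zero runs omitted, equal-value runs merged) with two
`#` header lines carrying the mode, genome size, and chromosome lengths so
that a read/write round-trip is lossless. bigWig is deliberately not
emitted: the text dialect round-trips exactly and keeps fixtures inspectable.

## Occupancy metrics

* **Gene RPK**: fragments overlapping the gene ± a 1 kb flank (any-overlap,
  ≥ 1 bp, like `bedtools intersect -c`), divided by the gene length in kb.
  The flank in the numerator with a gene-length denominator is asymmetric;
  we implement that definition literally and expose the flank as a
  parameter.
* **Density**: $\log_2(1 + \mathrm{RPK})$. The activity classifier uses a
  threshold of 4 on elongating-polymerase density, i.e. RPK 15. The
  threshold is conventionally quoted without strictness, so it is applied
  inclusively (density ≥ 4 is active) and exposed as a parameter.
* **Exon density**: exon count / gene length in kb, on the single supplied
  transcript model per gene.
* **GC percent**: $100 \cdot (\#G + \#C) / \mathrm{length}$; N bases count
  toward the length but never toward GC.
* **Nucleosome occupancy**: fragments of length ≥ 150 bp (nucleosome-sized)
  per kb of region, or per 1,000 GC bases (per kGC) to ask whether an
  exon/intron nucleosome contrast survives GC normalization.
* **eCLIP fold change**: IP fragment count / size-matched input count.

Metagene matrices summarize a track over genes × bins, strand-flipped so
the left edge is always 5′. The bin statistic is the mean of per-base
values (the `computeMatrix` default), never the sum. In scale-regions mode
the gene body is cut into `body_bins` near-equal spans with the remainder
spread over the leftmost (5′) bins; genes shorter than `body_bins` bp are
dropped, warned about, and recorded in the run manifest. Window bases that
fall off a chromosome end are missing, not zero, and are excluded from bin
and column means — zero-filling would fabricate depletion at chromosome
edges.

## Gene classification

**Occupancy classes.** Genes are clustered with k-means (k = 3) on the
scale-regions matrix of coverage-normalized signal (100 body bins, ±1 kb
flanks at 50 bp). Two numerical choices matter and were made after
observing failure modes on synthetic data:

1. *Log scaling.* Clustering operates on $\log_2(1+x)$ of the matrix. On the
   raw matrix the squared-error objective is dominated by the heavy-tailed
   high-occupancy genes: the global optimum splits the high tier in two and
   merges the low tier with the inactive tier, so no k-means variant can
   recover a three-tier structure. Log scaling stabilizes within-tier
   variance and makes the tier structure the optimum.
2. *Deterministic restarts.* `kmeans_pp()` is Lloyd's algorithm with
   k-means++ initialization; a single start can land in a poor local
   optimum, so 10 restarts (all derived deterministically from the seed)
   are run and the lowest within-cluster sum of squares wins. Results are
   reproducible across runs and platforms for a fixed seed. An emptied
   cluster is re-seeded from the point farthest from its assigned center.

The cluster with the highest mean becomes the high-occupancy class and the
remaining clusters merge into the low class (the analysis design calls for
a two-way split derived from k = 3, but not for a specific merge rule —
the highest-mean rule is this package's choice); ties in cluster means
break toward the larger cluster.

**Activity.** Density ≥ 4 (inclusive) on the elongating-polymerase track.

**RNase sensitivity.** A fully specified substitute for a negative-binomial
GLM differential test, chosen so results are reproducible from this
package alone: median-of-ratios size factors (genes with any zero count
excluded from the reference), fold change
$\log_2\frac{\bar n_T + 0.5}{\bar n_C + 0.5}$ on normalized means, a Welch
t-test on $\log_2(\mathrm{normalized}+0.5)$ across replicates,
Benjamini-Hochberg adjustment, and the label *sensitive* when
$\log_2\mathrm{FC} \le -1$ and adjusted $p < 0.05$ (the signal decreases on
sensitive genes). One caveat is worth stating plainly: with three
replicates per condition the Welch test has ~4 degrees of freedom, so even
a clean 4-fold decrease under realistic replicate noise (negative-binomial
dispersion 0.1, i.e. a ~32% biological CV) yields raw p-values around
10^-2^–10^-3^, and after multiplicity adjustment the test detects only a
minority of such genes. This is a real property of small-replicate designs,
not an implementation defect; detecting 4-fold changes reliably at these
settings would require either more replicates or a variance-moderated test.
The thresholds conventionally quoted for this comparison mix a positive
fold-change cutoff with genes described as *reduced*, and state the
p-value cutoff on an inverted scale; both look typographic. We implement
*reduced* = $\log_2\mathrm{FC} \le -1$ with raw $p < 0.05$ (before
adjustment) and document the choice rather than asserting it as anyone
else's.

**Quantile groups.** `quantile_split()` ranks values and assigns group
$\lceil r q / n \rceil$ with minimum-rank ties, so tied values share the
lower group and distinct values give groups within one of $n/q$. Constant
input (or any split leaving a group empty) is a degenerate-quantile error,
not a silent single group.

## Splicing-error classification

PSI event tables (rMATS-style: gene, event type ∈ {SE, MXE, RI, A5SS,
A3SS}, IncLevelDifference, PValue) are interpreted with ΔPSI oriented
**WT − KD**; the reader lets the caller declare the table's orientation and
flips on read when needed. Significance is strict: $p < 0.05$.

* Event-level error types: SE/MXE → exon inclusion, RI → intron removal,
  A5SS/A3SS → splice site.
* Gene exon class, over significant events: any SE with ΔPSI > 0 (higher
  inclusion in WT, so the exon is *skipped* upon knockdown) → skipped;
  else any SE with ΔPSI < 0 → included; else any MXE → MXE; else unchanged.
  Genes with no SE/MXE events are untested and excluded from denominators.
  The precedence *skipped > included > MXE* is a configurable default — the
  source's classes are disjoint but its tie rule is unstated.
* Gene intron class over significant RI events: ΔPSI < 0 (intron inclusion
  higher in KD) → retained; ΔPSI > 0 → removed.
* A5SS/A3SS events never affect gene classes; they count only in the
  event-level breakdown.
* All printed percentages use round-half-away-from-zero
  (`percent_round()`), the only rule consistent with every published
  count→percent pair.

Concordance between two cohorts is computed over genes tested in both:
among error genes of the first, the percent also erroneous in the second,
and symmetrically for no-error genes. The decile report splits genes into
FPKM deciles, tabulates percent-skipped and median $\log_2(1+\mathrm{FPKM})$
per decile and occupancy class, and compares expression between classes per
decile with the rank-sum test under Bonferroni correction (adjusted
threshold 0.01, the convention used for all group comparisons here).

## Statistical primitives

`mann_whitney()` is two-sided; with both groups ≤ 8 and no ties it uses
exact tail probabilities, otherwise the normal approximation with tie and
continuity corrections. The exact/approximate switch at n = 8 is where
enumeration stays trivially cheap. The continuity-corrected approximation
has a known worst-case absolute gap from the exact two-sided p of ~0.011 at
n = m = 8 (larger for smaller samples); the test suite pins that bound.
Bonferroni is $\min(1, pm)$; Benjamini-Hochberg is the standard step-up,
both via `stats::p.adjust`.

## What the synthetic generator emulates — and what it does not

`simulation_config()` fixes the study conditions; the defaults are chosen
once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| genome / genes | 1 chromosome, 5 Mb, 400 genes | every stage completes in minutes on one CPU; proportions below still give ≥ 50 genes per tier |
| class proportions | 0.15 / 0.35 / 0.50 high-active / low-active / inactive | mirrors the published 1,763 / 4,265 / 6,368 split |
| intronless fraction | 0.06 | ~793 of ~13,200 genes |
| exon length | normal(145, 20), ≥ 50 bp | vertebrate exons are ~140–150 nt |
| intron length | log-normal; shorter in high-occupancy genes | produces the higher exon density at similar gene length that distinguishes the high tier |
| GC | exon 0.55, intron/intergenic 0.40 | the exon > intron GC contrast |
| U2AF2 rates | 40 / 5 / 1 RPK by tier; exon enrichment ×3 | three distinguishable occupancy tiers; exon preference |
| polymerase rates | 70 / 50 / 0.3 RPK | active tiers clear the density-4 threshold; inactive genes stay far below |
| replicate noise | NB dispersion 0.1 | a typical biological CV (~32%) |
| gene spacing | ≥ 2.5 kb minimum gap | keeps ±1 kb counting flanks of neighbors disjoint, as in a real genome where genes are orders of magnitude sparser |
| RNase condition | rate ×0.25 on 3% of high genes | a planted 4-fold loss on a small sensitive subset |
| PSI events | depth 200, ΔPSI 0.4, 2 null SE per gene | planted events are detected with near-certain power; null p-values are calibrated by construction |
| planted error probabilities | skipped 0.37/0.20, included 0.10/0.06, MXE 0.07/0.04 (high/low) | reproduces the published error-rate contrast between tiers |
| cohort concordance | 0.65 error→error, 0.66 no-error→no-error | the published cross-cell-line agreement |

PSI p-values come from an explicit two-proportion z-test on binomial
inclusion counts, so planted significance is internally consistent; the
likelihood machinery of rMATS itself is not emulated. Skip probability
optionally rises with expression rank (default on) so the decile trend is
plantable.

The generator deliberately omits: sequence motifs (polypyrimidine tracts,
splice sites), read-level error models, multi-isoform transcript
structure, mappability and duplicate artifacts, chromosomal context
(speckle proximity, topological domains), and inter-gene correlation.
Passing tests on synthetic data therefore demonstrate that the *pipeline
arithmetic and classification logic* are correct under known truth — not
that the biological conclusions would survive artifacts absent from the
simulation.

## Degenerate inputs and edge rules

* Empty track → normalization error (no count mass to form fractions).
* Zero spike-in count → calibration error.
* Fragments beyond chromosome ends → error naming the offending record;
  flank clipping at chromosome edges, by contrast, is silent and logged.
* Constant values → quantile-split error; zero GC bases → per-kGC error.
* All-zero count rows → excluded from size-factor reference, p = 1.
* Annotation parsers name the offending line number; exon blocks must be
  sorted, disjoint, and inside the span.

## Problem sizes used by the shipped checks

The test suite exercises brute-force oracle comparisons on ≥ 200 random
toy genomes (≤ 10 kb), the full default bundle (400 genes, 5 Mb, one
seed) for planted-structure recovery, and ≥ 2,000 null events for
significance calibration; the pipeline smoke tests use a reduced 60-gene,
0.9-Mb bundle. These sizes are the package's own validation choices: large
enough that every tier has tens of genes and proportions are estimable to
a couple of percentage points, small enough to run interactively.

## Known limitations

* One transcript model per gene; exon ordinals and exon density depend on
  the supplied annotation row.
* The differential test's sensitivity at 3 replicates is modest (see
  above); it controls false positives well but under-detects.
* BAM parsing is out of scope: fragments arrive as BED3 (the format
  produced by standard paired-end post-processing).
* The high/low occupancy split treats a continuum as two classes; on real
  data the boundary is arbitrary, which is why the underlying densities
  and matrices are all exported.
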