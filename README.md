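# splicechrom

Quantify chromatin occupancy of splicing factors from CUT&RUN / CUT&Tag
fragments and classify splicing errors from PSI event tables.

The package is for computational biologists analyzing antibody-tethered
chromatin-profiling data of spliceosome components (U2AF2, U2AF1, SF3B1)
alongside knockdown RNA-seq splicing calls. It turns mapped fragment BED
files, a gene annotation, and rMATS-style PSI tables into:

* coverage-normalized and spike-in-calibrated signal tracks,
* per-gene and per-exon/intron occupancy metrics,
* gene classes (active/inactive, high/low gene-body occupancy,
  RNase-sensitive vs chromatin-bound),
* gene-level splicing-error classes with summary, cross-cohort concordance,
  and expression-decile reports,
* and a deterministic synthetic-data generator that plants every effect, so
  the whole chain is testable end to end without downloads.

## The quantities at the core

With per-base fragment coverage `c_b`, genome size `G`, and `T = Σ_b c_b`:

* **coverage normalization** — `v_b = (c_b / T) · G`, so uniformly
  distributed counts give `v_b = 1` at every base; enrichment reads
  directly as fold over uniform.
* **spike-in calibration** — raw counts scaled by `10,000 / (spike-in
  fragment count)` for cross-condition comparisons.
* **occupancy** — `RPK = fragments over gene ± 1 kb / gene length (kb)`;
  `density = log2(1 + RPK)`; genes with elongating-polymerase density ≥ 4
  are active.
* **feature metrics** — exon density (exons/kb), `%GC = 100·(G+C)/len`,
  nucleosome occupancy (≥150-bp fragments per kb or per 1,000 GC bases),
  eCLIP IP/input fold change, `log2(1 + FPKM)` expression scores.
* **occupancy classes** — seeded k-means (k = 3, k-means++ with
  deterministic restarts) on the log-scaled gene-body metagene matrix; the
  highest-mean cluster is the high-occupancy class.
* **splice classes** — with ΔPSI oriented WT − KD and `p < 0.05`: a
  significant SE event with ΔPSI > 0 marks a gene *skipped* upon
  knockdown, ΔPSI < 0 *included*, significant MXE events *MXE*; RI events
  with ΔPSI < 0 mark introns *retained*. Percentages round half away from
  zero.

## Worked example

Simulate a small cohort (60 genes on a 0.9-Mb chromosome) and run every
stage:

```r
library(splicechrom)
cfg <- list(seed = 11, bundle = "bundle", outdir = "out",
            simulate = list(n_genes = 60, chrom_length = 9e5))
report <- run_pipeline(cfg)
#> [simulate] bundle written to bundle (60 genes, seed 11)
#> [coverage] 10 sample track(s) + pooled track written
#> [occupancy] 60 genes quantified, 56 intron-containing in metagene matrix (0 dropped)
#> [classify] 30 active / 30 inactive; 8 U2AF2-high
#> [splice] 56 genes classified from primary PSI table
#> [report] written report.json / report.tsv (12 error genes of 28 tested)
```

The classify stage recovered all 8 planted high-occupancy genes and the
30/30 active/inactive split. The splice summary over the 28 active,
exon-tested genes:

```r
report$splice_summary$exon
#>       class count percent
#> 1 unchanged    16      57
#> 2   skipped    11      39
#> 3  included     1       4
#> 4       MXE     0       0
```

so 12 of 28 active genes (43%) carry exon-inclusion errors upon the
simulated knockdown, concentrated in the high-occupancy class; agreement
with the simulated second cohort is 67% for error genes and 75% for
no-error genes (`report$concordance`). Outputs land in `out/`
(`gene_classes.tsv`, `differential.tsv`, `splice_classes_*.tsv`,
`report.json`, bedGraph tracks, and a manifest with per-stage checksums).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/splicechrom.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/splicechrom.R", package="splicechrom"))')" \
    all --config run.yaml --seed 11
```

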