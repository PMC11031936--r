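# loopscape

Integrative downstream analysis of chromatin architecture for
comparative epigenomics: given the outputs of standard Hi-C and ChIP-seq
callers — chromatin loop lists (HiCCUPS-style BEDPE), TAD calls
(Arrowhead-style BED), A/B compartment eigenvector tracks (bedGraph),
CTCF peaks (ENCODE narrowPeak), methylation/coverage tracks (bedGraph),
gene models (BED12 or refFlat) and an FPKM expression table — loopscape
computes the comparative statistics a multi-cell-type study reports:

* **Loop/TAD architecture** — counts, mean/median sizes, per-chromosome
  breakdowns, long-range loop census (> 3 Mb), Mann–Whitney size
  comparisons with BH correction, and the four-way loop–TAD arrangement
  classification (*intra-TAD* / *inter-TAD* / *one anchor in TAD* /
  *not in TAD*, decided by anchor midpoints).
* **Compartments** — A/B labels as the sign of the eigenvector,
  gene→compartment assignment by the promoter largest-overlap rule
  (2 kb upstream / 500 bp downstream of the TSS, all isoforms kept,
  majority consensus per gene), `log2(FPKM + 1)` expression medians per
  compartment, and filtering of differential-compartment tables.
* **CTCF integration** — merged-event peak sharing between cell types
  (`percent shared = 100 · shared / union`), three-way Venn regions,
  loops classed by 0/1/2 CTCF-bound anchors, and methylation
  meta-profiles in ±5 kb around peak summits.
* **Promoter contacts and enrichment** — anchor annotation with
  promoter > exon > intron > intergenic precedence, promoter-contact
  gene sets (2 kb upstream / 100 bp downstream), three-way contact
  sharing, and hypergeometric over-representation analysis
  (`P(X ≥ k)` with BH adjustment) against GMT gene sets.
* **Expression × Pol II × CTCF cross-analysis** — top-100 expressed
  genes, longest transcript per gene, length-weighted mean gene-body
  signal per track, coding genes only.
* **A synthetic feature universe** — a seeded generator that plants
  TADs, loops, peaks, compartments, genes, expression and methylation
  with a ground-truth ledger, so every classifier above can be validated
  by exact recovery.

A configuration-driven runner (`run_pipeline()` / the `exec/loopscape`
script) executes all stages and writes deterministic TSV reports.

## Worked example

```r
library(loopscape)

truth <- generate_universe(sim_config(seed = 1), "universe")

loops <- read_loops("universe/loops_fib.bedpe")
tads  <- read_intervals("universe/tads_fib.bed", "bed3")
classify_all(loops, tads)
#>      INTRA      INTER ONE_ANCHOR NOT_IN_TAD
#>         60         25         10          5
```

The generator planted 60/25/10/5 loops per category
(`truth$loop_category_counts$fib`) and the classifier recovers the
census exactly.  Peak sharing between the two simulated cell types:

```r
sh <- classify_sharing(read_intervals("universe/ctcf_epi.narrowPeak", "narrowPeak"),
                       read_intervals("universe/ctcf_fib.narrowPeak", "narrowPeak"))
unlist(sh$result)
#>       n_shared    n_specific1    n_specific2          union percent_shared
#>          290.0           30.0           50.0          370.0           78.4
```

290 shared events are the 20 planted shared background peaks plus the
270 anchor-derived peaks (planted as shared); the 30/50 cell-specific
counts match the configuration.  Compartment-wise expression:

```r
genes <- read_genes("universe/genes.bed12")
bins  <- compartment_bins(read_intervals("universe/pc1_fib.bedgraph", "bedGraph"))
calls <- assign_gene_compartment(genes, bins)
expression_by_compartment(calls$genes,
                          read_expression("universe/expression.tsv"), "fib")$medians
#>    A    B
#> 5.09 3.23
```

Compartment A genes are more highly expressed (planted log2 means 5 vs
3; the `log2(FPKM+1)` pseudocount compresses the difference slightly).
The methylation meta-profile around CTCF peaks shows the planted dip,
baseline 0.8 dropping to 0.1 at the summit:

```r
prof <- metaprofile(read_intervals("universe/ctcf_fib.narrowPeak", "narrowPeak"),
                    read_intervals("universe/meth_fib.bedgraph", "bedGraph"), bin = 50)
prof[prof$offset %in% c(-5000, 0, 250), ]
#>     offset offset_mid mean_value n_contributing
#>      -5000      -4975        0.8            340
#>          0         25        0.1            340
#>        250        275        0.8            340
```

The same analyses run unattended from the generated configuration:

```sh
exec/loopscape run --config universe/pipeline_config.yaml
```

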