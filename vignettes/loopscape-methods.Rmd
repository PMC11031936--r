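---
title: "loopscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{loopscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

loopscape implements the downstream integration layer of a chromatin-
architecture study: it consumes the outputs of upstream callers — loop
lists (HiCCUPS-style BEDPE), TAD calls (Arrowhead-style BED), compartment
eigenvector tracks (bedGraph), CTCF peaks (narrowPeak), methylation and
ChIP coverage tracks (bedGraph), gene models (BED12/refFlat) and an FPKM
expression table — and computes the comparative statistics that sit
between those callers and a figure: loop/TAD size distributions, the
four-way loop–TAD arrangement census, A/B compartment assignment of genes
with expression comparison, CTCF peak sharing and CTCF-bound anchor
classes, methylation meta-profiles, promoter-contact gene sets with
over-representation analysis, and a top-expressed-gene × Pol II × CTCF
gene-body cross-analysis.  Upstream steps (alignment, contact-map
construction, loop/TAD/compartment/peak calling, motif discovery) are
deliberately out of scope; their outputs are inputs here.

## Coordinate model and the overlap engine

Every user-facing table uses BED conventions: 0-based starts, half-open
`[start, end)` intervals, plain data.frames.  One consequence is applied
uniformly: **abutting intervals do not overlap** — a peak ending at
position `x` does not touch an anchor starting at `x`.  Overlap queries
are delegated to GenomicRanges/IRanges internally; the 1-based conversion
happens in one private helper, so no off-by-one can drift through the
code.  `find_overlaps()` returns a deterministic ordering (query order,
then subject `(chrom, start, end, name)`), so every downstream tie-break
is reproducible.

## Loop–TAD arrangement classification

A loop's two anchors are fixed-width bins (callers typically emit 10-kb
bins); the loop size is the distance between anchor **midpoints**, which
stays well defined when anchor widths differ.  Containment of an anchor
in a TAD is likewise decided by the midpoint: anchors can straddle TAD
boundaries, and an any-overlap rule would let one anchor sit in two
adjacent TADs at once, breaking the partition property.  With the
midpoint rule the four categories —

* `INTRA`: one TAD contains both midpoints,
* `INTER`: each midpoint lies in a TAD but no TAD contains both,
* `ONE_ANCHOR`: exactly one midpoint lies in a TAD,
* `NOT_IN_TAD`: neither does —

partition any loop set exactly, which the test suite asserts on a
thousand random configurations.  Nested TADs are handled by an existence
quantifier: a loop inside both a child domain and its parent is `INTRA`,
with no need for a unique TAD assignment.  Because published figures do
not always state which containment rule was used, an
`containment = "overlap"` switch is available; midpoint is the default
and the documented behaviour.

Size distributions are compared with a two-sided Mann–Whitney U test
(normal approximation, tie correction) — the conventional choice for
heavy-tailed loop/TAD sizes — and per-chromosome families are
Benjamini–Hochberg adjusted.  Long-range loops are counted strictly
(`size > threshold`, default 3 Mb).

## Compartments and gene assignment

Compartment labels are the sign of the eigenvector value, exactly:
positive → A, negative → B.  A bin at exactly 0 is `unassigned` and
excluded from medians, because the sign rule is undefined there; no
magnitude threshold is applied.

Genes attach to compartments through their promoter, defined
strand-aware as 2 kb upstream / 500 bp downstream of the TSS.  The
promoter is intersected with the eigenvector bins and the
largest-overlap bin kept; ties go to the lower bin start (bins are
validated non-overlapping, so this is unambiguous).  All transcript
isoforms are assigned individually; the per-gene consensus is the
majority label, with ties resolved by the longest transcript and then
the lexicographically smallest transcript id — a deterministic reduction
from isoform-level calls to the gene-level medians that get reported.

Expression is transformed as `log2(FPKM + 1)`.  The pseudocount keeps
unexpressed genes finite and is the dominant convention; it also means a
planted difference of Δ in log2 means is recovered slightly compressed
(for means 5 and 3, the expected observed median difference is
`log2(2^5+1) − log2(2^3+1) ≈ 1.87`, not 2.0), which is why the recovery
tolerance is ±0.3 rather than something tighter.

## CTCF integration

**Peak sharing** uses merged-event semantics: both peak sets are merged
wherever they overlap by ≥ 1 bp (abutting peaks stay separate), and each
merged interval counts once, labelled `shared` when covered by at least
one peak from each set.  This is order-independent and well defined for
many-to-many overlaps; when peaks match one-to-one it reduces to the
familiar union arithmetic `shared / (n1 + n2 − shared)`, which is exactly
the printed-count worked example the acceptance script recomputes
(11,947 / (16,424 + 23,859 − 11,947) → 42.2%).  A `min_overlap` escape
hatch demotes marginally covered events for users who want a stricter
criterion than ≥ 1 bp.

**CTCF-bound anchors** count, per loop, how many anchors are overlapped
by ≥ 1 peak (`slack` bp of optional extension per side, default 0); the
class proportions over `{0, 1, 2}` always sum to one.

**Meta-profiles** average a signal track in offset bins tiling
`[-flank, +flank)` around peak centers (the narrowPeak summit when
present, else the interval midpoint).  Within a peak × bin window the
track records are averaged weighted by overlap length; across peaks the
per-peak means are averaged unweighted over peaks with ≥ 1 covered
record.  Bases with no record contribute **nothing** (they are not
zeros) — the bedGraph convention; users who want zero-fill can densify
their track first.  A constant track therefore yields the constant in
every covered bin, which is the weighting-correctness test.

**Cross-analysis** ranks genes by descending FPKM (ties by gene id),
keeps the top 100 by default, selects each gene's longest transcript
(ties by smallest transcript id), computes length-weighted mean signal
of each supplied track over the transcript interval, and optionally
drops non-coding genes after selection — so "20 non-coding among the
top 100" leaves 80 rows, not 100.

## Annotation and enrichment

Anchors are annotated with fixed precedence
**promoter > exon > intron > intergenic**; an anchor over a TSS window is
a promoter even when it also overlaps exon 1.  The promoter window for
contact annotation defaults to 2 kb upstream / 100 bp downstream —
narrower downstream than the compartment-assignment window, matching how
contact figures are typically drawn; both extents are plain arguments
because conventions differ between studies (1 kb upstream is also seen),
and no attempt is made to guess which produced any given published
figure.

Over-representation uses the upper-tail hypergeometric probability
`P(X ≥ k)` with BH adjustment across tested terms.  The universe
defaults to all genes in the supplied gene-model file; query genes
outside it are dropped with a warning, terms are intersected with the
universe, and terms empty after intersection are skipped rather than
reported at p = 1.  The tests pin the implementation to an exhaustive
binomial-coefficient tail sum to 1e-12 for universes up to 30 genes.

## The synthetic universe

`generate_universe()` plants a coherent toy data set in which every
downstream answer is known by construction, then writes it in exactly
the standard formats the pipeline reads.  It emulates the statistical
*structure* of real data — nested TADs, loops in all four arrangement
categories, CTCF peaks at anchors and in the background with controlled
sharing between two cell types, blocky ± eigenvector compartments,
promoters wholly inside compartment blocks, expression elevated in A,
methylation dips at peak centers, gene-body coverage proportional to
expression — without fitting any real genome.  Defaults: a two-
chromosome 80-Mb genome; log-normal TAD sizes with median 300 kb (the
few-hundred-kb scale typical of mammalian domain calls) tiled with
optional gaps; 10-kb loop anchors (the common calling resolution); 2-Mb
compartment blocks (megabase-scale, the A/B scale); expression log2
means 5 (A) vs 3 (B) with SD 1, giving the planted two-unit elevation in
A; methylation baseline 0.8 with linear dips of depth 0.7 and half-width
250 bp at peak centers, on a 50-bp CpG grid.

Construction details that make recovery *exact* rather than approximate:

* all planted peak centers and anchor midpoints sit on the 50-bp CpG
  grid; peak centers are ≥ 1 kb apart, so merged-event and one-to-one
  sharing semantics coincide;
* anchor midpoints are ≥ 12 kb apart across both cell types, and
  background peaks keep ≥ 7 kb from every anchor midpoint, so a peak can
  never accidentally bind another loop's anchor;
* anchor-derived CTCF peaks are planted as *shared* between the two cell
  types (CTCF binding is largely cell-invariant at structural sites);
  background peaks carry the configured
  `{epi_only, fib_only, shared}` counts;
* gene promoters sit wholly inside one compartment block; the optional
  `boundary_genes` plant promoters that straddle a block edge and are
  the only genes the assignment may mislabel;
* methylation is emitted only within ±6 kb of peak centers.  Because
  meta-profile means are taken over covered records only, this changes
  nothing downstream while keeping files small.  With the 50-bp grid and
  on-grid peak centers, a 50-bp profile bin at offset 0 contains exactly
  the dip minimum, so the planted `baseline − depth` is recovered
  exactly; a 100-bp bin would mix in the 50-bp neighbour and read ≈ 0.07
  high — the tests therefore profile methylation at `bin = 50`.

What the generator does **not** emulate: real contact matrices or
ligation noise, sequence composition, replicate variability, irregular
CpG density, overlapping genes, or correlated placement of TADs and
compartments.  Passing the recovery tests therefore demonstrates that
the *classification and summarisation logic* is correct under the stated
conventions, not that any particular biological dataset would be
reproduced.

A single integer seed drives all randomness; the same seed yields
byte-identical files, and the ground truth (`truth.json`) maps every
emitted record to its planted label.

## Pipeline and determinism

`validate_config()` resolves a YAML configuration: unknown keys are
errors, every referenced file must exist, parameter defaults are filled
(promoter windows 2000/500 for compartments and 2000/100 for contacts,
3-Mb long-loop threshold, 5-kb flank with 100-bp bins, top-100 coding
cross-analysis, α = 0.05), and stages are enabled from the inputs
present.  `run_pipeline()` executes the enabled stages, writes each
output table with a header and a provenance comment line, counts every
warning into the report (never silently), retains partial outputs when a
stage fails and then exits with an error.  No timestamps enter any
output, so identical configs and inputs produce byte-identical tables —
asserted by the test suite and the acceptance script.

Problem sizes used by the shipped tests and the acceptance script — a
two-chromosome toy genome of 80–96 Mb, 100 loops and ~350 peaks per
cell type, 400–1,000 genes — were chosen as the smallest sizes at which
every planted structure (nesting, all four loop categories, both
sharing classes, 500 genes per compartment for the expression check)
occurs in comfortable numbers; the full suite runs in under two minutes
on one CPU.

## Known limitations

* bedGraph only, no bigWig; no `.hic`/cooler parsing; no liftover.
* Differential-compartment tables are consumed, not recomputed: the PCA,
  sign correction and Mahalanobis statistics of tools like dcHiC are out
  of scope.
* The ORA machinery is generic; reproducing any published GO p-value
  additionally depends on the annotation release and background used
  there.
* BED12 gene files carry no gene id; the reader derives it by stripping
  a trailing `.<n>` isoform suffix from the name, which matches the
  generator's convention — use refFlat input when gene symbols are
  explicit.
* Loop midpoints falling exactly on a TAD edge follow the half-open
  rule: the start is inside, the end is not.
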