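---
title: "Methods: the overlap association workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the overlap association workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomicOverlaps)
```

# The problem

Candidate regions from omics experiments — differentially expressed
genes, ChIP peaks, methylation windows — acquire biological meaning
through the annotations they overlap: transcription factor binding sites
(TFBS), CpG islands (CGI), promoters. This package implements that
association step as a deterministic pipeline: ingest region files,
normalize them into one coordinate model, compute parameterized
query–subject overlaps, and summarize, profile and visualize the hits.

# Coordinate model

Internally every interval is **1-based and closed** (GFF convention), so
width is uniformly `end − start + 1` and a single base is `[x, x]`.
BED's 0-based half-open intervals are shifted on read
(`start + 1, end`) and shifted back on write; GFF3/GTF coordinates are
taken verbatim; delimited tables declare their convention in a
`columnMap()`. This choice keeps all interval arithmetic free of ±1
case analysis, and the BED round trip (`readBed` → `writeBed` →
`readBed`) is asserted bit-stable in the tests.

Strand `"*"` means *unstranded* and is deliberately **compatible with
both orientations** in strand-specific operations: annotation tracks
such as CGIs carry no strand, and requiring strand equality would
silently drop all of their hits. Genome builds are compared only via
their metadata labels — `validateWorkspace()` warns on label or
naming-style mismatches but never lifts coordinates over, because no
reliable liftover is possible from coordinates alone.

Chromosome-name normalization translates only the canonical chromosomes
(`1..n`, `X`, `Y`, `MT` ↔ `chr*`, `chrM`). Scaffolds and haplotype
contigs have no 1:1 cross-dialect mapping, so they are kept verbatim
with a warning, which keeps the operation lossless.

Duplicate removal keys on `(chromosome, start, end, strand)` and ignores
name and score: duplicated rows in annotation dumps typically differ
only in metadata while describing one physical interval. The first
occurrence wins, preserving input order and hence region indices.

# The hit rule and its parameters

For query *q* and subject *s* on one chromosome, with intersection
width `w_ov = min(e_q, e_s) − max(s_q, s_s) + 1`, a hit requires:

* `w_ov ≥ minOverlap` — default **1 bp**: a hit is an overlap of at
  least one nucleotide base. Raising it filters glancing contacts.
* type — `any` (default; partial overlaps count), `within`
  (*q* entirely inside *s*), `equal` (identical interval). "Complete"
  overlap is directional; this package fixes it as
  *query-inside-subject*, since the query is the user's region of
  interest, and the reverse containment is obtained by swapping roles.
  `minOverlap` applies to every type (the parameters are orthogonal).
* strand compatibility — ignored by default; when enforced, strands
  must be equal or either must be `"*"`.

Each hit records the intersection interval and the overlapped fractions
`w_ov / w_q` and `w_ov / w_s`, so `fracQuery == 1` exactly characterizes
containment. Hits are reported once per (query, subject) index pair and
sorted by those indices, making all downstream tables byte-stable.

## Engine design

`findRegionOverlaps()` sorts the subjects of each chromosome by start
and, per query `[a, b]`, locates the candidate window by two binary
searches: subjects with `start ≤ b − minOverlap + 1` and, using the
widest subject width `W_max` as a bound, `start ≥ a + minOverlap −
W_max`. Candidates are then filtered exactly. This is
`O((n+m)·log m + candidates)` and degrades gracefully when subject
widths are heterogeneous (the pruning bound loosens with `W_max` but
correctness never depends on it). `bruteForceOverlaps()` evaluates the
rule on every pair and is the reference semantics; the acceptance suite
asserts field-level identity on 20 randomized 1,000×1,000 instances
across all 18 parameter combinations, and a separate test cross-checks
index pairs against `GenomicRanges::findOverlaps` as an external
reference implementation.

# Strand-aware resizing

`resizeRegions()` anchors at the TSS (`start` for `+`/`*`, `end` for
`-`), the TES (mirror), or the whole body. The anchor base counts as
position 0 and **is included by default**, so `upstream = U,
downstream = D` yields width `U + D + 1`; the inclusive convention is
this package's documented choice, since "U bp upstream of the TSS" does
not by itself fix inclusivity. `includeAnchorBase = FALSE` is defined
only for one-sided windows (strictly upstream or strictly downstream,
width `U` or `D`); excluding an interior base from a two-sided window
would split the interval and is rejected. Unstranded regions anchor
like `+` with a one-time warning. Coordinates are clipped to
`[1, chromSize]` when sizes are supplied and to `[1, ∞)` otherwise
(no genome file is required); regions emptied by clipping are dropped
with a warning rather than silently kept as artifacts.

# Summaries

Per-query hit counts are summarized as minimum, lower quartile, mean,
median, upper quartile and maximum. Quartiles use linear interpolation
between order statistics — at probability *p*, `h = (n−1)p + 1`, value
`x⌊h⌋ + (h−⌊h⌋)(x⌊h⌋₊₁ − x⌊h⌋)` — i.e. `stats::quantile()` type 7. The
definition is stated explicitly so ports in other ecosystems can match
it; it is hand-verified in the tests (`[0,1,4,30]` → 0.75 and 10.5).
Both the mean and the median are always emitted, since either may be
the headline statistic of a comparison.

Histograms default to one bin per integer count up to a maximum of 50,
then fall back to 30 equal-width bins — readable for the sparse counts
typical of gene–TFBS runs without exploding for heavy-tailed ones.
Custom edges define `[e_i, e_{i+1})` bins with the last bin closed, must
be strictly increasing, and must cover the data (so frequencies always
sum to the number of queries).

# Binned coverage profiles

Every query body is split into `nBins` (default 100) equally sized bins
with the floor rule `bin_i = [s + ⌊(i−1)W/n⌋, s + ⌊iW/n⌋ − 1]`, which
tiles the region exactly with widths differing by at most 1 bp. Three
deliberate choices:

* **A subject element counts once in every bin it touches** (≥ 1 bp),
  not fractionally and not once per region. Per-bin presence is the
  simplest rule that reproduces edge-enrichment shapes (e.g. gene–gene
  overlaps concentrating at gene starts and ends) and keeps the matrix
  integer-valued.
* **Queries shorter than `nBins` bases are dropped** (and counted):
  `nBins` non-empty equal bins cannot tile a shorter region. Padding
  would fabricate positions that do not exist.
* **Bins are reported 5′→3′**: for minus-strand queries the bin order
  is reversed so bin 1 always starts at the TSS. This is on by default
  (`orient = TRUE`) and switchable, and the row-reversal symmetry under
  strand flip is asserted as a property test.

Coverage uses the same `OverlapParams` as the main engine — one overlap
semantics everywhere.

# What the synthetic generators emulate

`generateRegionSet()` draws regions uniformly (chromosome ∝ length,
uniform start and length) — the null background for engine correctness
tests. `tileRegionSet()` lays non-overlapping fixed-width "gene bodies"
end to end, so that elements placed *inside* a region by
`generateSubjectsFor()` overlap exactly their host: the per-query
Poisson(rate) counts returned by the generator are then the exact truth
for parameter-recovery tests. The 5′ bias option draws the element
offset with linearly decaying density `f(x) = 2(1 − x)` along the body
(strand-aware), emulating TSS-proximal clustering of regulatory
elements.

Two distributional facts shape the recovery tests, both derived before
testing: (i) the mean of 2,000 Poisson(4) counts has standard error
`√(4/2000) ≈ 0.045`, so the recovered mean must land within 3 SE of 4;
(ii) under uniform placement of **single-base** elements each of the
100 bins is a Binomial(T, 1/100) total, so every bin must lie within
4·√mean of the mean (a ≥99% bound jointly over 100 bins). Single-base
elements are used for the flatness fixture deliberately: elements of
finite length confined to the region body are geometrically depleted at
the two edge bins (an element of length L can intersect an interior bin
from `binWidth + L − 1` start offsets but an edge bin from fewer), so a
"flat" expectation is only true at L = 1. The fixtures do **not**
emulate GC content, repeat structure, clustered annotation families, or
inter-region correlation — passing these tests demonstrates engine and
statistic correctness, not realism of any biological conclusion.

Problem sizes throughout (1,000×1,000 oracle instances, 2,000-region
recovery fixtures, 100-bin profiles) were chosen as the smallest scales
at which the asymptotic engine and the statistical bounds are
meaningfully exercised; all generators are pure functions of their seed.

# Degenerate inputs and tie-breaks

Empty subject sets yield empty hit tables, not errors; empty histograms
and summaries of empty count vectors are errors (there is no meaningful
statistic). Inverted BED intervals and sub-3-column lines fail with
their line number. Ties in sorting never occur because the
`(queryIndex, subjectIndex)` key is unique by construction. Pipeline
runners delete partial outputs on failure so a run directory is either
complete or empty.

# Known limitations

* No nearest-neighbor or distance queries, no overlap *enrichment*
  statistics (permutation tests) — hit finding and description only.
  Comparing count distributions between gene sets (e.g. a rank-sum
  test) is left to the user on the exported counts.
* No liftover; build mismatches are only warned about.
* Coverage is presence-based; no base-pair pileups, no length
  normalization, no flanking-window metagene extension.
* Track plots are static (PNG/PDF) by design; interactive exploration
  is delegated to the UCSC browser via `ucscUrl()`.
* Applying the workflow to public annotation releases (gene sets vs a
  TFBS database filtered to one factor) requires downloading those
  files locally; the package deliberately performs no network access,
  so such analyses are recipes (`scanDirectory()` + `subsetRegions()` +
  `runOverlap()`) rather than built-ins.
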