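---
title: "samforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{samforge: methods and design notes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samforge)
```

This vignette explains the models and procedures behind `samforge`, the
assumptions they make, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## The phased, single-pass engine

A SAM preparation pipeline is a composition of two kinds of operations:
*per-record filters* (keep/remove/transform decisions that may not depend
on neighbouring records) and *whole-set operations* (sorting, duplicate
marking, recalibration tabulation). `samforge` executes any requested
combination in three phases over a single read of the input:

1. **Phase 1** — filters applied while parsing: target-region filter,
   unmapped-read filter, header rewrites. Surviving records are collected
   into the in-memory `SamFile`.
2. **Phase 2** — whole-set operations, in the fixed canonical order
   *sort → duplicate marking (+ optical) → recalibration tabulation*.
   Tabulation must run after marking because it skips duplicate-flagged
   reads.
3. **Phase 3** — steps applied while writing: recalibration application,
   duplicate removal, metrics emission.

`buildPlan()` derives this structure as a pure function of the option
*values*, so any permutation of the options yields an identical plan, an
identical `@PG` provenance line, and an identical output file.

The per-record independence contract is what makes the engine
parallelizable in principle: phase-1/3 filtering is performed on
contiguous shards of the record table (the `workers` option) and
recombined by concatenation, which is deterministic by construction. At
the scale this package targets the sharding is an executable statement of
the contract rather than a throughput device; results are verified
byte-identical for any worker count.

### Deterministic mode and tie-breaking

Duplicate survivor selection can tie (equal keys *and* equal quality
scores). In deterministic mode ties resolve by the record's ordinal in
the current record order. Three properties follow:

* for a freshly parsed file this ordinal **is** the original file index,
  so repeated runs are byte-identical and comparable with `diff`;
* when marking runs after the in-memory sort, the ordinal equals the
  ordinal the record would have if the sorted file were written and read
  back — so the fused pipeline is byte-identical to running the steps as
  separate chained invocations through intermediate files;
* within an `sfm` chunk, the class-local relative order equals the
  global sorted order (classes never span chunks), so all execution
  shapes agree.

Non-deterministic mode is permitted to pick any tied member; this
implementation simply uses the same rule.

## Duplicate marking

Reads are grouped by *library* (`RG` tag → header `@RG LB`; reads without
one fall into `"Unknown Library"`) and by *adapted position and
orientation*: the 5′ alignment coordinate after undoing soft and hard
clips. Pairs (both ends mapped, primary) are keyed by both ends after
canonically ordering them by (contig index, unclipped position, strand),
which makes the key invariant under swapping mate roles. Mapped primary
reads that are unpaired, mate-unmapped, or whose mate is missing from the
file (reported with a warning) form fragment classes on the single-end
key. A fragment whose key matches *any* pair-class end is marked
duplicate regardless of score — pairs beat fragments. Survivors maximize
the sum of base qualities ≥ 15; the threshold and the
pairs-beat-fragments rule are Picard MarkDuplicates defaults, adopted so
marking decisions agree with the established tools. Secondary,
supplementary and unmapped records are never examined and never
rewritten.

### Optical duplicates

Within each pair-duplicate class, members are *optically linked* when
they share a read group and tile and both pixel offsets are at most
`opticalPixelDistance` (default 100; a per-axis rectangle test, with a
Euclidean option for experimentation). Optical clusters are the
transitive closure of links; each cluster contributes its size minus one
to `READ_PAIR_OPTICAL_DUPLICATES`. Physical locations come from the read
name: split on `:`, and if at least five fields remain and the last three
parse as integers, they are (tile, x, y); anything else never links.

### Metrics and library size

`PERCENT_DUPLICATION = (UPD + 2·RPD) / (UPE + 2·RPE)` over unpaired and
pair counts. `ESTIMATED_LIBRARY_SIZE` solves the saturation equation
`U = X(1 − e^{−N/X})` with `N` = pairs examined − optical duplicates and
`U` = pairs examined − pair duplicates, by bisection to relative
tolerance 1e−9; it is undefined (blank in the report) when no
duplication, or nothing, was observed. The metrics file is structurally
Picard's (a `## METRICS CLASS` section, tab-separated, six decimals on
the duplication fraction), which is the layout MultiQC consumes.

## Base quality score recalibration

### Covariates

Each tabulated base is binned by read group, reported quality, **cycle**
(1-based position in sequencing order: reversed for reverse-strand
alignments, negated for second-of-pair reads) and **context** (the `k`
preceding bases in sequencing orientation, reverse-complemented for
reverse-strand reads; `contextSize` default 2). At the first `k` cycles
the context is the shorter available prefix (possibly empty). This choice
keeps an exact invariant: every tabulated base falls in exactly one bin
at every level, so parent counts equal the sum of their children's — a
property the test suite asserts. Contexts containing N would be binned by
their literal string; the generator never produces them, and real-data N
bases are excluded earlier because only unambiguous base/reference pairs
are counted.

### Tabulation

Only aligned bases (CIGAR `M/=/X`) of usable records count: records that
are duplicate-flagged, secondary, supplementary, unmapped or MAPQ 0 are
skipped, as are records with `*` quality strings (a policy switch; the
alternative is an error). Known polymorphic sites are masked so true
variants are not counted as machine errors; a site's mask spans its full
REF footprint (a deletion allele masks every covered position), with the
POS-only alternative available by constructing the `KnownSites` object
with unit spans. Masking is applied before counting, so removing the
known-sites input changes observation counts by exactly the number of
masked aligned bases — another asserted invariant.

### Empirical quality and deltas

A bin with `n` observations and `e` mismatches gets the integer
`Q ∈ [0, 93]` maximizing

  log N(Q; prior, σ) + log Binom(e | n, 10^(−Q/10)),

with σ = 0.5 Phred (default) and the prior centred on the parent level's
estimate; with zero observations the prior centre passes through
unchanged, and likelihood ties resolve to the lowest Q. Deltas are the
level-by-level corrections: global (per read group, against the
count-weighted mean reported quality), per reported quality, and per
cycle/context. Two numerical choices matter:

* deltas are stored **rounded to four decimals** — the precision of the
  `.recal` report — so applying a table from memory and applying the same
  table after a write/read cycle give identical output;
* the global level stores the exact integer *sum* of reported qualities
  rather than their mean, so per-chunk tables in `sfm` mode reduce to
  bitwise the same global table as a whole-file tabulation (integer sums
  are exact in doubles at any realistic scale; means are not).

One modelling consequence worth knowing: on perfectly calibrated data
with a *mixture* of reported qualities, the global delta is legitimately
non-zero (the empirical quality of a rate mixture is below the mean
reported quality) and is compensated by the per-quality deltas; the
"deltas vanish" property is a per-bin statement, which is how the tests
phrase it.

The prior width interacts with bin occupancy: with σ = 0.5 a cycle bin
needs on the order of 10⁴ observations before its posterior mode can move
within ±1 Phred of a large injected effect. The recovery experiments
therefore concentrate observations (one read group, one reported quality,
30 bp reads, 8000 pairs ≈ 4.8·10⁵ bases) rather than spreading the same
base count across many sparsely populated bins.

### Application

Every record — including duplicates and unmapped reads; the skip list
governs tabulation only — has each base with reported quality ≥
`preserveBelow` (default 6) rewritten to the rounded sum of its deltas,
clamped to [1, 93]. A base whose sub-bin is missing falls back to the
deltas of its deepest available ancestor; reads from a read group absent
from the table pass through unchanged. Optional quantization snaps
recalibrated qualities to levels learned by a deterministic
one-dimensional k-means (quantile seeding, Lloyd iterations); it is off
by default.

## Split-filter-merge mode

`splitByRegion()` routes each record to exactly one chunk: its contig's
group (default: one group per contig) if its mate, when mapped, is in the
same group; otherwise — spanning pairs (both mates) and unmapped reads —
the shared overflow chunk. This keeps every pair class and every fragment
class wholly inside one chunk. The one cross-chunk interaction is the
pairs-beat-fragments rule: a cross-contig pair lives in the overflow
chunk while a colliding fragment lives in a contig chunk. The engine
therefore shares the set of pair-end keys across chunks before fragment
resolution — the sequential analogue of a shared concurrent hash table —
and mode equivalence holds exactly; a dedicated test constructs this
collision.

Per-chunk recalibration tables are reduced (summed) into one global table
before deltas are computed; application and the remaining phase-3 steps
run on the merge pass. The merge itself concatenates the sorted chunks
and orders by the global sort key with the original file ordinal as
tie-break, which equals a k-way merge and reproduces the filter-mode
order exactly. Chunk SAM files are materialized under a scratch directory
when one is given (reused if a previous interrupted run left it behind,
removed on success); record identity across the scatter is carried by the
in-memory ordinal.

## The synthetic data generator

`simReads()` emulates the features the engine's algorithms key on:
multi-contig paired-end layouts with soft-clip variation on planted
PCR-duplicate groups (so raw positions differ but adapted positions
match), flow-cell coordinates with controlled chain geometry for optical
clustering, per-quality error rates of exactly 10^(−q/10) with an
optional per-cycle boost, known sites (SNPs and 2-base deletion alleles)
carrying alternate alleles, cross-contig pairs, mate-unmapped pairs,
unmapped singletons, secondary records and MAPQ-0 reads. Its truth tables
are computed in "generator space" — from the planted origins, scores and
coordinates rather than through the engine's CIGAR/flag machinery — and
account for accidental key collisions between independently placed reads,
so they are usable as independent oracles.

What it does **not** emulate: indels in CIGARs (aligned reads are pure
match/soft-clip; the engine's CIGAR arithmetic over I/D/N is covered by
hand-built cases instead), N bases, ambiguous references, adapter
read-through, GC- or context-dependent error structure, and realistic
quality-score autocorrelation. Passing tests on this generator therefore
demonstrate the engine's combinatorial correctness (keys, classes,
clusters, counts, determinism) and its statistical behaviour under a
known error model — not robustness to every artifact of real sequencers.

Default study conditions: 300 pairs of 100 bp reads over three contigs
(12/9/7 kb), fragment lengths 180–320, 15 duplicate groups of 2–4 copies
with clips 0–4, 12% unpaired fragments (a quarter planted on pair ends),
5% cross-contig pairs, 3% mate-unmapped, 4% unmapped singletons, 2%
secondary, 2% MAPQ 0, qualities {20, 25, 30, 35}, 40 known sites (25%
deletion-allele), 4 tiles with a 40-pixel chain offset. Equivalence and
oracle suites run many seeds at 40–500 records; the recalibration
recovery experiments use the concentrated design described above. These
sizes keep the default test run in the tens of seconds while leaving
every statistical check comfortably powered.

## Known limitations

* SAM text only; BAM/BGZF and CRAM are compression/container layers out
  of scope, as is alignment itself.
* Queryname sorting is byte-lexicographic, not Picard's numeric-aware
  "natural" order; the comparison recipe sorts both sides with this same
  function, so the choice cancels out.
* The `.recal` report is this tool's own stable dialect
  (GATKReport-inspired); its contract is read/write identity and
  run-to-run byte stability, not byte compatibility with another tool's
  report writer.
* Mate rescue in the region filter (keeping a read whose mate overlaps a
  target) is not performed.
* Indel recalibration (insertion/deletion qualities) is not implemented;
  the model covers base mismatches only.
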