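---
title: "Diagonal partitioning of gapped-extension workloads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagonal partitioning of gapped-extension workloads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(diagpart)
```

## The problem

Seed–filter–extend aligners hand their gapped-extension stage a stream of
*segment files*: plain-text lists of high-scoring ungapped pairs (HSPs),
one file per square chunk of the target x query alignment matrix. Each
file is processed by one single-threaded extension job. Chunks are equal in
*area* but wildly unequal in *work* — an HSP count per chunk can span five
orders of magnitude — so a handful of dense chunks dominate the wall clock
while every other core idles. This is a classic tail-latency problem: it
cannot be fixed by adding cores, only by bounding the size of the largest
job.

Bounding job size means splitting oversized segment files, and the naive
ways of doing that (cutting the record list in row order, or blocking the
matrix) are not free. The extension engine starts each job from a single
point per HSP, the *anchor*, and suppresses any anchor that a previous
extension in the same job has already crossed. Split two such anchors into
different jobs and neither job knows about the other: both anchors extend,
and the output gains duplicate and extra — *straddling* — alignments.

## Diagonal partitioning

Alignments extend along dot-plot diagonals: a forward-strand alignment
follows a locus of nearly constant $d = t - q$ and a reverse-strand
alignment nearly constant $d = t + q$, with only small vertical and
horizontal excursions at gaps. Anchors that one extension can cross —
anchors on the same alignment — therefore share a diagonal, up to gap
drift. `partition_by_diagonal()` exploits this:

1. reduce each HSP to its anchor, approximated by the floor midpoint of
   its target and query intervals (computing the engine's true optimal
   anchor point would require scoring every HSP during partitioning);
2. key each anchor with $d = t_{mid} - q_{mid}$ on `+` and
   $d = t_{mid} + q_{mid}$ on `-`;
3. per strand, sort anchors by `(diag_key, target_mid, query_mid, input
   order)` and cut the sorted run greedily into partitions of at most
   `max_size` records.

Every partition is a contiguous diagonal band; same-strand bands never
interleave, so dependent anchors land in the same extension job except
where more anchors share a diagonal neighbourhood than `max_size` allows —
the hard cap always wins, and a residual straddle near a band boundary is
accepted. The row-wise baseline, `partition_rowwise()`, is the same greedy
cut over `(target_mid, query_mid)` order; it exists purely as the
comparison arm.

A single pass of greedy cutting is used rather than recursive halving:
under a hard cap both produce bands of at most `max_size` covering the
same sorted order, so the results are interchangeable and the single pass
is simpler to reason about.

## Choosing the cap

The best `max_size` depends on genome size, similarity and core count.
Rather than ask the user to guess, the adaptive policy
(`size_policy("adaptive")`) tracks the pre-split sizes of segment files
seen so far and uses their upper quartile as the current cap. The quartile
is the nearest-rank order statistic `sort(h)[ceiling(0.75 * n)]` —
integer-valued, like the record counts it summarises, and matching
`stats::quantile(type = 1)`. Until the first file is observed the policy
falls back to `default_max` (20 000 records). The history lives in the
policy object and is threaded through `split_segment_file()` calls;
`size_policy_from_dir()` can seed it by scanning a folder of existing
segment files, reproducing a shared output folder acting as an implicit
size registry, but as an explicit object the behaviour is deterministic
and testable. The recorded size is the parsed record count — the file is
read anyway to partition it — while the *split decision* uses the cheap
byte-ratio estimate (`estimate_line_count()`: file bytes over
first-data-line bytes, floor division), which never requires reading a
file that will pass through whole.

## Bin packing and the keg

Running several aligner instances side by side needs the genomes split
*across* chromosomes into bins of similar total length; splitting a
chromosome in half would both create straddles at the cut and force
coordinate remapping. `lpt_pack()` applies longest-processing-time-first
(sort decreasing, assign to least-loaded bin, ties to the lowest index),
which is within $4/3 - 1/(3m)$ of the optimal makespan;
`pack_to_capacity()` derives the bin count from a target capacity
(production-scale practice is ~200 Mbp per bin) by ceiling division.

The partition files plus their extension commands travel as a *keg*
(`write_keg()`): a gzipped tar with `partitions/`, `commands.txt` (exactly
one command per partition, in plan order) and `manifest.tsv`. This is the
hand-off boundary between the seeding half and the extension half of the
pipeline, which may run on different machines. `run_batch()` executes the
commands on a worker pool; every command writes to its own file on disk
(no pipes, so a slow consumer can never backpressure a producer) and the
per-command outputs are concatenated in command order with MAF-header
deduplication, making the final output byte-identical for any worker
count. An optional `nice` increment on `shell_executor()` lowers the
batch's scheduling priority so extension work does not starve other
processes; being OS-dependent it is not exercised by the test suite.

## The toy aligner

Partitioning quality is only measurable against an extension engine that
reproduces the suppression dependency. The package ships a small,
self-contained one:

* `simulate_pair()` builds a target core of i.i.d. bases and derives the
  query core by substitutions at the stated divergence (always to a
  different base) and indels (insertion or deletion with equal
  probability, lengths uniform on 1–5 bp) at a per-base rate of 1%, then
  adds independent random flanks of 1000 bp to each end of both
  sequences. The flanks bound every alignment; the indels scatter the
  homology across many diagonals. Both indel directions and uniform
  random flanks are this package's choices where the construction allowed
  alternatives.
* `find_seeds()` reports every exact k-mer match in both query
  orientations (the CPU stand-in for a GPU seeder — partitioning
  behaviour depends only on the resulting HSP set, not on how fast seeds
  were found).
* `ungapped_extend()` grows a seed gap-free in each direction until the
  running score drops `x_drop` below that direction's maximum, keeping
  the best-scoring span; extensions below `hsp_thresh` are discarded.
* `gapped_extend()` extends each record's anchor with banded affine-gap
  dynamic programming in both directions (implemented in C++), pruning a
  band row once its best score falls `y_drop` below the running maximum,
  and suppresses every pending same-strand anchor whose midpoint lies on
  an aligned column of a produced alignment.

Defaults (`score_model()`): HOXD70 substitution scores, gap open 400 /
extend 30, `k = 12`, `x_drop = 300`, `y_drop = 3000`, `hsp_thresh = 3000`
— the magnitudes used in practice for distant-vertebrate alignment, all
configurable. The chunk side defaults to 10 kb in the toy pipeline, the
desk-scale analogue of the production 10 Mb interval.

Numerical choices that pin down determinism:

* midpoints use floor on both axes (integer coordinates, no rounding
  rule needed beyond that);
* DP tie-breaking prefers the diagonal move, then the horizontal
  (query-consuming) move, then the vertical, identically in the forward
  and backward passes — differing tie-breaks between the two passes are
  themselves a source of extra alignments, so the toy engine uses one
  rule everywhere;
* a gap of length $L$ costs `gap_open + L * gap_extend`, and every
  alignment's stored score is exactly reproducible from its column runs
  (`score_alignment()`, asserted as an integer identity in the tests);
* partition tie-breaks (`diag_key`, then `target_mid`, then `query_mid`,
  then input order) make partition plans a pure function of the record
  list.

Degenerate inputs are defined rather than accidental: empty record sets
produce empty partition lists and empty MAFs; a single-base HSP anchors at
that base; anchors outside an extension window raise an error naming the
record; an empty adaptive history falls back to the default cap.

## What the experiments show — and what they cannot

`evaluate_strategies()` runs the whole loop on one pair: seed, filter,
tile into chunks, split each chunk's records under each strategy, extend
each partition independently, and count straddling (target columns covered
by more than one partition of the same chunk and strand, overlapping
cross-partition pairs, output bytes). On simulated single-locus pairs
(100 kb core, 2% divergence) diagonal partitioning matches or beats the
row baseline at every cap in the sweep {10, 25, 50, 100}; on rearranged
multi-block fixtures with duplications — where row stripes genuinely cut
alignments apart — it is strictly better on every measure. The
unpartitioned run defines the zero-straddling floor, and any strategy with
`max_size = Inf` reproduces it exactly, which is the package's core
correctness contract.

The simulator emulates divergence, short indels and unrelated flanking
context. It does not emulate repeat families, low-complexity sequence,
large-scale inversions within a locus, or the HSP densities of real
multi-gigabase chunks, so a passing suite demonstrates the *mechanism*
(dependency-preserving partitioning, bounded job sizes, deterministic
batching) and the *direction* of the row-vs-diagonal comparison — not
production wall-clock behaviour, which depends on hardware and on the real
aligner's constant factors. Claims about optimal cap values on real
genomes are likewise out of reach at desk scale and are not asserted.

Problem sizes in the test suite are chosen to exercise every code path at
interactive cost: cores of 3–100 kb, 1000-file partition sweeps, LPT
instances small enough ($n \le 10$, $m \le 3$) for an exhaustive
assignment oracle, and DP oracle pairs of at most 200 bp where the full
unbanded affine-gap matrix is computable in R.

## Command-line use

One entry point with subcommands (`exec/diagpart`) covers the pipeline:
`simulate`, `seed`, `partition`, `keg`, `run-batch`, `evaluate`. The keg
boundary keeps the two halves separable even though they share a binary;
`--config file.ini` mirrors the flags, explicit flags win, and every run
drops a `run_config.json` with the resolved configuration, seed and
package version. The command template stored in a keg is user-supplied
(`{segments}` and `{output}` placeholders), so a keg can also drive an
external extension binary via `shell_executor()`; that path is supported
but the test suite only ever executes the built-in extender and trivial
shell commands.

## Known limitations

* The toy engine's y-drop search is internally consistent (scores
  validate; the unbanded case matches a full affine-gap oracle) but is
  not claimed to reproduce any production aligner's alignments or scores.
* Straddle counts are computed on the target axis; query-axis duplication
  is symmetric in the fixtures used and is not separately tracked.
* `read_segments()` defines a fixed eight-column dialect; aligner
  variants with different segment-file column orders need conversion.
* LPT's quality guarantee is for the makespan; it does not balance the
  *number* of sequences per bin, which is irrelevant to runtime.
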