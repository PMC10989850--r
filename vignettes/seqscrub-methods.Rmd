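---
title: "seqscrub: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqscrub: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqscrub)
```

This vignette explains the models and procedures behind seqscrub, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data validation does and does not demonstrate.

## The deterministic pack pipeline

Preprocessing is embarrassingly parallel per read, but naive
multi-threading makes output order depend on thread timing, so two runs of
the same command can produce different files. seqscrub removes that
nondeterminism structurally rather than by locking:

1. the input stream is split into *packs* of `pack_capacity` reads
   (default 1,000); pack indices are consecutive from zero and only the
   final pack may be short;
2. each pack is routed to worker `pack_index mod workers` — a pure
   function of the index, decided before any work starts (with two
   workers this is an odd/even alternation);
3. the per-pack transform (trimming, overlap operations, filtering,
   statistics) is pure: it depends only on the pack contents and the
   configuration;
4. outputs are reassembled strictly in ascending pack index, and the one
   order-sensitive stage — deduplication — runs at this reassembly point,
   never inside workers.

The worker scheduling is therefore a *contract* (fixed routing, in-order
reassembly), not a mechanism: the reference scheduler in this package runs
workers sequentially, which satisfies the contract trivially, and any
parallel scheduler honouring it must produce byte-identical results. QC
counters are integers, so merging per-worker accumulators is exact and
order-free; this is asserted fieldwise in the tests rather than assumed.

Which copy of a duplicate survives does depend on read order — the first
occurrence wins — which is precisely why dedup is pinned to the reassembly
point. Everything else commutes.

## Overlap analysis and what hangs off it

For a pair, let `s2rc` be the reverse complement of read 2 and define the
*offset* as the read-1 coordinate at which `s2rc` begins. Non-negative
offsets mean the fragment is at least as long as read 1; negative offsets
mean both reads ran through the fragment end into adapter. Candidates are
scanned in increasing absolute offset, trying non-negative before negative
at ties, and the first offset whose overlap has at least
`overlap_min = 30` bases and at most
`min(overlap_max_mismatch = 5, floor(0.2 * overlap_len))` mismatches is
accepted. The fixed scan order makes the search deterministic; the
thresholds are the conventional ones for short-read overlap analysis, and
30 bases at a 0.2 mismatch fraction makes a chance acceptance of a wrong
offset improbable for real sequence.

One overlap computation then feeds four stages:

* **Adapter clipping.** With offset `o < 0`, read 1 is truncated to
  `len2 + o` bases and read 2 to `len1 + o` bases — everything 3' of the
  fragment end goes, adapters included, without knowing the adapter
  sequence. After clipping, the pair's geometry in its new coordinates is
  a full overlap at offset 0, and the stored overlap result is updated
  accordingly before correction and merging reuse it.
* **Base correction.** At a mismatch inside the overlap, if one mate has
  quality at least `correction_high_q = Q30` and the other below
  `correction_low_q = Q15`, the low-quality base is replaced by the
  strand-consistent base of the high mate and inherits its quality.
  Symmetric mismatches are left alone: with no quality asymmetry there is
  no evidence which strand is right, and guessing would bias downstream
  variant evidence.
* **Merging.** The merged read covers the union of both mates in read-1
  orientation; in the overlap the higher-quality base wins with ties going
  to read 1. Merged quality is the maximum of the two when bases agree and
  the chosen base's quality when they disagree. This max/chosen rule is a
  documented package choice — a posterior recomputation of merged
  qualities is deliberately out of scope.
* **Insert size.** `offset + len2` for non-overhanging pairs, the overlap
  length for read-through. Pairs with no acceptable overlap are counted as
  *unknown* rather than guessed; the largest estimable insert is
  `len1 + len2 - overlap_min` (270 bp for 150-bp reads), so long-fragment
  libraries necessarily report a large unknown fraction. All pairs are
  measured by default; sampling is unnecessary at the package's scale.

## Trimming order

Stages apply in a fixed order: UMI extraction, global trim, polyG/polyX,
window cuts, overlap-based clipping and correction, adapter-by-sequence,
filters. UMI first because the UMI occupies synthesis cycles before the
insert; artifact and quality trims before overlap analysis so the overlap
sees the best available sequence; filters last so length thresholds apply
to the final read. The sliding-window cuts use the arithmetic mean of
Phred scores in a `cut_window_size = 4` window against
`cut_mean_quality = 20`, with three variants: `front` drops 5' bases until
the first window passing the threshold, `tail` is its mirror, and `right`
truncates from the first failing window onward. Windows truncated by the
read end are averaged over the bases they cover.

PolyG runs are an artifact of two-color chemistries, where a dark cycle
reads as G: a 3' run of at least `poly_g_min_len = 10` bases is removed,
tolerating one mismatch per 8 bases of run so that a sequencing error
inside an artifact run does not protect it (an exact-run mode is
available). The tolerant rule can extend a run through an isolated
real base just 5' of the artifact; that is accepted as the cost of robust
artifact removal and is the same trade the widely used preprocessors make.

Filters run in a fixed order — low quality (more than
`max_unqualified_fraction = 0.40` of bases below `qualified_phred = 15`),
too many N (more than 5), too short (under 15 bases), too long — with the
first failure winning, so the per-reason counts partition the filtered
reads and `units_in = units_out + sum(filtered)` is an exact identity, not
an approximation. For pairs the first failing check across both mates
decides. These defaults mirror the established preprocessor CLI defaults
for interoperability.

## Bloom-filter deduplication

The dedup index is `B = 3` bit arrays of `L` bits, each with its own
seeded 64-bit hash (FNV-1a with an avalanche finisher, reduced mod `L`).
Checking a key computes one position per array; if all `B` bits are
already set the key is a duplicate, otherwise the bits are set. Bits never
clear, so an exact repeat of an inserted key is always flagged — false
negatives are impossible — while false positives occur when an unlucky key
finds all its bits set by other keys.

Paired reads are combined into a single key (the two sequences joined by a
separator outside the base alphabet) and treated like a single-end read;
swapping mates changes the key. Keys are taken from the sequence *after*
trimming by default, so two copies of one fragment still collide when
adapter-length jitter has been removed; a pre-trim keying option exists.

The expected number of false positives is tracked analytically: before
check *k* with *u* unique keys inserted, a new key collides with
probability `(1 - (1 - 1/L)^u)^B`. Summing this over checks gives the
correction subtracted from the reported duplication rate (clamped to
[0, 1]). The correction adjusts the *rate* only; read removal always uses
the raw verdicts, so removal behaviour never depends on an estimate.

`L` defaults to 2^26 bits per array (8 MiB × 3 ≈ 24 MiB), which keeps the
expected false-positive count below one in a million reads at typical
duplication levels; the CLI accuracy levels scale `L` up to 2^30 and `B`
from 2 to 4. Memory is exactly `B * L / 8` bytes no matter how many reads
stream through — the tests assert the actual allocation. Hash seeds are
fixed constants so that rerunning a command flags the identical read set;
they can be overridden for experiments.

## QC statistics and reports

The accumulator keeps per-cycle base counts, per-cycle quality sums
(overall and conditioned on the called base), Q20/Q30/GC totals, and
counts over all 1,024 5-mers (k = 5 keeps the table small enough to embed
in a report while still exposing composition bias; k-mers containing N are
skipped). Cycle indices are 0-based internally and 1-based in reports.
Two accumulators are kept per input — before and after preprocessing — so
the report can show what the pipeline changed.

Overrepresentation analysis counts every substring of lengths
{10, 20, 40, 100, read_len/2} from every 20th read and flags sequences
whose count reaches `max(10, expected * 10)`, where the expectation
assumes uniform base composition (`0.25^len` per sampled position). The
uniform-composition null is deliberately crude — real libraries are not
uniform — but it only sets a flagging threshold; the per-cycle hit
distribution attached to each flagged sequence is what distinguishes a
positionally anchored contaminant (an adapter) from an abundant
transcript. The exact threshold is a documented package choice.

The JSON report serializes one payload with a fixed key order and lossless
numbers, so runs diff cleanly except for the timestamp. The HTML report is
a self-contained file rendering the same payload — summary and filtering
tables plus quality-curve, content-curve, insert-size and
overrepresentation panels as inline SVG — and embeds the full JSON in a
`script` block, so every displayed number is machine-recoverable from the
HTML itself. Interactivity beyond that is out of scope.

## The synthetic generator and what validation shows

`simulate_reads()` draws fragments from a fresh random reference, reads
them from both ends, appends adapter and random padding on read-through,
applies a linear per-cycle quality decay (Q36 to Q32, Gaussian noise
sd 2, clamped to [2, 40]) and uniform substitution errors, then plants
exact duplicates, polyG tails and UMIs as configured. Defaults describe a
typical modern library: 150-bp reads, inserts Normal(300, 30) truncated at
1, 0.1% substitution error, TruSeq adapter sequences. Everything is a pure
function of the seed, with a documented draw order, and every read is
reconstructible from the truth table.

Duplicates are copied byte-for-byte *after* error injection — including
duplicate-of-duplicate chains, which are resolved to identical bytes — so
"exact duplicate" has an unambiguous ground truth.

What passing tests on this corpus demonstrate: the offset arithmetic,
clipping geometry, merge reconstruction, bookkeeping identities,
reproducibility, and the bloom filter's statistical behaviour. What they
do not demonstrate: robustness to indels (the generator plants none and
the overlap model is mismatch-only), platform-specific quality binning,
optical/tile duplicates, or non-uniform genomic composition. Conclusions
about real data should lean on the invariants (conservation,
reproducibility, no false negatives), which hold regardless of the error
model, more than on the accuracy rates, which are corpus-dependent.

## Numerical and degenerate-input choices

* Qualities are fixed Phred+33; Phred+64 input is rejected rather than
  auto-detected, since detection heuristics misfire exactly on the
  low-diversity inputs where it matters.
* Parsing is strict: 4-line records only, `A,C,G,T,N` after uppercasing,
  hard errors (with the record index) for anything else. Corrupt input
  should stop a pipeline, not shrink it.
* Trimming can produce empty reads; they are legal values and are removed
  by the length filter, so stages compose without special cases.
* An empty input file yields an empty result and a valid report.
* Window means near read ends use the covered bases; mismatch budgets use
  floors (a 33-base overlap at fraction 0.2 tolerates
  `min(5, floor(6.6)) = 5` mismatches), never rounding up.
* Ties in the overlap scan are broken toward non-negative offsets, i.e.
  toward "no adapter read-through", the conservative reading.

## Problem sizes

The test suite validates on corpora of 50,000 pairs (reproducibility
across worker counts 1, 2, 4, 8), 100,000 keys (dedup statistics at
L = 2^20), 8,000–10,000 pairs (geometry, clipping, merging) and 1,000
reads (QC against a from-scratch oracle); the acceptance script uses the
same scales with 20,000 pairs for the reproducibility check. These sizes
were chosen so the full validation runs in about a minute while keeping
binomial noise well below the asserted tolerances.

## Known limitations

* Overlap alignment is ungapped; an indel inside the overlap usually
  yields *unknown* rather than a shifted estimate.
* Single-end adapter trimming requires an explicit adapter sequence; there
  is no consensus-based auto-detection, and paired-end input needs none
  because read-through clipping is sequence-free.
* Deduplication is exact-sequence only: no mismatch tolerance, no
  alignment positions, no UMI-aware consensus.
* The insert-size histogram cannot see past `len1 + len2 - overlap_min`.
* The in-memory pipeline materialises its input; it is designed for the
  package's analysis scale, not for streaming hundred-gigabyte runs.
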