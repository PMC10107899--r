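---
title: "Validating repeat alignments with rare k-mer collinearity"
author: "kmapq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating repeat alignments with rare k-mer collinearity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmapq)
```

## The model

A read aligned to the wrong copy of a repeat matches the reference well
in the sequence the copies share, and poorly exactly where the copies
differ. kmapq turns this into a score by treating **rare k-mers** —
k-mers whose canonical (strand-collapsed) count across the whole
reference set is at most `m` — as markers of copy-specific variation.
Inside a repeat, the conserved sequence produces k-mers with one count
per copy (not rare once there are more than `m` copies), while each
copy's private substitutions and indels create k-mers seen nowhere else.
Outside repeats, in effectively unique sequence, almost every k-mer is
rare.

For one alignment the score compares the rare k-mer *profiles* of the
two aligned intervals: the reference sublist (`l_r` occurrences) and the
query sublist (`l_q` occurrences, scanned against the same
reference-derived rare set). K-mers present exactly once in each sublist
are matched; the reference positions of the matches, taken in query
order (reversed for `-`-strand alignments so that collinearity always
means "increasing"), form an integer sequence whose longest strictly
increasing subsequence (LIS, computed by the greedy-plus-binary-search
patience method in O(n log n)) counts the shared rare k-mers in
consistent order. The score is

$$\mathrm{kMAPQ} = -10 \log_{10} \frac{l_{LIS}}{\min(l_r,\; l_q)}$$

A correct alignment of a low-error read matches nearly all of the
shorter side's rare k-mers collinearly (`kMAPQ` near 0). An alignment to
the wrong copy shares only the k-mers conserved between the two copies
*and* globally rare — a small fraction — so `kMAPQ` is large. The LIS,
rather than a common-subsequence count, keeps the cost O(n log n) while
still rejecting shuffled (non-collinear) coincidental matches.

An LIS-based score deliberately ignores k-mer orientations and
inter-k-mer distances; both are recorded in the database and available
for a stricter score, but are unused here.

## Parameters

* `k` (default 21, cap 32): window length. Must satisfy $2k \le 64$ so a
  k-mer packs into one 64-bit word, 2 bits per base (A=00, C=01, G=10,
  T=11 — complementing a base is a bitwise NOT of its pair). 21 is the
  conventional length at which k-mers of a multi-megabase genome are
  mostly unique yet a single sequencing error destroys only 21 windows.
  The scalar helpers (`encode_kmer()` etc.) exchange codes as R doubles
  and therefore accept only `k <= 26` (codes stay below 2^53, exact);
  the scanning/counting/scoring pipeline keeps codes in compiled code
  and supports the full cap.
* `m` (default 3): rarity ceiling. Raising `m` admits k-mers shared by
  up to `m` repeat copies, adding markers in repeat-dense regions at the
  cost of more coincidental matches.
* threshold (defaults 12 HiFi / 10 ONT under the `printed` convention):
  removal cutoff on kMAPQ. Threshold 12 corresponds to removing
  alignments whose collinear fraction is below $10^{-1.2} \approx 6.3\%$.
* ground-truth tolerance (defaults 10 bp HiFi / 30 bp ONT): the maximum
  start-coordinate discrepancy still counted as a correct alignment when
  labelling against simulation truth, reflecting each technology's
  start-position jitter.

Two filtering conventions are provided because the two natural readings
of a phred-like alignment score disagree about direction: under
`printed` (default) the formula above is used directly and *high* kMAPQ
(low collinear fraction) is removed at `kmapq >= threshold`; under
`mapq_like` the monotone transform $-10\log_{10}(1 - f)$ of the LIS
fraction $f$ scores *good* alignments high, as aligner MAPQ does, and
records *below* the threshold are removed. Both are monotone in the LIS
fraction — the canonical internal quantity — so a threshold in either
convention maps to a fraction cutoff. All defaults and all reported
results use `printed`.

Degenerate cases are fixed as follows: `min(l_r, l_q) = 0` (an interval
with no rare k-mers at all, common in high-error reads) makes the
alignment *unscorable*, and unscorable alignments are always kept — the
absence of markers is no evidence of misplacement; `l_lis = 0` with
non-empty sublists is reported as the cap value 60; k-mers occurring
2..`m` times within one interval are ambiguous to pair and are excluded
from matching (while still counting toward `l_r`/`l_q`); palindromic
k-mers tie with their reverse complement and are recorded as `+`;
windows containing non-ACGT characters are skipped and the rolling
window restarts after them.

## The position database

Scanning writes one line per sequence — `id TAB n TAB
pos:code:orient,...` — plus a sidecar index mapping sequence ID to the
line's byte offset, so any sequence's list is reachable with one seek.
Reference lists are pulled into memory once per reference (alignments
are processed sorted by reference, so a single-slot cache suffices) and
interval sublists are cut out by binary search; query lists are *not*
materialised — the query database stores fixed-width records (12-digit
positions, 20-digit codes, 36 bytes per record) and the interval bounds
are located by binary search with direct file seeks, after which only
the matching byte range is read. An occurrence belongs to an interval
only if its whole window is contained (`start <= pos` and
`pos + k <= end`); k-mers straddling alignment ends are not credited.
The index header records `k`, `m` and an FNV-1a checksum of the data
lines; identical inputs and parameters produce byte-identical files.

A `threads` argument is accepted across the interface for parity with
multi-threaded scanners, but execution is sequential and results are
defined to be identical for any value.

## The synthetic-data generator

The generator emulates the two repeat architectures the method targets,
at desk scale:

* **Interspersed**: 10 copies of a 10 kb unit inserted at sorted random
  positions in a 2 Mb i.i.d. background. Each copy receives exactly
  `floor(0.03 L)` substitutions (each to a different base) and then
  `floor(0.01 L)` deletions — exact-count sampling, so divergence is
  deterministic and tests can assert it sharply. The unit itself is not
  part of the background, mirroring a source segment taken from a
  different chromosome than the one being analysed.
* **Tandem**: 20 such copies concatenated head-to-tail into one array
  appended to a 1 Mb background — a structural analogue of a
  centromeric higher-order-repeat array, not a reproduction of any real
  centromere.

Reads are drawn uniformly (position and strand) to 30x mean depth with
truncated-Gaussian lengths — HiFi-like: 15 kb +/- 3 kb, 0.3% errors;
ONT-like: 25 kb +/- 10 kb, 7% errors — and per-base errors split 1:1:1
among substitutions, insertions and deletions. Each read's origin is
encoded in its name. The built-in `placement` alignment mode emits, for
every read overlapping a repeat copy, one alignment at its true locus
plus one at the corresponding offset in every other copy — false
positives by construction, labelled by the start-coordinate rule; an
`external` mode can shell out to a real long-read aligner instead.
Aligner MAPQ is set to 60 for uniquely placed reads and 1 for
multi-placed ones, so MAPQ-baseline comparisons behave like aligner
output.

What the generator does *not* model: empirical read-length/quality
profiles, homopolymer-biased ONT errors, diploidy, and structural
variation beyond the specified repeat insertions. Passing benchmarks on
this data therefore demonstrates that the scorer separates true-locus
from wrong-copy alignments under controlled divergence — not that the
operating thresholds are optimal for any particular real genome, where
repeat divergence, copy number and read quality all vary.

All randomness flows through R's RNG (including the compiled error
model), so a single `set.seed()` — or the benchmark master seed, from
which stage seeds are derived — reproduces a dataset exactly.

## Numerical and design choices

* Rarity is defined on canonical k-mers, so a k-mer and its reverse
  complement share one count; scanning checks both strands of each
  window via a second rolling code updated in the opposite direction.
* `l_r` and `l_q` count sublist *occurrences*, not distinct k-mers, per
  the definition of the sublists.
* Strict LIS is used; after the unique-match rule the reference
  positions in play are distinct, so strict and non-strict coincide.
* `score_paf()` has two implementations: a compiled fast path (cached
  reference list and interval matching in C++, query sublists read as
  raw byte blocks) and a step-by-step path composing the exported
  operations. They are verified to produce identical output; the fast
  path is the default and is what makes 30x genome-scale runs take
  minutes.
* Problem sizes: the bundled test suite runs the oracle checks at full
  spec (1000 random LIS instances up to n = 200, whole-sequence rolling
  comparisons) and the benchmark presets at their full configured sizes;
  the worked example in the README uses a reduced background so it runs
  interactively in seconds.

## Evaluation protocol

An alignment is labelled false-positive against simulation truth when it
is on the wrong sequence or its start deviates from the true origin by
more than the tolerance (strictly greater). With removal decisions from
a threshold: TP = false positives removed, FP = correct alignments
removed, FN = false positives kept, and

$$\mathrm{precision} = \frac{TP}{TP+FP}, \qquad
  \mathrm{sensitivity} = \frac{TP}{TP+FN},$$

both reported as undefined (NA) on zero denominators. The MAPQ baseline
(`mapq_baseline()`) removes alignments below an aligner-MAPQ cutoff and
exists to quantify how many false positives survive conventional
quality filtering but are caught by kMAPQ.

## Known limitations

* High-error (ONT-like) reads lose most of their rare k-mers (a 7%
  error rate leaves roughly $0.93^{21} \approx 22\%$ of windows intact),
  so some repeat intervals genuinely lack markers and come out
  unscorable; such alignments are kept by design.
* Repeat copies separated by less than a read length produce false
  placements whose intervals overlap the true one; the shared interval
  contributes genuine collinear matches and such placements can score
  below the removal threshold. This is the dominant residual
  false-negative mode on tandem arrays (placements shifted by a single
  copy).
* Rarity is computed from the reference actually supplied; an incomplete
  or redundant reference shifts counts and with them the rare set.
* Scoring treats every PAF record independently; secondary/supplementary
  annotations are preserved but not interpreted.
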