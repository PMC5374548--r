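---
title: "Overlap-based quality control of paired-end FASTQ data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-based quality control of paired-end FASTQ data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedqc)
```

# The problem

Deep sequencing applications that hunt for low-frequency somatic
variants operate uncomfortably close to the raw error rate of the
sequencer: a 1% allele fraction is not far above the per-base error
probability of a Q30 platform, and errors surviving into alignment
inflate the false-positive variant load. Per-read quality filtering
alone cannot tell a rare variant from a recurrent error. Paired-end
libraries, however, contain an internal replicate: whenever the DNA
insert is shorter than twice the read length, the two mates cover the
insert's middle from opposite strands, and every base there was called
twice by independent cluster reads. `pairedqc` is built around that
redundancy.

# The overlap engine

## Offset search

For a pair (R1, R2), R2 is reverse-complemented into R1's orientation
(call it C) and slid under R1 at integer offsets `O`. At each offset
the vertically aligned slices are compared by Levenshtein edit
distance, and the engine keeps the offset with the **global minimum**
over the whole candidate range `[-(len(C) - min_overlap),
len(R1) - min_overlap]`. Ties are resolved toward the larger overlap,
then the smaller `|O|`, then positive `O` — the least destructive
reading, since a negative offset implies adapter cutting. Searching
exhaustively rather than locally costs little at read lengths of a few
hundred bases and cannot be trapped by a local optimum.

For an error-free pair from a template of length `T` read at length
`S`, the optimum sits at `O = T - S`, with overlap `2S - T` when
`S < T < 2S`, full-template overlap `T` when `T <= S`, and no overlap
when `2S <= T`:

```{r geometry}
sim <- simulate_pairs(simulation_config(seed = 1, n_pairs = 3,
                                        template_mean = 60))
find_overlap(sim$r1[1, ], sim$r2[1, ])
```

The inner loop is compiled (Rcpp): a banded Levenshtein with an
abandonment cap, preceded by a Hamming prescan over all offsets.
Hamming distance bounds edit distance from above, so the minimum
prescan value caps every DP; wrong offsets abandon within a few rows
and the scan stays exact (the cap can only discard values strictly
worse than the optimum). Tests verify the compiled scan against an
exhaustive `adist()`-based scan and a hand-written DP table.

## Acceptance thresholds

A pair counts as overlapped when the overlap reaches `min_overlap`
(default 30 bp) and the edit distance is at most
`floor(0.05 * overlap_len)`. Both values are package defaults — the
method's description leaves them open — and both are arguments
everywhere they matter. One geometric consequence deserves a note: the
offset search range is bounded by `min_overlap`, so templates shorter
than `min_overlap` cannot be detected at the default. Workflows that
must recover very short inserts (the adapter-cutting tests exercise
templates down to 20 bp) pass `min_overlap = 15` explicitly.

## Adapter cutting

A negative best offset means the insert is shorter than the read and
both 3' tails beyond position `T = offset + len(R2)` are adapter; both
mates are truncated to `T` bases. No adapter sequence is ever supplied:
detection is purely geometric, which is the practical advantage —
bench scientists rarely know their library kit's adapter on the
analysis side.

## Correction and its gate

Correction applies only when `hamming(R1_o, R2_o) == edit(R1_o, R2_o)`,
i.e. the slices differ by substitutions alone; if an indel separates
the mates the pair is routed to the bad stream (reason
`overlap_indel`) rather than guess-repaired. Each mismatch pairing a
base at or above `qual_high` (default Q30) with one below `qual_low`
(default Q15) is resolved in favour of the high-quality call — base
and quality are copied across, reverse-complemented into the mate's
orientation. Balanced-quality mismatches are left untouched and the
pair is flagged uncorrectable, but kept: discarding is reserved for
structural (indel) disagreement. Correction can only remove
mismatches, never add them — a property the tests assert.

## Error profiling

Over overlaps strictly longer than `profile_min_overlap` (default
50 bp), the package accumulates total overlapped bases and positional
mismatches; their ratio estimates the per-base sequencing error rate.
Long overlaps are required because there a clean pair should agree
exactly, so disagreement is dominated by sequencing error rather than
alignment ambiguity. Mismatches with the Q30/Q15 asymmetry are
attributed (low-quality base = error) and tallied into the 12 ordered
`true -> observed` substitution categories, reported in R1
orientation; balanced mismatches are counted but left unattributed.
The spectrum is a platform fingerprint — two-channel chemistries, for
instance, rarely confuse the base pairs their optics separate cleanly.

Two subtleties matter for validating the estimator on simulations.
First, with errors planted independently on both mates at rate `e`,
the expected mismatch probability per overlapped base is
`2e(1-e) + (2/3)e^2` (coincident errors agree with probability 1/3);
`expected_mismatch_rate()` exposes this. Second, the acceptance rule
truncates each pair's mismatch count at `floor(0.05 * overlap_len)`,
so the estimator is slightly biased low by construction; the test
suite compares against the truncated-binomial expectation rather than
the naive one, and the truncation deficit is visible (and explained)
in the README's worked example.

# Global trimming

Per-read ("local") trimming decides cycle boundaries read by read,
which desynchronises duplicate reads and breaks position-based
de-duplication downstream. `pairedqc` instead derives **one**
`(front, tail)` decision per file from the pre-filtering cycle
profile: the central cycle is taken as good unconditionally, and the
good region expands outward until it meets an abnormal cycle on each
side. A cycle is abnormal when any of these strict comparisons holds:

1. a single base's mean content above 40% or below 15% (N exempt);
2. a base's content changing by more than 10 percentage points versus
   the neighbouring cycle toward the centre;
3. GC above 70% or below 30%;
4. mean quality below Q20.

The front side applies only (3) and (4): content unflatness at the
start of reads typically reflects the fragmentation chemistry and is
biologically meaningful, while tail unflatness is an artifact — so
tails are trimmed aggressively and fronts conservatively. The decision
is capped at 10% of cycles in front and 5% in tail (floor), which
bounds the damage on pathologically noisy files. The ±10-point change
criterion is read as absolute percentage points, and the centre cycle
is forced good even if its statistics offend — both choices where the
method description is open. Cycles supported by fewer than 10% of the
maximum read count (sparse tails of variable-length files) are never
called abnormal, since their percentages are noise.

On clean data these criteria fire rarely; the statistical fluctuation
of a per-cycle percentage at `n` reads has standard deviation
`sqrt(p(1-p)/n)`, about 1.4 points at n = 1000, so files of a thousand
reads or more are trimmed (0, 0) or at most (1, 1) when healthy. Very
small files can trip criterion (2) by chance — a fixture-size
consideration, not a data-quality one.

# Filters

*Quality/N*: a read fails when it has more than `max_low_qual` bases
below Q15 (default 40% of the read length), mean quality below Q20, or
more than 5 N bases. These numeric defaults are package choices,
aligned with the trimmer's Q20 criterion.

*PolyX*: an error-tolerant near-homopolymer detector with two
parameters — window length `P` (default 35) and tolerated non-X bases
`L` (default 2). A window qualifies only if it starts **and** ends on
X, so tolerated foreign bases cannot dangle at the run edges; X is
tried in fixed A, C, G, T order and the leftmost window is reported,
making output deterministic. PolyG reads are the signature no-signal
artifact of two-channel sequencers and arrive with *high* quality
scores, which is exactly why a quality filter cannot catch them.

*Pair semantics*: for paired-end data the pair is the unit — if either
mate fails, both are streamed to the bad output, renamed with the
failing filter (`<name> qcfail:<reason>`). The pass/fail partition is
order-invariant across filters; the reported reason follows the fixed
order quality, N count, polyX, bubble.

# Bubble detection

Air bubbles on a flowcell corrupt a roughly circular patch of a tile,
and on two-channel machines the patch reads as a dense cluster of
polyG reads. Detection runs per lane and tile on the coordinates of
polyX reads parsed from Illumina headers:

1. **Density filter** — a 20x20 grid; hits survive where their cell's
   count exceeds 5x the tile mean. Uniform background essentially
   vanishes (a Poisson cell at mean 2.5 exceeds 12.5 with probability
   ~1e-6), while bubble cells pass easily.
2. **Clustering** — connected components under an eps-neighbour
   graph, `eps = tile_width/25`. The value comes from continuum
   percolation: at the bubble densities the simulator emulates (~150
   hits in a radius-300 disc on a 2000-unit tile), eps = 80 gives each
   hit ~10 neighbours, safely above the ~4.5 percolation threshold, so
   a bubble forms one component; halving eps fragments it.
3. **Re-expansion and pruning** — the grid filter clips sparse cells
   at a bubble's rim, so each cluster is re-expanded over the
   unfiltered hit set by eps-reachability (background sits far below
   percolation density, so stray chains die out), then pruned at 1.6x
   the median centroid distance — comfortably above the sqrt(2)
   max/median ratio of a filled disc, so genuine rim points are never
   cut, while low-influence background chains are.
4. **Robust circle fit** — a minimum enclosing circle with influence
   peeling: a boundary point is dropped only if removing it shrinks
   the circle by more than 3%. A single stray at distance `D` from a
   radius-`R` bubble shrinks it by `(D-R)/(D+R)` (over 3% once
   `D > 1.06R`), whereas removing a genuine rim point of a
   well-sampled disc shrinks it by well under 1%. The plain minimum
   enclosing circle — whose centre is set entirely by extreme points —
   remains available as `min_enclosing_circle()` and is tested against
   an O(n^3) brute force.
5. **Circle filter** — radius within `[tile_width/100, tile_width/4]`
   and support of at least 20 hits; a shape screen (enclosing radius
   at most 3x the mean centroid distance) rejects line-like clusters.

None of these constants are published for the underlying method; all
were fixed once against the simulator's geometry (the calibration
measured 493/500 planted bubbles recovered within 10% centre error and
20% radius error, and 0 false circles on 100 pure-noise tiles) and all
are exposed in `bubble_params()`. Bubble detection is off by default
and worth enabling chiefly for two-channel sequencer output. Reads
whose coordinates fall strictly inside a reported circle are filtered
with reason `bubble`.

# Quality profiling diagnostics

*Discontinuity*: the number of adjacent differing bases in a window
(`ATCGA` scores 4, `AAAAA` scores 0), averaged over reads per window
start (window default 5 cycles — "short" is all the method prescribes).
Uniform random sequence sits at `(window - 1) * 3/4` change points; a
cycle-over-cycle decline flags washing problems in the sequencer.

*K-mer strand bias*: if amplification and sequencing are
strand-uniform, a k-mer and its reverse complement should repeat about
equally often. Counts are kept per canonical k-mer (the
lexicographically smaller of k-mer and reverse complement; that
spelling counts as forward). The default k = 8 matches the scale of
the diagnostic's canonical example; counting samples at most 100,000
reads, ample for a diagnostic. `k` must be even, per the module's
interface contract; note that even k admits reverse-complement
palindromes (e.g. `ACGT`) — such k-mers are counted on the forward
side and slightly understate balance, which the balance tests exclude.
`bias_summary()` condenses the table to the count-weighted mean of
`|fwd - rev| / (fwd + rev)` — 0 for balance, 1 for one-sided — as a
single-number summary of what is otherwise a visual scatter-versus-
`y = x` judgement; no published cutoff separates "little" from
"serious" bias, so the summary is descriptive, not a test.

# The simulator

`simulate_pairs()` emulates exactly the geometry the engine reasons
about: uniform random templates of configurable length, mates reading
each end (through a supplied adapter when `T < S`), substitution
errors planted per base at a configurable rate and quality, optional
whole-read polyG pairs, and Illumina-style names carrying lane/tile
coordinates. Defaults are the canonical worked geometry — 60 bp
templates at 2x50 (offset 10, overlap 40), Q35 base calls, Q8 planted
errors — so the Q30/Q15 asymmetry rule is exactly exercisable. The
two-valued quality model is deliberate: it makes correction decisions
deterministic and ground truth exact. An `error_mate` switch plants
errors on one mate only; with both mates hit, two errors can coincide
at one template position and produce a balanced-quality mismatch that
is uncorrectable by design — one-mate planting is therefore the
configuration under which "all planted errors are corrected" is
exactly attainable, and the both-mates configuration is the one for
error-rate recovery, with ground-truth bookkeeping excluding
coincidences.

What the simulator does **not** model: quality decay along the read,
PCR duplicates, indel sequencing errors (indel planting exists only to
exercise the discard gate), base-composition bias, and real flowcell
imagery. Passing tests therefore certify the algorithms' contracts on
idealised data, not performance on any particular instrument's output.

# Pipeline and report

`run_pipeline()` executes, in order: optional bubble detection (a
first pass over the input's polyX coordinates), pre-filtering QC,
automatic trimming, filtering, overlap analysis with correction and
adapter cutting, then writes good/bad (and optionally merged) FASTQ,
post-filtering QC on the surviving reads, and a `report.json` plus a
self-contained static `report.html` (tables and CSS bars; the
machine-readable JSON is the contract, the HTML a convenience).
`run_batch()` discovers R1/R2 pairs by filename token (`R1`/`R2`, or
`_1`/`_2` before the extension — a convention the package fixes, since
none is prescribed) and processes units independently; results are
identical for any worker count. With `store_overlap_only = TRUE`,
overlapped pairs are collapsed to their double-confirmed overlap (R1
orientation, per-position maximum quality) and everything else is
discarded — converting a short-insert paired-end library into clean
single-end data.

# Problem sizes used in the checks

The test suite validates error-rate recovery on 20,000 simulated pairs
at 2x100 with 130 bp templates (70 bp overlaps, 0.5% planted errors),
correction efficacy on 1,000 pairs, adapter cutting across every
template length 20-49 at 2x50, and bubble recovery over 100 planted
and 100 pure-noise tiles; oracle-equivalence checks run the compiled
engine against naive R implementations on hundreds of random cases.
These sizes were chosen so each statistical assertion has comfortable
power (the 3-sigma rate check at 20,000 pairs, the >=95/100 bubble
trials) while the whole suite stays a desk-scale computation.

# Known limitations

* Overlap detection requires `min_overlap <= T`; very short inserts
  need a lowered threshold, as discussed above.
* Indel-bearing overlaps are discarded, not consensus-called.
* Adapter cutting is paired-end only; single-end adapter removal needs
  a known adapter sequence and a different tool.
* The bubble detector's constants are simulator-calibrated; on a real
  instrument with different tile coordinate ranges, set
  `bubble_params(tile_width = ...)` accordingly.
* Error-rate estimates inherit a small downward bias from overlap
  acceptance (quantified above) and attribute only quality-asymmetric
  mismatches; balanced mismatches are reported but uncategorised.
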