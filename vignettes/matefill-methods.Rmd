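---
title: "Certified local assembly between mate pairs: the matefill method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certified local assembly between mate pairs: the matefill method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matefill)
```

## The problem

Short-read sequencers deliver read pairs whose two mates sit at the ends of
the same DNA insert, typically a few hundred bases apart, with the sequence
between them unobserved. `matefill` reconstructs that hidden interior: one
mate (the *seed*) is extended base by base through overlaps with other
reads until the other mate is located inside the growing contig. A contig
that contains the mate — at the expected orientation and within a small
Hamming distance — carries its own certificate of correctness: the
extension walked from one physically linked read to the other. Contigs
without that certificate are still emitted, but labelled by the reason the
extension stopped, which is diagnostic in itself (coverage exhaustion,
repeat collapse, or overlong extension).

The output is therefore not a genome assembly but a set of *certified*
insert-length sequences that downstream tools can treat as long,
high-accuracy pseudo-reads.

## Overlap detection: fingerprint shortlist plus Hamming verification

Scanning every read at every extension step is infeasible, so candidate
overlaps are shortlisted with a Karp–Rabin style hash. A DNA window of
length $b$ is read as a base-4 number (digits A=0, C=1, G=2, T=3, most
significant digit first) and reduced modulo a Mersenne number
$q = 2^w - 1$; the residue is the window's *fingerprint*. Two identical
windows always share a fingerprint, so the shortlist has no false
negatives; unequal windows can collide, so every candidate is re-verified
character by character. The mismatch radius of the hash is fixed at $k=0$
(exact window equality); the witness-set generalization for $k>0$ exists in
the parameter object but is deliberately not implemented, since the method
never exercises it.

Each read is indexed twice: its forward orientation keyed by the window at
read position $0$, and its reverse complement keyed by the window at
position $L-b$, where $L$ is the minimum overlap length. This placement
keeps the window inside the oriented read's $L$-prefix for every admissible
overlap length, so one pair of keys per read suffices for all overlap
lengths $\ell \in [L, L+\Delta]$.

Digit order is a free choice the hash definition leaves open;
most-significant-first is fixed here so that implementation and test
oracles agree. The modulus default $q = 2^{30}-1$ (configurable) keeps
collisions rare at desk scale while all arithmetic stays exact in double
precision: for $b \le 26$ the base-4 value is accumulated as a sum below
$2^{53}$ and reduced once; longer windows fall back to a Horner loop that
reduces at every step, with identical results. No rolling update across
window positions is used — at most $\Delta + 1$ windows are hashed per
step, so recomputation is cheap and the code stays single-path.

## The extension step

With contig $S_i$ in hand, one step performs four phases.

**Selection.** For each $\ell \in [L, L+\Delta]$, candidates from the index
are re-verified: the oriented read prefix of length $\ell$ is compared to
the contig's $\ell$-suffix and kept if the Hamming distance is at most
$\delta(\ell) = \lfloor M \ell / |r| \rfloor$ (with $|r|$ the average read
length; the floor is the conservative reading of the proportional rule). A
read qualifying at several lengths is kept once, at its largest valid
$\ell$ — the overlap set is a set, and the largest overlap carries the most
evidence. An accepted read is placed at $I(r) = |S_i| - \ell$ with end
$F(r) = I(r) + |r| - 1$ (0-based contig coordinates).

**Consensus.** The consensus window starts at the leftmost read,
$I(C) = \min I(r)$, and ends at the rightmost position still supported by
at least $m$ reads. Each column takes its majority character; ties go to
the character contributed by the earliest read under the fixed total order
"ascending $I(r)$, then input order" — a deterministic completion of the
first-read-from-the-left rule. The *representation rate* $\pi(j)$ of a
column is the fraction of covering reads that agree with the consensus
character; with a four-letter alphabet $\pi \in [0.25, 1]$ at full
disagreement. Thresholds $0.25 \le T_1 < T_2 < 1$ partition columns into
*non-represented* ($\pi \le T_1$), *low-represented*
($T_1 < \pi \le T_2$), and *high-represented* ($\pi > T_2$).

**Filtering and trimming.** Reads that disagree with the consensus at a
low-represented column are discarded: at those columns a minimum agreeing
majority is required, and dissenters are evidence of foreign origin. At a
non-represented column no character has meaningful support, so *every*
surviving read covering it is cut just before its first such column,
whether or not it matches there. The method's two descriptions of this
step disagree in one corner case — whether a read *mismatching* at a
non-represented column is discarded outright or merely cut there. This
package follows the trim-regardless-of-match behaviour. The choice is not
cosmetic: under the discard reading, a non-represented column (which, at
$T_1 = 0.3$ and four reads, forces four distinct characters) would discard
every read except the single consensus contributor, so no
minimum-support extension past a non-represented column could ever retain
two survivors; the trimming reading makes the documented worked scenario
constructible and is what the per-column semantics of "unsafe to extend,
safe to keep the agreeing prefix" intend.

**Extension.** Bounds and consensus are recomputed over the filtered,
trimmed survivors (again requiring $m$ reads at the rightmost kept
position). If the new consensus exceeds the contig's right end, the contig
becomes its prefix up to $I(C_{new})$ concatenated with $C_{new}$ — note
the consensus may *revise* contig positions from $I(C_{new})$ on, a mild
self-correction of earlier greedy choices; the seed itself is untouched
whenever $I(C_{new})$ lies at or beyond its end. Otherwise the step halts.

Zero-depth columns can only arise inside the already-built contig (beyond
the contig end the bound definition guarantees depth $\ge m$); they fall
back to the contig's own character rather than inventing one.

## Stop criteria and labels

- `NO_MORE_EXTENSION` — the *raw* overlap set already fails: fewer than $m$
  reads, or no consensus position beyond the contig end. A local signal of
  coverage exhaustion.
- `REPEAT_FOUND` — the raw set was viable but the *filtered* set fails.
  This is the repeat signature: reads from distinct genomic copies agree
  inside the repeat and split at its exit, driving columns low- or
  non-represented until filtering starves the consensus. The attribution
  between these two labels is exactly the before/after-filtering
  distinction.
- `LENGTH_EXCEED` — the contig outgrew `Lmax` (default: mean insert size
  plus three standard deviations) without meeting the mate; the extension
  was possible but cannot be certified.
- `MATE_FOUND` — the oriented mate occurs at some position $p$ with at most
  $M$ mismatches. The scan runs on the fly, never re-checking positions
  already examined at earlier steps. The match position is retained, so the
  certificate is re-assertable post hoc.

The mate's orientation on the contig strand is a library-level convention:
for the default forward–reverse (fr, "innie") geometry the mate is
reverse-complemented before scanning; `rf` and `ff` geometries are
selectable. The method statement leaves this orientation implicit; fr is
the standard Illumina paired-end layout and is what the simulator
generates.

## Tunable parameters

| Parameter | Default | Unit | Role and rationale |
|---|---|---|---|
| `L` | 50 | bases | Minimum overlap; ~half the read length balances specificity against coverage demands. |
| `Delta` | 40 | bases | Overlap slack; `L + Delta` = 90 keeps the overlap within a 100 bp read. |
| `b` | 20 | bases | Fingerprint window; larger values suppress shortlist collisions but refuse mismatch-bearing overlaps near the window. |
| `w` | 30 | — | Modulus exponent, $q = 2^{30}-1$. |
| `m` | 2 | reads | Minimum cluster size for a consensus; deliberately coverage-independent, since filtering already scales with coverage. |
| `T1` | 0.6 | rate | Non-represented threshold: below it, extension is unsafe and reads are cut. |
| `T2` | 0.9 | rate | Low-represented threshold: up to it, dissenting reads are discarded. |
| `M` | 10 | mismatches | Mate-check cap (~10% of a 100 bp read) and numerator of $\delta(\ell)$. |
| `Lmax` | mean + 3 sd | bases | Maximum contig length before giving up. |

## What the simulator states, and what a green test establishes

The generator emulates: a uniform-random (optionally repeat-planted)
genome; inserts placed uniformly with Gaussian length (truncated to
$[2\cdot\text{read\_len}, G]$); forward–reverse read orientation with the
strand drawn per pair; i.i.d. per-base substitution errors; and a truth
table with every insert's locus, strand, and planted error positions. Pair
count follows $\lceil \text{coverage} \times G / (2\,\text{read\_len})
\rceil$.

The end-to-end experiments run on a **circular** 50 kb chromosome
(`circular = TRUE`): bacterial chromosomes are circular, and at desk scale
a linear simulation spends a visible fraction of the genome inside the two
end regions where insert placement is impossible — an artifact of
miniaturization, not of the method. On the megabase genomes the method
targets, the same end effect is negligible.

The simulator deliberately does **not** model position-dependent Illumina
error profiles, indel sequencing errors (the engine's overlap model is
Hamming, so indels would only depress certification rates), quality-score
structure, GC-coverage bias, or chimeric pairs. A green end-to-end test
therefore establishes that the engine correctly reconstructs inserts and
correctly refuses repeats *under uniform substitution noise at the stated
rate* — it does not establish robustness to real instrument error
structure, which the upstream trimming/correction step is assumed to
absorb.

## Validation of output contigs

A simulated contig is validated where its seed says it must lie: the
contig (reverse-complemented first for reverse-strand seeds) is aligned by
Smith–Waterman — match $+1$, mismatch $-1$, each inserted or deleted base
$-2$, linear gap costs — against the genome window of length $|S| + g$
anchored at the seed locus, with the indel budget
$g = \lceil 3|S|/200 \rceil$. The contig is *aligned* when
$\text{score}/|S| \ge 0.95$; at that scoring the threshold admits, per
200 bp, five mismatches, or three indels, or one indel plus one mismatch,
on average. The best local score within the window is used (rather than an
end-anchored alignment); windows are clamped at genome boundaries, or
wrapped when the chromosome is circular. Crossing the trusted/untrusted
label with aligned/unaligned yields the TP/FP/FN/TN classification, and
the union of aligned trusted loci gives the reconstructed-genome fraction.

The Smith–Waterman recurrence is evaluated row-wise with the left-gap
chain closed by a cumulative maximum: for linear gap costs,
$H_{i,j} = \max_{j' \le j}\bigl(\text{base}_{i,j'} - 2(j-j')\bigr)$ with
$\text{base}$ the gap-free candidate, which one `cummax` pass computes
exactly. A full-matrix textbook implementation serves as the test oracle,
and an independent library alignment (zero gap-opening, gap-extension 2)
cross-checks both.

## Numerical and degenerate-input choices

- Sequences are validated strictly: any non-ACGT character is a distinct
  error, and the pipeline counts and skips such reads/seeds rather than
  guessing.
- The 2-bit packed representation (`encode_dna`/`decode_dna`) is exact and
  involutive under reverse complement; the engine itself operates on
  integer code vectors, which is what R's vectorized comparisons need —
  the packed form is the storage/interchange representation.
- $\delta(\ell)$ uses `floor`; ties in the consensus use the read-order
  rule above; duplicate reads are indexed independently (multiplicity is
  evidence under a coverage-based consensus); reads shorter than $L$ are
  excluded and counted.
- Every seed of the seed library is tried exactly once; reads used inside
  one contig remain available to all others (seed usage is the only
  consumed status).
- The index's residue table is a hashed map rather than a dense
  $4q$-byte array — identical query semantics at desk-scale memory.

## Known limitations

Overlaps are ungapped, so a single sequencing indel in a read suppresses
that read rather than being absorbed; consensus is unweighted by base
quality; repeats shorter than $L$ inside otherwise unique context are
resolved implicitly, but near-identical long repeats stop the extension by
design rather than being traversed; and the certification guarantee is
probabilistic in the same sense as the mate-pair protocol itself — a mate
found within $M$ mismatches at the wrong locus is possible in principle,
vanishingly rare in practice, and measured by the FP rate of the
validation experiments rather than assumed away.
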