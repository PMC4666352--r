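---
title: "Scanning genomes for intrastrand triplex motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for intrastrand triplex motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intriplex)
```

## The structural model

An intrastrand triplex arises when one DNA strand folds back twice, so
that three tracts of the same strand stack into a triple helix: two tracts
form an ordinary antiparallel Watson–Crick duplex and the third binds the
purine tract's major-groove (Hoogsteen) face. Unlike H-DNA, which needs a
mirror repeat within a duplex, the intrastrand fold is a property of a
single strand. Four classes exist, distinguished by the 5′→3′ order of the
pyrimidine-rich (Y), purine-rich (R) and Hoogsteen (H) tracts; classes I
and II are purine-motif structures (stability driven by G·G-C triads),
classes III and IV pyrimidine-motif (driven by T·A-T).

The scanner models a motif as stemA + loop1 + stemB + loop2 + stemC. Both
fold-backs are antiparallel, so the stacked triad at position *k* is
`(stemA[k], stemB[L-1-k], stemC[k])`. Each class admits a fixed triad set
(`triplet_table()`), and "mixed stems" are allowed: any triad of the class
may appear at any stack position. A candidate qualifies when at most one
stack position falls outside the class's set, and only for stems of 7 nt
or longer — 6-nt stems must be perfect. This mismatch allowance is a pure
function of stem length.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_stem`/`max_stem` | 6 / 15 | nt | shortest stem with plausible stability; beyond 15 hits are vanishingly rare and runtime grows |
| `min_loop`/`max_loop` | 1 / 6 | nt | loops are unconstrained spacers; longer loops destabilise the fold |
| mismatch rule | 1 if stem ≥ 7 | triads | imperfect triplexes are documented; a 6-nt stem cannot absorb a defect |
| hairpin stems | 9–15, loop 1–6, ≤ 1 mismatch | nt | matches the TM geometry, so hairpins act as the Watson–Crick-only control |
| v_j window `l` | 11 | columns | odd, centred; small enough to resolve motif-scale variability |
| region thresholds | open v > 0.9 ×10, close v < 0.5 ×10 | — | hysteresis: entry requires sustained high diversity, exit sustained conservation |
| locus flanks | 500 | nt | query window is motif ± 500 nt |
| `missing_min` | 300 | nt | an uncovered stretch longer than this is a missing region, not a local change |
| pair `max_gap` | 200 | nt | the five known E. coli inverted pairs lie 16–59 nt apart; 200 separates them cleanly from all other inter-motif distances |

All scans are strand-complete (reverse strand scanned on the reverse
complement, coordinates mapped back) and, for circular records, the
sequence is extended by `3*max_stem + 2*max_loop` nt of its own prefix so
origin-spanning motifs are found exactly once (anchors are restricted to
the original length).

## Enumeration multiplicity and collapsing

The enumeration reports **every** qualifying (anchor, stem length, loop1,
loop2) tuple — a 9-nt-stem motif therefore also appears as its embedded
7- and 8-nt-stem sub-motifs, and alternative loop splits of the same span
are separate rows. This is the honest primitive: any de-duplication is a
policy. `collapse = "leftmost_longest"` implements one such policy
(cluster mutually overlapping same-class same-strand hits; keep smallest
start, then largest stem, then smallest loops). Genome-level motif counts
depend strongly on this choice, which is why the package exposes both
modes rather than asserting one. For circular records, clusters merge
across the origin, making the collapsed count independent of where the
sequence was linearised.

## The TM consensus and its classification

The TM consensus is `CCCTCNCCC N(3-6) GGGNGAGGG N(3) GGGNGAGGG [GTC-]`:
a C-rich stem, then two G-rich stems, i.e. a G/C-rich class II motif.
Matching is non-overlapping on both strands, and per anchor the shortest
first loop is taken (the only ambiguity in the consensus is the boundary
between a long loop1 and the tail; the shortest-loop1 rule makes the
decomposition unique and reproduces the annotated decompositions of all
reference motifs).

Typing follows the last base of the second loop — A → type A (the T·T-A
triad), G → type B (C·C-G), anything else `unassigned`. The annotated
reference set contains loops `CTG` and `TCG` typed B, so the final base,
not the full loop, is the rule consistent with the data.

For the "mm" (mismatch) label we made a deliberate choice: a stack
position counts as mismatched when its triad is valid in **no** class, not
merely outside class II. The two rules differ on exactly one reference
motif, whose stemB carries a T at the degenerate position, creating a
T·T-A stack triad: T·T-A is the class IV triad (and the triad that defines
a type A second loop), so it is a formable triple rather than a defect,
and the motif is annotated without "mm". The any-class rule reproduces all
23 annotated labels; the class II-only rule mislabels that one motif. The
general class I–IV finder keeps the strict per-class rule — there the
class assignment itself is the question. The classifier reports up to 9
mismatches but genomic TMs carry 0 or 1.

Inverted-repeat pairing is greedy left to right over position-sorted hits,
pairing adjacent opposite-strand hits with an inner gap ≤ 200 nt, each hit
used at most once. On the reference set this yields exactly the five known
pairs, each combining one type A with one type B motif.

## Controls: scrambling and hairpins

Mononucleotide scrambling (a uniform Fisher–Yates permutation, seeded) is
the enrichment null: identical length and base composition, all
higher-order structure destroyed. Long-stem motifs essentially never
survive scrambling, so `scramble_sign_test()` checks — one-sided sign test
over replicate scrambles — that the wild-type genome carries more
stem-≥ 9 hits than its scrambles. The hairpin scanner (9–15 nt arms,
1–6 nt loop, ≤ 1 mismatch) is the Watson–Crick-only control: hairpins
share the duplex part of the motif but not the third stem, so effects
specific to triplexes should not reproduce at plain hairpins.

## Alignment variability and locus categorisation

For an alignment of closely related strains, `column_states()` counts the
distinct symbols among A, C, G, T and gap per column (`N` excluded; an
all-`N` column counts 1). This is the only reading under which a fully
conserved column contributes 0 to `v = mean(n - 1)` over the centred
11-column window. Edge columns without a full window carry `NA` — regions
can neither open nor close there. The region caller is a hysteresis state
machine: open after 10 consecutive columns with v > 0.9, close at the
column *before* 10 consecutive columns with v < 0.5 (the closing run is
outside the region; the sustained-conservation reading keeps regions
maximal without swallowing conserved tails), or at the last defined
column.

Locus categorisation consumes homology rather than computing it: 12-column
tabular BLAST output (`read_blast_tab()`) against the motif ± 500 nt
query. Thresholds the homology data do not pin down were fixed once:
coverage requires ≥ 90% identity, "no change" requires ≥ 99% identity with
no uncovered stretch ≥ 10 nt, a missing region is an uncovered stretch
> 300 nt, and the motif counts as mutated when its interval is covered
but below 100% identity. These values make the four categories mutually
exclusive and testable; they are parameters, not claims about the
original analysis. Without a coding-interval BED the `intergenic_change`
category cannot be assigned and such loci fall through to the remaining
rules with a warning. The `palindrome_effect` subcategory (a retained
hairpin after partial loss of an inverted-repeat motif) is a qualitative
approximation and is off by default.

## Synthetic data: what it does and does not show

`gen_genome()` draws i.i.d. (order-0) background — exactly the scrambling
null — and overwrites it with implanted motifs; `gen_alignment()` builds
conserved rows with blocks of controlled per-column state counts;
`gen_tmeco_sequence()` emits consensus-true motifs of requested type and
mismatch count (rejection-sampled so the parse round trip is exact). These
fixtures have no codon structure, no repeats beyond the implants, no
phylogenetic correlation between alignment rows and no indel process.
Passing tests on them demonstrates the correctness of the algorithms —
enumeration completeness, coordinate bookkeeping, statistic values, state
machines — not biological claims about real genomes. Genome-scale counts
in real data additionally depend on the enumeration-multiplicity policy
above.

## Numerical and testing choices

Test problem sizes were chosen to exercise every code path densely while
keeping the default suite fast: oracle-equivalence sequences of 300–900 nt
(50 seeds, alphabet compositions from pure A/T to pure G/C plus implanted
reference motifs — random triplexes are rare at balanced composition, so
skewed compositions provide the hit density), rotation fixtures of 900 nt,
sign tests over 20 scramble seeds on 3 kb genomes with 12 implants, and 50
replicate alignments of 8 × 600 for the variability contrast. The
brute-force oracle enumerates stripes over (stem, loop1, loop2, stack
position) in pure R with no prefiltering — an independent decomposition of
the search space from the compiled anchor-major scanner.

Degenerate inputs: `N` invalidates any triad or base pair it touches but
may sit in loops; sequences shorter than the circular padding are scanned
as linear with a warning; empty hit sets propagate as zero-row tibbles
with full column contracts.

## Known limitations

* Thermodynamics are out of scope: hits are geometric candidates, not
  stability predictions.
* H-DNA (duplex-context) triplexes and triplex-forming-oligo target sites
  are different objects and are not searched.
* The locus categoriser's identity thresholds are package conventions;
  with different BLAST parameterisations the category boundaries shift.
* Alignment variability treats all rows symmetrically; phylogenetic
  structure (the same mutation inherited by many strains) inflates `n_i`
  relative to independent events.
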