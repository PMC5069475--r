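---
title: "Dissecting an insect mitochondrial control region: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting an insect mitochondrial control region: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocr)
```

mitocr re-implements, as a tested pipeline, the comparative analysis of a
seed-bug (Rhyparochromidae) mitochondrial genome whose control region is
dominated by an unusually large tandem-repeat array: 52 full 18-bp units in
four sequence types plus one 13-bp terminal partial copy, 949 bp in all.
This vignette explains the models and algorithms, the tunable parameters
and why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and the design choices made where the
design was genuinely open.

## Coordinates and conventions

All coordinates are 1-based, fully inclusive: a tRNA at 1--65 is 65 bp.
The genome is circular, but circularity matters only to junction analysis;
the junction from the last feature back to the first is reported with
`origin = TRUE` and excluded from overlap/spacer summaries, and features
never wrap. Minority-strand ("N") feature sequences are the reverse
complement of the majority-strand ("J") slice. Truncated stop codons
("T-", "TA"), which are completed to UAA by post-transcriptional
polyadenylation, are stored verbatim and dropped before codon statistics:
they are not full codons, so including them would bias third-position
composition. Sizes are always computed from coordinates, not taken from a
table's printed size column, because printed sizes sometimes include the
truncated terminator.

## Organization statistics

The signed junction gap is `downstream start − upstream end − 1`: negative
values are overlaps, positive values intergenic spacers. Overlap and
spacer summaries exclude the origin junction and junctions flanking the
control region, so that "spacer" means a genuine short intergenic stretch;
with these exclusions the packaged reference table yields 16 overlapping
junctions totalling 75 bp (maximum 20 bp) and 4 spacers totalling 82 bp,
and these counts are reproduced only under these exclusions. Ties for the
maximum overlap would all be reported.

## Composition, skew, codon usage

AT skew is `(A − T)/(A + T)` and GC skew `(G − C)/(G + C)`; a zero
denominator is flagged, never an exception or an infinity. `N` bases are
excluded from numerator and denominator alike. Whole-genome statistics are
reported on the J strand; per-gene statistics on the coding strand, which
is the convention under which majority-strand protein-coding genes appear
AT-skewed. Codon usage uses the invertebrate mitochondrial code
(translation table 5, via Biostrings); codons containing ambiguous bases
are skipped and tallied, stop codons are excluded from the table and
tallied separately, and percentages are kept at full precision internally.

## Ka/Ks: Nei--Gojobori with Jukes--Cantor correction

No single canonical tool defines pairwise Ka/Ks for mitogenome
comparisons, so the package implements the canonical simple method (NG86): per-codon synonymous site
fractions averaged over the two sequences; for codons differing at more
than one position, synonymous/nonsynonymous step counts averaged over all
orderings of the differing positions; Jukes--Cantor correction of the raw
proportions. Two conventions needed fixing: mutations that create a stop
codon count as nonsynonymous in site counting, and pathways passing
through a stop are excluded from the average (if every ordering passes
through a stop, the codon's differences are counted as nonsynonymous
rather than dropped). A proportion at or above 0.75 leaves the corrected
rate undefined and flagged -- visible on inputs as small as a single
synonymous codon pair, where the raw proportion saturates. `ks = 0`
leaves the ratio flagged, never infinite. The regression of Ka/Ks on G+C
content is ordinary least squares via `lm`, with the coefficient of
determination computed from residual and total sums of squares.

## Tandem-array decomposition

The detector is written from scratch; the full indel-tolerant alignment
model of general-purpose repeat finders is out of scope.
For each candidate period `p` it computes the shifted self-match vector
`m[i] = (seq[i] == seq[i+p])` and a rolling `p`-window match rate; runs of
windows at or above `min_identity` (merged across gaps shorter than `p`)
seed a candidate array. Boundaries are then refined in three steps:

1. **strict trim** -- boundary positions must themselves be periodic;
2. **tolerant extension** -- a boundary mismatch is crossed only when the
   `p` positions beyond it still match at `min_identity`, which crosses
   variable sites inside an array but stops in flanking noise;
3. **score-walk polish** -- from an interior anchor, the boundary is the
   argmax of a cumulative walk scoring matches `+(1 − min_identity)` and
   mismatches `−min_identity` (scaled to exact integers so ties are
   deterministic, resolved to the outermost position). At the default
   `min_identity = 0.8` a mismatch costs four matches, so isolated
   chance matches in the flanks can never outweigh a sustained boundary.

Units are cut in phase from the array start, so a terminal partial copy is
a prefix of the consensus, matching the observed partial-at-the-3'-end
arrangement. Candidates across periods are resolved longest-array-first
with a period-minimality rule: a smaller period replaces a larger one when
their spans overlap at 90% of their union and the smaller period's
consensus identity is within 0.02 of the current best. The comparison is
against the running best, so a chain of harmonics (4p, 2p, p) collapses
stepwise to p even when the largest harmonic's span is bloated.

Defaults: `min_period = 5`, `max_period = 250` (control-region repeat
units in true bugs span several bp to beyond 200 bp), `min_copies = 3`,
`min_identity = 0.8`, minimality tolerance 0.02.

Known limitation: boundary determination assumes the outermost one or two
bases of the terminal units are not themselves variable sites between the
two edge units; an array whose edge units differ right at the edge is
recovered with a phase shifted by the distance to the first agreeing
position, because the data genuinely cannot distinguish the two phases.

## Unit typing and adjacency

Variable sites are unit-alignment columns with at least two residues each
carried by `min_minor_count` (default 2) or more units; a residue
combination seen fewer times is treated as a point mutation and folded
into the nearest type by Hamming distance at the variable sites. Types are
numbered by descending copy count, ties by first occurrence, which on the
default architecture reproduces the I(18)/II(15)/III(15)/IV(4) labelling.
The partial copy is labelled by exact prefix match against the type
templates. Adjacency rules of the form "every X is immediately followed by
Y" are evaluated on the transition-count matrix; an X in final position
falsifies the rule (its successor is the partial copy, reported
separately).

## Motif scanners and partition

Homopolymers are maximal single-base runs (default threshold 8 bp, the
length of the dissected poly-C and poly-A tracts). Microsatellites are
maximal perfect tandem runs of primitive units of 2--6 bp with at least 3
full copies; runs whose unit is itself periodic are reported at the
shortest period only, and single-base units are left to the homopolymer
scanner. Content blocks merge sliding windows meeting an A+T or G+C
threshold (gap < window merges) and recompute content on the merged slice.
Hairpins are inverted repeats: two arms of at least `min_stem` (default 6)
flanking a loop of 3--20 bases with at most one mispair, annotated with
whether TATA occurs within 10 bp upstream of the 5' arm; hits are ranked
by stem length minus mismatches.

The partition runs all scanners and resolves overlaps by fixed precedence:
tandem array > hairpin > microsatellite > poly tract > content blocks
(longer first within the content tier). Three rules keep the partition
stable at window resolution: content scanning masks positions already
claimed by a higher tier (so the pure-C poly tract cannot seed a G+C
block); content fragments shorter than the scan window are dropped; and
short unlabeled gaps adjacent to a content block are absorbed into it.
Detected arrays with period at or below the microsatellite unit bound are
left to the microsatellite scanner. Remaining gaps become `linker`
segments -- or one `unassigned` segment when nothing at all was detected.
Segments always tile the input; this is asserted on every run. Content
thresholds default to A+T >= 0.85 in 40-bp windows (midway between the
planted A+T block's 0.903 and AT-rich background filler near 0.76) and
G+C >= 0.25 (between background ~0.24 and the GC block's 0.321; the small
separation is why the GC tier relies on window merging). The hairpin
search is restricted to the sub-sequence downstream of the tandem array by
default, where the replication-origin stem-loop sits, and only the
top-scoring hairpin enters the partition.

## Slippage simulator

Slipped-strand mispairing during replication adds or subtracts repeat
units; the simulator works at whole-unit granularity because that is the
granularity of the proposed mechanism (nucleotide-level mutation is out of
scope). Per replication, duplication and deletion event counts are Poisson
with rates `dup_rate` and `del_rate`; each event picks a uniform position
and a geometric block length (`1 + Geom(block_p)`, truncated at the array
end); duplications insert an adjacent copy of the block, deletions remove
it. Defaults are `dup_rate = 0.05 > del_rate = 0.02` per replication,
reflecting the repeatedly observed excess of duplications over deletions;
the rates themselves are free parameters with no value stated in the
source. A deletion whose 5' breakpoint lies in a Type II unit and whose 3'
breakpoint lies in a downstream Type I unit leaves a single chimeric Type
IV unit -- the minimal formalization of the proposed origin of the rare
fourth type; which parent's variable-site residues the chimera inherits
outside the junction is not modelled, only the label. A deletion that
would empty the array truncates the trajectory with an extinction flag
rather than resampling, keeping ensembles unbiased. Trajectories record
an event log from which every intermediate state is reconstructible
(`replay_trajectory`), and the whole trajectory is a pure function of
(config, initial state): the per-trajectory seed is scoped with
`withr::with_seed`, so callers' RNG state is untouched. Ensembles derive
member seeds as `base_seed + i`.

With `dup_rate = del_rate` and single-unit blocks the mean array length is
a martingale; the test suite checks mean preservation over 10,000
trajectories of 30 replications from length 20 against three Monte-Carlo
standard errors, and that under default (duplication-biased, chimera-
enabled) dynamics Type IV stays the rarest type.

## tRNA conservation

A column is `identical` iff all rows carry the same residue and none is a
gap -- the colored-site convention of cloverleaf conservation figures
implies ungapped identity; `ge80` iff the modal non-gap residue covers at
least 80% of all rows (gap rows in the denominator); else `variable`.
INP% is 100 x identical columns / alignment length; whether the reference
figures used alignment length or ungapped consensus length as denominator
is not stated, and alignment length was chosen as the more conservative,
reproducible option. The center-star aligner (match +1, mismatch −1, gap
−2, center = greatest total pairwise score, first index on ties, merged
under once-a-gap-always-a-gap) is convenience plumbing for unaligned
input; published INP% values for real taxa depend on curated external
alignments and are cited as reference behaviour only, not tested. The
strand contrast reports per-strand mean INP% descriptively, with no
significance test: the contrast is descriptive.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of (config, seed) and emulate the
*architecture* of the reference data: the control-region element order
(GC-richer block, (AATTT)x3, poly-C, (TA)x5, A+T-rich block, poly-A,
linker, tandem array, linker, stem-loop with 5' TATA), the unit-type
counts 18/15/15/4 at two variable sites, the 13-bp Type I terminal
partial, and reference-table whole-genome coordinates with the shared
ATGATAA overlap motif planted at the two junctions that carry it. The
18-bp unit templates extend the known 13-bp partial-copy prefix
"GAATTAGATTAAA" with five fixed bases and place the variable sites at
unit offsets 5 and 11: both inside the 13-bp prefix, so the partial
prefix-matches Type I uniquely, and chosen so the Type II 5' + Type I 3'
chimera yields the fourth distinct combination. The templates are
synthetic: no claim of sequence-level identity to the deposited genome is
made, and real-data properties such as indels, heteroplasmy, and
position-specific substitution biases are not emulated -- passing
round-trip tests therefore demonstrates correctness of the pipeline's
logic under the stated architecture, not performance on raw reads or
divergent genomes.

Unit order is sampled by randomized backtracking over orders satisfying
the arrangement rules (II after I or IV; III between II and I; IV followed
by II; terminal partial a Type I prefix) with exact type counts; plain
rejection over random permutations has essentially zero acceptance at
these counts, so uniformity over valid orders is approximate. An
unsatisfiable configuration (e.g. a single Type IV and no Type II) raises
an error naming the violated rule.

**Identifiable ground truth.** A generator whose output contained
incidental motifs outside its truth table would make round-trip testing
ill-defined. Two mechanisms prevent this: *seam guards* -- fixed or
anti-matched bases at element junctions (e.g. the linker bases adjacent to
the array anti-match the periodic continuation over a block longer than
the decomposer's per-window mismatch allowance, so no qualifying window
can cross the boundary) -- and *motif-free resampling* -- random elements
(GC block, A+T block, linkers, hairpin stem) are redrawn until they
contain no homopolymer, microsatellite, content-window, or tandem-array
hit of their own, and the assembled control region is re-scanned to
confirm that every motif hit outside the array coincides with a planted
element. Both are deterministic given the seed. The slight compositional
distortion (e.g. the A+T block is conditioned on containing no 8-bp
homopolymer) is the price of a well-defined truth table and is confined
to the synthetic data.

The whole-mitogenome generator fills gene bodies with J-strand composition
targets (defaults 76% A+T, AT skew 0.168, GC skew −0.208, the reference
genome's values). The control-region element sum (1,518 bp with
the default 36-bp hairpin element) is smaller than the 1,853-bp annotated
slot, whose remainder the source does not dissect; the generator pads
downstream of the hairpin with AT-rich filler so the genome is exactly
16,345 bp.

## Problem sizes and numerical choices

The test suite and acceptance script run at the study's own scales: the
full 949-bp array and 1.5-kb control region for dissection (sub-second per
seed), 500-codon CDS pairs for rate recovery, 10,000 x 30-replication
trajectories for the neutral-drift check, and 15--25 random cases per
property test. Monte-Carlo assertions use three standard errors computed
from the realized sample. All percentage aggregation happens at full
precision; rounding to one decimal is left to report time.
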