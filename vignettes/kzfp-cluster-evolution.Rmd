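---
title: "Models and methods for KZFP gene-cluster evolution analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for KZFP gene-cluster evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kzfpcluster)
```

# The scientific problem

KRAB zinc finger proteins (KZFPs) form the largest transcription-factor
family in mammals. Their genes sit in tandem clusters that expand by
segmental duplication, and the youngest clusters — in mice, loci on
chromosomes 4, 2 and 12 — are simultaneously colonised by endogenous
retroviruses (ERVs), the very elements many KZFPs repress. Two observations
tie the locus biology together:

* the repertoire of KZFP genes (identified by the *fingerprint array* of
  their zinc fingers) differs radically even between mouse strains, implying
  rapid, parallel expansion of the same locus; and
* ERV families over-represented at these clusters show *tie groups* of
  copies with nearly identical divergence to their consensus, the signature
  of copy-number gain by segmental duplication rather than by independent
  retrotransposition (independently inserted copies show a continuum of
  divergence).

The mechanistic model is non-allelic homologous recombination (NAHR):
near-identical repeat copies provide ectopic microhomology, recombination
between them duplicates or deletes the intervening span — genes and TEs
alike — and every duplication adds new recombinogenic substrate, a
self-reinforcing loop.

This package implements the analysis stages needed to characterise such a
locus (fingerprint extraction and repertoire comparison, TE enrichment with
permutation tests, divergence tie-group statistics, paralog gene-block
detection, contig curation, a conservation census) together with a
generative simulator of the NAHR expansion model, so that every analysis can
be exercised and validated end-to-end on synthetic data with known ground
truth.

# Zinc-finger fingerprints

A C2H2 zinc finger follows the pattern `C-x(2,4)-C-x(12)-H-x(3,5)-H`. The
four residues at helix positions −1, +2, +3 and +6 (offsets −7, −5, −4, −1
from the first histidine) dominate DNA base recognition and form the
*fingerprint*; the fingerprints of all fingers, joined N-to-C, form the
*fingerprint array*, and exact string identity of arrays is the key used to
compare repertoires across assemblies.

`detect_fingers()` scans for the canonical pattern taking, at each anchor
cysteine, the smallest spacings that complete a match (equivalent to a lazy
regular expression) and never letting fingers overlap. Degenerate fingers —
which a strict pattern cannot see — matter because C/H-mutant fingers are
part of the published red/yellow flag scheme, so a rescue pass inspects
inter-finger gaps compatible with exactly one missing finger (gap of about
one 28-aa finger period, or start-to-start stride of about two periods) and
accepts a relaxed match anchored at the expected stride when at least two of
the four C2H2 residues are present. Classification follows the conserved
residue rules: a finger is a C/H mutant ("red") when a cysteine or
histidine is missing, else a structural mutant ("yellow") when position
−12 is not F/Y, −3 is not F or +4 is not L; truncated fingers are
conservatively treated as degenerate. Array signatures include mutant
fingers by default (dropping them would manufacture spurious cross-assembly
matches); an intact-only mode is available because the published
exact-match comparison does not state which convention was used.

# TE enrichment and permutation tests

Enrichment of a repeat family at a locus is the bp-density ratio

    (bp of family in locus / locus bp) / (bp of family genome-wide / genome bp)

with bp counted on the union of copy intervals (RepeatMasker output
routinely contains fragmented and nested hits; unions prevent double
counting). The statistic is scale-invariant and undefined (flagged, not 0)
for a family absent genome-wide.

Significance is assessed by a permutation test that re-places intervals
uniformly within an allowed placement space, preserving lengths. Two modes
cover the two directions such tests are run in practice: re-placing a single
locus against a fixed copy set (statistic: overlap bp), and re-placing a
peak set against fixed TE annotations (statistic: number of peaks
overlapping by at least 1 bp, preserving each peak's chromosome). The
p-value uses the +1-corrected estimator `p = (1 + #{null >= obs}) /
(n_perm + 1)`, which cannot return 0; the Z-score is reported alongside and
is `NA` when the null is degenerate. Families of interest are selected as
those with strictly more than 2% of their annotation records (midpoint rule)
and strictly more than 10 records inside the locus.

ChIP-seq peak filtering follows the published three-step rule: remove any
peak overlapping a negative-control peak by ≥1 bp, keep `q ≤ 0.01` and fold
enrichment ≥ 10, and fall back to fold enrichment ≥ 5 when fewer than 20
peaks survive. narrowPeak q-values are −log10 in column 9 by convention, so
the reader exposes a dialect flag defaulting to that convention.

# Divergence tie groups

For each family the locus and genome-wide divergence values form a
`DivergenceProfile` (locus membership by the midpoint rule). Tie groups are
found by single-linkage chaining on the line: sort the values and chain
consecutive gaps ≤ ε; chains of ≥ `min_size` values are groups, and the
*tied fraction* is the share of locus copies in groups. Defaults are
ε = 0.2 percentage points — one RepeatMasker reporting step (0.1) on each
side; the published analysis never quantifies "nearly identical", so this is
a package default, surfaced in output metadata — and `min_size = 3`, below
which a "group" is indistinguishable from a coincidental pair.

The test statistic is the locus tied fraction; the null resamples
`|locus values|` draws *without replacement* from the genome-wide values
(locus copies are part of that finite population) and the p-value uses the
+1-corrected estimator. Because the locus values are included in the pool,
the test is conservative when the locus holds a large share of the family's
copies; it is well calibrated when the locus share is modest, which is the
regime the selected families occupy (about a quarter of annotations or
less).

# Gene blocks from 3' exon similarity

The 3' exon of a KZFP gene encodes the zinc-finger array and is the most
informative sequence for recognising recent gene duplications. All-vs-all
global alignment (match +1, mismatch −1, a gap of length L costs
2 + 0.5·L) gives an identity matrix (matched columns over alignment
columns); genes are linked at identity ≥ 0.95 and single-linkage components
become paralog labels in coordinate order. The published analysis coloured a
clustalO guide tree by eye; a pairwise-identity threshold is the
deterministic, testable replacement, and 0.95 is a tunable default rather
than a published value.

Duplicated *gene blocks* are maximal runs of ≥ 3 paralog labels occurring
≥ 2 times along the cluster, counting reversed-order occurrences (inverted
duplications); occurrences are made non-overlapping greedily left-to-right.
A block is reported only when no one-gene extension retains its occurrence
count, which lets shorter blocks sharing a prefix/suffix with a longer block
surface exactly when they have an occurrence outside it — the signature of
partial duplications.

# Contig curation and conservation census

Reference-guided assembly curation: contigs with no alignment to a known
chromosome are dropped; a contig is assigned to the chromosome with its
largest *total* aligned bp (robust to fragmented alignments, unlike the
single-longest record); per chromosome, a contig whose reference footprint
is contained in a kept contig's footprint is dropped as nested, processing
contigs in decreasing aligned bp with lexicographic name tie-breaks for
determinism; and a kept contig is flagged for strand flipping when the
majority of its aligned bp is on the minus strand (real contigs carry
mixed-strand fragments, so a majority rule replaces the informal "aligned to
the minus strand").

The conservation census assigns each (species, KZFP unit) pair to exactly
one category, evaluated in order: unique to the species; shared only within
the focal clade; shared only among mammals; shared beyond mammals. Counts
are reported per unit or weighted by copy number, and the categories
partition the totals exactly in both modes.

# The expansion simulator

`simulate_cluster()` evolves a single-chromosome genome carrying one gene
cluster through discrete generations of (i) TE insertion, (ii) NAHR and
(iii) mutation accumulation. It is an annotation-level model: TE copies are
interval records with a divergence counter (not nucleotide sequences), while
gene 3' exons and finger arrays *are* explicit sequences because the
fingerprint and gene-block analyses consume them. A generation is an
abstract coarse time step; rates are desk-scale model parameters, not
estimates of murine rates (the source data constrain no rates).

Model structure and the reasoning behind the defaults:

* **Insertion.** Each family inserts as a Poisson process
  (`insertion_rate`/generation genome-wide); a copy lands in the cluster
  with probability `cluster_bias`, else uniformly. The ERV family inserts as
  a full-length provirus — two identical LTR copies flanking an internal
  segment — because LTR pairs born identical are the canonical NAHR
  substrate and the natural cascade founder. Genes are never disrupted
  (positions are drawn over non-gene sequence); neutral and TE segments are
  split, mirroring nested RepeatMasker annotations.
* **NAHR.** Anchor pairs are same-family, same-strand copies at most
  `max_pair_dist` apart with divergences within `div_tol` of each other and
  each at most `max_div` — a microhomology proxy: recombination needs
  near-identity, so old copies lose recombinogenic potential and every
  cascade self-terminates once its lineage divergence exceeds `max_div`.
  Pairs trigger independently with `p_nahr`; one event per generation (the
  first triggered pair in coordinate order) avoids intra-generation
  coordinate invalidation. A triggered event duplicates the span from the
  left anchor's start to the right anchor's start in tandem with probability
  `p_dup_given_nahr`, else deletes it (deletion between one element's LTRs
  produces the classic solo LTR). Anchor pairs are considered within the
  cluster only: elsewhere the genome is gene-dense and structural variants
  are purged by selection. A `scatter` geometry relocating the copy within
  the cluster is available for the scrambled-similarity pattern seen across
  strains.
* **Mutation.** Every TE copy gains an independent Gamma(shape 2, mean `mu`)
  divergence increment per generation — copies of one age class spread into
  the genome-wide continuum the tie-group test contrasts against — and gene
  sequences substitute per site at `exon_mu`.

Default study conditions: a 20 Mb genome with a 500 kb cluster (2.5%; large
enough to host gene blocks, small enough that 800 generations run in about
2 s), 12 ancestral genes, 10 ancestral LINE copies per Mb (young clusters
appear to derive from LINE-rich regions), ERV insertion rate 0.18/generation
with cluster bias 0.05 and LINE 0.1 with bias 0.07 (`cluster_bias` is the
exact probability of landing in the cluster; the complementary draw is
uniform over the rest of the genome, so bias equal to the cluster's genome
fraction is insertion-neutral), `p_nahr` 0.02, duplication:deletion 0.7:0.3
(net expansion, partially counterbalanced by contraction), `mu` 0.0133 so
the oldest copies reach ~10% divergence — giving the genome-wide continuum
enough spread relative to the tie-group ε — while the run-long divergence
noise (`mu`·√generations ≈ 0.38) stays small enough that duplication ties
persist, `max_pair_dist` 10 kb (adjacent-element recombination within tandem
arrays), `div_tol` 1 and `max_div` 1.2 (NAHR efficiency falls steeply below
~99% pairwise identity, so a cascade's lineage ages out of eligibility after
~90 generations and amplification bursts self-terminate before the locus
dominates its own family). Under these conditions
a typical run founds a few duplication cascades of roughly 3–15 events
anchored on the ERV family's LTR pairs, the cluster holds a minority share
of the family's copies, and the locus divergence distribution shows discrete
tie groups against a genome-wide continuum — the qualitative fingerprint of
the duplication model. With `p_nahr = 0` and neutral bias the locus is an
exchangeable sample of the genome and all analyses should report null
results; the test suite checks both regimes.

A practical note on which family to profile for tie groups: a full-length
LTR element deposits two *identical* LTR copies at insertion, so even a
locus that never recombines carries twin near-ties of its LTR family — the
LTR profile is not an exchangeable sample under the retrotransposition-only
null. The internal-segment family (`<name>-int`, mirroring RepeatMasker's
`MMTV-int`-style annotations) has exactly one record per insertion and is
copied along with every NAHR duplication, so it is the clean substrate for
the tie-group contrast; the validation suite and the reproduction script
profile it.

Determinism and bookkeeping: a run is fully determined by its config
(including the seed); every event is logged with enough detail (positions,
segment indices, per-copy divergence increments, per-site substitutions)
that `replay_log()` reproduces the final genome exactly without touching the
RNG, and the final length satisfies `initial + inserted + duplicated −
deleted` exactly.

What the simulator deliberately does not model: nucleotide-level breakpoints
(TE copies are annotations), selection and fitness beyond the in-cluster
NAHR restriction, diploidy and meiosis (the young clusters are depleted of
meiotic-hotspot machinery), and KZFP-mediated silencing of their target
ERVs — the proposed brake on the loop is left as future work. Passing tests
on simulator output therefore demonstrate internal consistency of the
analyses under the duplication model, not their power on real RepeatMasker
annotations, which carry fragmentation, mis-assignment between related
families and non-uniform insertion preferences that the generator omits.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion happens
  only at file boundaries (GFF and RepeatMasker .out are 1-based inclusive).
* Unstranded intervals are treated as "+" with a warning wherever
  orientation matters.
* Permutation and resampling p-values use the +1-corrected estimator; ties
  count against significance (`>=` in the null comparison).
* Alignment identity denominators are full alignment columns (including
  gaps); alignment scores follow the gap cost `open + L·ext` convention with
  open 2, ext 0.5.
* Single-linkage label assignment and contig tie-breaks are made
  deterministic by first-occurrence order and lexicographic names.
* Divergence increments are capped so `pct_div` never exceeds 100.
* Degenerate cases return flagged results rather than silent zeros: a family
  absent genome-wide has undefined enrichment, an empty PAF yields an
  all-dropped decision table with a warning, fewer locus values than
  `min_size` yield an empty tie-group result.

# Problem sizes used in the test suite

The acceptance-style checks run the simulator at the default study
conditions (50 seeds per arm for the tie-group power/calibration contrast),
use 200 permutations × 500 replicates for permutation-test calibration, 100
random proteins / 50 alignment pairs / 100 toy PAF sets for the oracle
equivalences, and 100 seeded runs for the conservation/replay contract.
These sizes give Monte-Carlo error comfortably inside the stated acceptance
bands while keeping the full suite within a desktop-scale run.
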