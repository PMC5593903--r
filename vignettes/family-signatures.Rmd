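---
title: "Detecting conservation, coevolution and subfamily signatures with famsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conservation, coevolution and subfamily signatures with famsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsig)
library(tibble)
```

famsig analyses protein domain families that mix functional subfamilies on
a shared scaffold — the motivating cases are the arsenate reductase (ArsC)
domain, shared with Spx regulators and the YffB/YusI paralogs, and the
molybdopterin domain of arsenite oxidase (AioA), shared with a zoo of
other molybdoenzymes. This vignette is the package's account of the
statistics it implements, the parameters that matter, and the design
choices made where the method leaves room.

## The model

The substrate is a multiple sequence alignment, stored as a plain tibble
of `id`/`seq` records. All positional claims are made in the native
numbering of a reference protein via a column map
(`build_reference_map()`): every non-gap column of the reference row is
numbered consecutively, and columns where the reference is gapped carry
no number. This is the convention under which family positions are quoted
as, e.g., "Arg60 of *E. coli* ArsC".

### Filtering

Family alignments exported from domain databases carry fragments and
near-duplicates that distort column statistics. Two filters run before
any analysis:

* **Fragments** (`remove_fragments()`): records occupying fewer than 50%
  of the columns with residues (threshold configurable). Domain databases
  do not define "fragment"; the occupancy rule is this package's
  operational stand-in.
* **Redundancy** (`remove_redundant()`): a greedy scan in input order
  keeps a record only if its identity to every already-kept record is
  ≤ 0.70. Identity between aligned rows is matches divided by the number
  of columns where *both* rows carry a residue — the co-occupancy
  denominator makes the measure insensitive to fragments, which is the
  filter's purpose. Greedy-in-input-order is deterministic and needs no
  arbitrary scoring; the set of survivors (not the downstream statistics'
  validity) depends on input order, which the filter report records.

Both filters are idempotent, and the redundancy output provably satisfies
the all-pairs identity ceiling (asserted in the test suite).

### Conservation

`conservation_profile()` counts residues per column as fractions of *all*
sequences — a gapped row counts in the denominator. This family-wide
reading is deliberate: a catalytic residue absent from half the family
(because paralogs lack it) should read as ~50% conserved, not 100%
conserved among carriers. `conserved_positions()` reports columns whose
modal non-gap residue frequency strictly exceeds the threshold (default
0.80, the conventional ">80%" bar; a residue at exactly 80% is not
reported). Degenerate codes (B, Z, X) count as their own symbols. A
`column_frequencies()` accessor and an optional gaps-excluded reading are
available for sensitivity checks, but gaps-in-denominator is the default.

### Coevolution

A *residue event* is a (column, residue) pair present in at least 20% of
the sequences (`event_catalog()`; the floor keeps the association
statistics out of the sparse regime). For two events a, b in distinct
columns, with f(b) the background frequency and f(b|a) the frequency of b
among sequences carrying a, the pair is *correlated* when, in at least
one direction,

* the relative increase exceeds 80%: f(b|a) > 1.8 · f(b), and
* the one-sided Fisher exact p-value (hypergeometric upper tail of the
  2×2 presence table, enrichment direction) is below 10⁻¹⁰.

Coevolved sets are the connected components of the correlated-pair graph
with at least two members (`assemble_sets()`); a maximal-clique mode is
available when all pairwise supports should be required. Same-column
events are never paired (they are mutually exclusive by construction).

Three readings deserved explicit decisions:

* *Relative vs absolute increase.* "Increases the frequency by more than
  80%" is read as relative (f(b|a)/f(b) − 1 > 0.8). The absolute reading
  (f(b|a) − f(b) > 0.8) is unsatisfiable whenever f(b) > 0.2/1.8 ≈ 0.11,
  i.e. for almost every event above the 20% presence floor, so only the
  relative reading yields a workable rule; `increase_mode = "absolute"`
  is kept for comparison. Note the relative rule has a ceiling of
  1/f(b) − 1: events above ~55% background frequency cannot show an 80%
  increase no matter how perfect the association. This is a property of
  the rule, not of the implementation.
* *Direction.* Whether the original rule required the increase in both
  directions is not pinned down; the default accepts either direction and
  reports which held (`a->b`, `b->a`, `both`).
* *Test and correction.* The significance test is the one-sided Fisher
  exact test — exact and standard for sparse 2×2 residue tables. No
  multiple-testing correction is applied: the 10⁻¹⁰ bar is itself
  stringent, and the number of pairs screened is reported
  (`n_pairs_tested` attribute) for transparency.

### Signatures and classification

Signatures are data, not code: TSV tables of
(signature, reference position, allowed residues, required/forbidden).
`builtin_signatures("arsC")` ships the conserved triad
(Arg94, Pro95, Cys-or-Gly106), the four coevolved sets
(set1 = R60·R107·P108; set2 = H8·N9·S15; set3 = C12·L/I22;
set4 = K93·N60) and the two single-position discriminators `arsC_like`
(Cys106) vs `spx_like` (Gly106); `builtin_signatures("aioA")` ships the
thirteen conserved molybdopterin positions and six coevolved sets. Note
that position 60 appears in set1 as Arg and in set4 as Asn — the sets
describe mutually exclusive subfamily states of one column, which is
exactly how the coevolution model says subfamilies diverge.

`score_sequence()` evaluates one sequence: **not assessable** when any
required position lies outside the sequence's mapped span (an amplicon
covering 27–116 cannot be scored for a position-12 signature — the
honest answer, not "absent"); otherwise **present** iff every required
in-span position carries an allowed residue and no in-span forbidden
position matches. All members of a set are required (the all-or-none
reading of set membership); a `min_required_fraction`-style relaxation
was considered and deliberately left out of the default path to keep
calls crisp. `classify()` aggregates per-signature fractions over
assessable sequences; classification is deterministic and
order-independent.

### Amplicon mapping and logo statistics

Nucleotide amplicons are translated (standard code; N-containing codons
become X; stops either truncate or error, configurable), the reading
frame is chosen by aligning all three translations against the reference
and keeping the best score (ties break toward frame 0; a primer-design
frame can be forced), and the peptide is mapped by semi-global alignment
— the whole peptide against a substring of the reference (BLOSUM62, gap
open 10, extend 0.5), the geometry of an amplicon inside a full-length
domain. Mapped residues inherit reference numbers; reference numbering is
1-based inclusive. Frameshifted or garbage clones fall below the score
floor and are reported unmappable rather than repaired.

`residue_distribution()` summarises mapped peptides per reference
position: residue frequencies among covering peptides with a Bayesian
credible interval per residue from the Beta posterior of the binomial
proportion. The default prior is Jeffreys, Beta(½, ½) — the conventional
"Bayesian 95% confidence" of sequence-logo error bars; a uniform prior is
available. Interval ends are clamped to 0/1 when the count is 0/n so the
interval always contains the point estimate; widths shrink with coverage
(both properties are asserted in the tests).

### OTU clustering and Good's coverage

Clone libraries are clustered by hierarchical agglomeration of pairwise
distances d = 1 − identity, cut at the distance cutoff (default 0.03,
i.e. 97% identity). Furthest-neighbour linkage is the default — the
historical convention of clone-library OTU tools — with average and
nearest available. Sequences are processed in lexicographic id order so
ties resolve deterministically.

Good's coverage is C = (1 − n/N) × 100 with N the library size and n, by
default, the number of *singleton* OTUs (Good's 1953 estimator). The
printed formula in the source literature is typographically ambiguous
("1 − (n/N) × 100"); only the (1 − n/N) × 100 reading produces
percentages in the reported 60–83% range, so that is the implementation,
and a literal "distinct OTUs" mode is kept for fidelity comparisons.

### Identity of unaligned sequences

`decrease_redundancy()` (the 99%/30% maximum/minimum-similarity pruning
used before phylogenetics) and `distance_matrix()` need an identity for
*unaligned* sequences. famsig uses an overlap (free end gap) pairwise
alignment and defines identity as matches divided by the shorter
sequence's length. The length normalisation matters: identity over
aligned columns lets unrelated DNA score 45–55% (optimal alignments of
random sequences either rack up matches with cheap gaps or retreat to a
tiny high-identity overlap), which would defeat a 30% minimum-similarity
rule. Under the matches/shorter-length definition, unrelated pairs land
at the ~10–25% random floor and near-duplicates at 1 − substitution rate,
so both thresholds act as intended; the hand-checkable case (one
substitution in ten bases → d = 0.1) is unchanged.

## The synthetic-data generator

`generate_family()` draws each sequence column-wise i.i.d. from a
background (uniform over the 20 amino acids by default — sharpest
planted-signal tests — or a skewed UniProt-like preset for robustness
checks), overwrites planted conserved columns in a Bernoulli(target)
subset of rows, and writes subfamily event sets deterministically into
the members of each subfamily (proportions honoured by largest-remainder
rounding; membership randomised; optional per-event flip noise). Planted
coevolution therefore arises *mechanistically from subfamily membership*
— the divergent-evolution mechanism the statistics are meant to detect —
not from an artificial pair copula. Gap and fragment contamination are
optional and labelled in the returned truth record. All generators are
pure functions of (spec, seed) and restore the caller's RNG state.

`generate_amplicons()` reverse-translates a reference region with random
synonymous codons (so translation round-trips exactly), applies per-base
substitutions, and adds random flanks (a 5′ flank of f bases makes f mod 3
the true frame). `generate_clone_library()` plants OTUs by mutating
exact position counts (round(rate·L)): members sit at
within_otu_distance/2 from their centroid (≈ within distance pairwise)
and centroids at between_otu_distance/2 from a master (≈ between
pairwise), so a 0.01-within / 0.10-between library clusters unambiguously
at the 0.03 cutoff.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: phylogenetic correlation between sequences
(real families are tree-structured, which inflates coevolution
statistics relative to the i.i.d. null), alignment errors, indel
variation within the domain, and compositional biases beyond the skewed
preset. Conclusions about real families should lean on the stringent
p-value bar, not on the generator's clean behaviour.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is sharp: oracle equivalence on
alignments up to 20×20 and on the complete 2×2 table lattice to N = 60;
planted-signal recovery on a 500-sequence, 100-column family with a 40%
subfamily and 95% conserved columns; 100 amplicons for span/frame
recovery; 10-clone libraries for the coverage closed forms; 200-sequence
mixtures for the filter contracts. Worth knowing when choosing your own
parameters:

* At N = 40 a *perfect* 20/20 association sits at p = 1/C(40, 20) ≈
  7.3×10⁻¹², barely under the 10⁻¹⁰ bar; at N = 30 the same construction
  (p ≈ 6.4×10⁻⁹) is correctly rejected. Real collections need a few
  hundred sequences for the rule to have headroom, which is also why a
  40% subfamily is detectable where a 50%+ one starts to brush the
  relative-increase ceiling described above.
* Threshold comparisons are strict (`>` for increases and conservation,
  `<` for p-values), and boundary behaviour is pinned by tests.
* Frequencies are exact rational counts; the only floating-point
  tolerance in the package's contracts is the 10⁻¹² relative agreement of
  `phyper` with direct log-factorial summation.
* Degenerate inputs are defined, not special-cased: empty co-occupancy
  gives identity 0; an all-gap reference row gives an empty map with a
  warning; positions covered by no peptide appear with n = 0; a
  one-sequence library is a single singleton (C = 0).

## Workflows and reports

`run_family_workflow()` chains read → fragment filter → redundancy filter
→ reference map → conservation → coevolution → classification, writing
every stage's TSV/JSON report plus a manifest (inputs, parameters,
package version, per-stage record counts — the counts let you reproduce
"family of X sequences, Y after filtering" narratives on any input).
`run_coverage_workflow()` does distance → cluster → coverage. Both are
deterministic given their inputs: reruns produce byte-identical bundles,
and failures name their stage and remove partial outputs.

## Known limitations

* Coevolution detection is frequency-based by design; it does not attempt
  mutual-information or direct-coupling corrections for phylogeny, and
  inherits the i.i.d.-across-sequences assumption discussed above.
* Signature classification reports biology only as good as the signature
  table; the shipped AioA conserved set is, by the family's own
  structure, insufficient to *identify* arsenite oxidases (most
  molybdopterin proteins share the amplified-region positions), and the
  package deliberately reports that insufficiency rather than papering
  over it with similarity search.
* `decrease_redundancy()` mirrors the role of the classic
  maximum/minimum-similarity pruning tool, not its exact algorithm.
* No HMM search, no database download clients, no tree inference: inputs
  are alignments and sequence sets you already have.
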