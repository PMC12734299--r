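---
title: "Genome-based species delimitation and breeding-system inference with anidelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based species delimitation and breeding-system inference with anidelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Morphology alone frequently fails to separate closely related filamentous
fungi, and single-locus barcodes (ITS, LSU) often lack resolution or carry
errors inherited from historical collections. With cheap whole-genome
sequencing, two genome-wide statistics have become decisive for species
delimitation in Sordariales and beyond:

* **Average nucleotide identity (ANI)** between two assemblies, computed
  over alignable fragments. Pairs above ~99.5% ANI are consistently
  conspecific; pairs below ~99% are usually distinct species.
* The **identity spectrum** behind the single ANI number: the histogram of
  per-fragment identities, together with the fraction of fragments with no
  detectable counterpart in the partner genome ("specific sequences").
  The spectrum distinguishes a genuinely divergent pair from a conspecific
  pair whose mean is dragged down by a minority of highly divergent
  regions, and quantifies how much of each genome is lineage-unique.

A genome assembly also reveals the **mating-type (MAT) locus**, which in
Sordariales sits between the conserved single-copy genes *APN2* and
*SLA2*. Homothallic (self-fertile) strains typically carry the *mat1-1*
idiomorph genes (*mat1-1-1*, *mat1-1-2*, *mat1-1-3*) and the *mat1-2*
idiomorph gene (*mat1-2-1*) together in that span; heterothallic strains
carry one idiomorph per nucleus. Locus architecture plus per-gene read
coverage therefore supports an inference about the breeding system, which
in turn explains fertility or sterility observed in culture.

`anidelim` implements this whole chain — fragment ANI with spectrum
diagnostics, decision rules, barcode extraction and difference counting,
MAT-locus classification with a coverage test — together with a seeded
simulator that generates genome pairs, rDNA cassettes, MAT fixtures and
coverage tables with known ground truth, so that every stage is testable
without downloading any real assemblies.

# Fragment ANI

## Model and parameters

The query genome is tiled into non-overlapping windows (`window_bp`,
default 1000 bp; trailing fragments shorter than `min_fragment_length`,
default 500 bp, are dropped; fragments that are more than half N are
masked out and reported separately, since runs of N are assembly
artefacts, not biology). Each fragment is aligned locally against all
subject contigs on both strands. The identity of the best alignment is

> identity = matches / alignment columns,

with gap columns counting against identity. This definition is stated
explicitly because alignment tools differ in it, and it is the one the
package's exhaustive dynamic-programming oracle can reproduce exactly.

A fragment is a **hit** when at least half of it aligns
(`min_aligned_fraction` = 0.5) at identity of at least 70%
(`min_identity`). Everything below is a **zero-hit**: the fragment has no
detectable counterpart, and the zero-hit share of fragments is the
specific-sequence fraction. The separation of "divergent but alignable"
(down to 70%) from "absent" is what makes the spectrum interpretable.

Directional ANI is the *unweighted* mean identity over hit fragments
(fragments are near-uniform in length, so length weighting would change
little; the choice is recorded in the report). Reciprocal ANI runs both
directions with identical parameters and averages the two values.

The per-fragment local alignment step is executed with NCBI `blastn`
(task `blastn`, word size 11 — sensitive down to the 70% hit floor), with
scoring pinned explicitly: reward +2, mismatch −3, gap open 5, gap extend
2. Pinning matters: it makes runs reproducible across BLAST builds and
lets the package's own Smith–Waterman implementation
(`align_local_exact()`, affine gaps, cost of a length-`k` gap =
`gap_open + k * gap_ext`) serve as an independent oracle. On small genome
pairs the per-fragment identities from the two routes agree exactly; this
equivalence is asserted in the test suite.

## Histogram and summary fractions

Hit identities are binned into half-open bins `[lo, hi)` with edges 70,
75, 80, 85, 90, 95, 97, 99, 99.5, 100 (top bin closed). The edges refine
the two bands the decision rules need — the ≥ 99.5% "same species" band
and the 85–90% divergent-block band — near the species boundary. Two
scalar diagnostics summarize the pooled spectrum of both directions:

* `high_identity_fraction`: share of hit fragments at ≥ 99.5% identity;
* `divergent_band_fraction`: share of *all* (unmasked) fragments with
  identity in [85, 90).

# Decision rules

With thresholds `t_same = 99.5` and `t_diff = 99.0`, a pair is classified
in this fixed order:

1. `ani_mean >= t_same` → **same_species**.
2. `ani_mean < t_diff` *and* high_identity_fraction ≥ 0.80 *and*
   divergent_band_fraction ≥ 0.02 *and* mean specific fraction ≤ 0.03 →
   **same_species_divergent_blocks**: a conspecific pair whose ANI is
   dragged below the species line by a minority of highly divergent
   blocks, while the bulk of both genomes is nearly identical and almost
   nothing is lineage-unique.
3. `ani_mean < t_diff` otherwise → **different_species**.
4. The remaining zone `[t_diff, t_same)` → **ambiguous**.

Design choices made here: the 99–99.5% interval is deliberately reported
as ambiguous rather than forced to either side — above 99.5 conspecificity
is consistent, below 99 distinctness is usual, and the interval between is
not adjudicated by ANI alone. The exception's three numeric gates (0.80,
0.02, 0.03) quantify an otherwise qualitative spectrum argument; they are
configurable and echoed in every report so a reader can see exactly which
rule fired with which values. The exception is only consulted *below*
`t_diff`, mirroring the logic that a spectrum excuse is needed only when
ANI falls below the species line.

# Barcode extraction and difference counting

`extract_barcode()` locates a reference barcode (ITS, LSU, or combined
ITS+LSU) in an assembly by best local alignment over all contigs and both
strands, requiring ≥ 75% identity over at least half the reference, and
returns the aligned subject interval in reference orientation. When no
such region exists the function fails informatively — the biological
fallback (re-assembling rRNA reads) is outside this package's scope.

`align_and_count()` reports differences in the "N differences out of M
aligned nucleotides" idiom. Conventions, chosen because the idiom itself
is silent on them:

* **Aligned nucleotides** are columns where both sequences carry a base;
  indel columns are excluded from both N and M and reported separately,
  so either convention (with or without indels) can be reconstructed.
* **IUPAC-compatible pairs** (e.g. A against R) are not differences:
  Sanger-derived reference barcodes routinely contain ambiguity codes,
  and counting them as substitutions would inflate distances.
* Scoring is match +1, mismatch −2, gap open 5, gap extend 1 — standard
  nucleotide defaults, exposed because counts near alignment ties can
  shift by ±1 under different scoring.

The counts are validated against a column scan of an independently
computed optimal alignment (`align_global_exact()`, the package's own
Needleman–Wunsch).

# MAT-locus classification and the coverage test

`classify_architecture()` works from gene annotations (GFF3 or a
5-column TSV; coordinates 0-based half-open) over the fixed vocabulary
*APN2*, *SLA2*, *mat1-1-1*, *mat1-1-2*, *mat1-1-3*, *mat1-2-1*:

* **fused** — both idiomorphs present and all mat genes inside the
  APN2–SLA2 span on one contig. Gene order and strand inside the span are
  deliberately unconstrained: only the flanking anchors are conserved
  enough to rely on.
* **split, edge-reassemblable** — the locus is split over two contigs but
  the mat genes sit at contig edges (each within `edge_distance` of an
  end, with the anchor gene innermost), so the fused arrangement can be
  reconstructed. `edge_distance` defaults to 2000 bp — "at the edge"
  cannot mean much more than a few kb of unassembled spacer — and a value
  of 0 disables reassembly entirely.
* **split_unlinked** — both idiomorphs present, exactly one bordered by
  APN2/SLA2, the other on a contig carrying neither flank. This is the
  structure that cannot be distinguished from a heterokaryon assembly
  artefact by architecture alone, which is what the coverage test is for.
* **single_idiomorph** / **incomplete** — one idiomorph only, or missing
  anchors / contradictory placements (a duplicated gene on two contigs
  yields a warning and `incomplete`, never a guess).

`coverage_ratio_test()` compares reads/kbp of the flanks against the mat
genes. In a homokaryon all six genes are single-copy (ratio ≈ 1); in a
mat1-1/mat1-2 heterokaryon each idiomorph is carried by only part of the
nuclei, so the flanks accumulate the summed coverage of both classes
(ratio → 2 at a balanced nuclear ratio). The verdict `elevated_flank`
requires *both* a practically large ratio (≥ 1.5-fold) *and* a
significant one-sided two-sample Poisson rate test (α = 0.05, gene
lengths as exposures when available); `equal_coverage` requires neither
criterion to fire; disagreement between the two yields `undetermined`.
Requiring both is what makes the verdict calibrated: a significance-only
rule would mislabel ~5% of true homokaryons by construction (the test's
level), while the conjunction drives the false-positive rate to
essentially zero without costing power at the heterokaryon effect size
(a 2-fold ratio at realistic depths is both large and significant).
Pseudogenic *mat1-1-3* copies count as present for architecture but can
be excluded from the coverage means, since pseudogenes may diverge in
mappability.

`infer_breeding_system()` combines the evidence: fused → homothallic;
split_unlinked with equal coverage → homothallic (unusual unlinked
arrangement), with elevated flanks → heterothallic_likely, without usable
coverage → undetermined; single idiomorph → heterothallic_likely, unless
(possibly partial) sexual development of single-spore isolates was
observed, which leaves single-mating-type reproduction open
(`single_mating_type_unresolved`); incomplete → undetermined. The
truth table is total: every combination of architecture, coverage verdict
and fertility flag maps to exactly one call.

# The simulator

The generator exists so that every stage above can be verified against
known truth. What it emulates, and how:

* **Substitutions** follow a Jukes–Cantor-like model: each lineage
  substitutes a site with probability d/2 (uniform over the three
  alternative bases), so the pairwise divergence parameter d is realized
  up to double hits. The analytic expectation
  `identity = (1 - d/2)^2 + (d/2)^2/3` is stored in the truth record and
  inverted in closed form by `divergence_for_identity()`, which makes
  recovery tests exact rather than approximate.
* **Divergent blocks** and **specific segments** are placed uniformly
  without overlap by bounded rejection sampling (1000 retries, then a
  simulation error — silent degradation would corrupt ground truth).
  Default segment length is 5 kb, a few fragment windows wide, so block
  boundaries do not dominate the signal.
* **Specific segments** are implemented as replacement with fresh random
  sequence rather than deletion, keeping genome sizes comparable:
  specific sequence means zero-hit regions, not length differences. The
  *same* coordinates are replaced in both genomes (with independent
  random sequence): replacing a region in only one genome would make it
  lineage-unique in *both* directions (the partner's copy also loses its
  counterpart), doubling the realized specific fraction relative to the
  parameter.
* **Indels** default off (identity spectra are the object of study;
  indels add alignment-length noise without adding signal) but are
  available with geometric lengths for length-bookkeeping tests.
* **Coverage** is simulated at the level the analysis consumes — Poisson
  read counts per gene scaled to reads/kbp — not at read level. How
  reads/kbp is computed from raw mappings (deduplication, primary-only)
  is not modelled; the Poisson abstraction is the simplest model with the
  right mean structure.
* **MAT fixtures** randomize gene order, strands, spacers and pads within
  each of the five architectures, so classifier recovery is tested across
  layouts rather than against one frozen arrangement.

`evolve_spectrum_pair()` is a second, complementary generator that plants
an exact number of substitutions per fixed 1 kb tile, controlling the
*per-fragment identity spectrum* directly — the structure in which
fragment-ANI results are actually reported. It exists because a uniform
per-site process cannot hold per-fragment identities close to a sharp
cut: at 1 kb, fragment identity has a binomial standard deviation of
about 0.2 percentage points at 99.5% identity, so a genome simulated at a
mean of 99.5% scatters a third of its fragments below the cut. The
divergent-block scenario (`simulate_divergent_block_pair()`) uses planted
tiles — 95% of tiles at 99.5% identity, 4% at 85.2%, 1% specific — to
realize a pair whose spectrum is dominated by high-identity fragments
with a populated 85–90% band and a mean ANI just below 99%, which is the
regime the exception rule exists for. Tiles align with the default
fragment grid by construction; mismatch counts per tile are exact, and
the only stochastic elements are placements and base choices.

# Numerical and validation choices

* Problem sizes used in the shipped validation: ANI recovery on 1 Mb
  pairs (five seeds per identity level in the tests), the spectrum
  scenario and specific-fraction recovery on 0.5 Mb pairs, oracle
  equivalence on 20 kb pairs, 50 random layouts per MAT architecture, and
  200 simulated coverage tables per karyotype. These sizes put binomial
  sampling noise well inside the asserted tolerances (at 1 Mb the
  realized mismatch fraction has a standard deviation of ~0.03 percentage
  points).
* BLAST's local alignments trim terminal mismatches when that raises the
  alignment score; this biases per-fragment identity upward by a few
  hundredths of a percentage point at realistic divergences, which is far
  inside the ±0.3 recovery tolerance and is accepted rather than
  corrected.
* Determinism: every generator takes a mandatory seed and is
  byte-reproducible; `blastn` is deterministic for fixed inputs and
  pinned scoring; ties among equal-scoring HSPs are broken by bitscore,
  then identity, then BLAST's own output order.
* Degenerate inputs fail loudly: an all-N genome yields zero usable
  fragments and an error, a direction with no hits makes ANI undefined
  (flagged, never silently 0), and an empty annotation table or missing
  contig length is an error, not a guess.

# Limitations

* The simulator's genomes are i.i.d. random sequence: no repeats, no
  transposons, no compositional heterogeneity. Passing recovery tests
  shows the estimators are correct under the stated model, not that real
  assemblies are free of repeat-induced ambiguity (a repeated fragment
  can align at many places; the best-hit rule hides this).
* ANI values computed here follow this package's explicit conventions
  (fragmentation, hit criteria, identity definition). Other fragment-ANI
  tools use different internals and can differ by a few tenths of a
  percentage point on real genomes; comparisons across tools should be
  made at the level of verdicts, not raw decimals.
* Breeding-system calls are evidence summaries, not certainties: an
  unlinked split locus with equal coverage may still reflect an unusual
  genuine arrangement rather than an assembly artefact, and a single
  idiomorph with partial fertility is explicitly left unresolved.
* Barcode extraction assumes the rDNA cassette is present in the
  assembly; recovering it from raw reads is out of scope.
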