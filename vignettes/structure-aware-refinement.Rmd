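---
title: "Structure-aware alignment refinement for seven-transmembrane receptors"
author: "tmrefine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware alignment refinement for seven-transmembrane receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmrefine)
```

## The problem

G-protein coupled receptors share a rigid architecture — seven
transmembrane helices (TM1–TM7) connected by three extracellular and three
intracellular loops, with an extracellular N-terminus and an intracellular
C-terminus — while their loop lengths vary enormously between receptor
families (inner loop 3 and outer loop 3 can differ by an order of
magnitude between, say, a histamine and a dopamine receptor). A sequence
aligner that knows nothing about this structure will happily stack a helix
of one sequence against a loop of another, and a single badly-registered
sequence injects spurious gaps into everyone else's helices. Downstream
phylogenetics inherits those errors.

`tmrefine` refines a multiple sequence alignment using per-residue
structural evidence that is *external* to the aligner: posterior
probabilities, for every residue, of being extracellular (E),
transmembrane (M) or intracellular (I), as produced by a membrane-topology
annotator. The aligner itself stays structure-blind; the structure enters
only through a filter-and-iterate loop around it.

## The refinement loop

1. **Label.** Each residue gets the domain of maximum posterior if that
   maximum reaches the cutoff (default 0.5, boundary inclusive); otherwise
   it is *unassigned* (U) and treated as missing everywhere downstream.
   Ties are also U: we refuse to manufacture structural evidence.
2. **Align** the current sequences (built-in progressive aligner or any
   external tool).
3. **Consensus.** Each alignment column receives the majority label among
   its E/M/I residues; gaps and U are missing data. A tied or empty column
   is U.
4. **Cull.** A sequence's *discordance* is the fraction of its evaluable
   residues (non-gap, labeled, in labeled-consensus columns) whose label
   differs from their column's consensus. Every sequence at or above the
   threshold (default 5%, `>=` semantics) is removed in one batch.
5. **Repeat** from step 2 with the survivors until a pass removes nothing.
   The count strictly decreases between removing passes, so termination is
   guaranteed.

After convergence, residues that still disagree with their column's
consensus are masked with `?` (gaps, U residues and U columns are left
alone), the columns are split into a TM partition (consensus M) and an EM
partition (everything else), and the masked alignment plus partition file
are emitted for an external partitioned maximum-likelihood engine. The
manifest records the engine defaults: LG exchangeabilities, empirical
frequencies, CAT site heterogeneity with 25 categories, final GAMMA
optimization, 100 independent searches, 200 bootstrap replicates.

Two readings of the culling denominator exist in the field — discordant
residues over a sequence's *evaluable residues*, or over the alignment's
*columns*. The residue reading is the default here (residues are what carry
labels, and the two coincide for sequences spanning most columns); the
column reading is available as `denominator = "columns"`.

Masking uses the *final* consensus only, not per-iteration consensus:
masking is a post-processing step for the inference engine, and the final
consensus is the only one every retained sequence was validated against.

## The built-in aligner

The package ships a deterministic progressive aligner so the pipeline is
testable offline: UPGMA guide tree over shared-3-mer distances (the fast
proxy large-scale aligners use; all-pairs optimal alignment would be
quadratic in both sequences and length), then profile–profile merges with
an affine-gap Gotoh dynamic program written in C++. `pairwise_global()`
exposes the two-sequence case with textbook BLOSUM62 / open −10 / extend
−1 scoring (a length-L gap costs |open| + L·|extend|, the same convention
as `Biostrings::pairwiseAlignment`, which the test suite uses as an
independent oracle).

Two scoring choices matter for keeping helices in register across merges,
and both are standard devices of the progressive-alignment literature:

* **Column scores** are count-based expected pair scores
  (`f_A' S f_B` with frequencies over all rows, gaps contributing zero
  weight). Sparsely occupied "loop corridors" therefore score near zero —
  they neither attract nor repel — while dense helix blocks retain full
  match strength.
* **Gap penalties are occupancy-weighted**: consuming a column opposite a
  gap is charged in proportion to that column's non-gap fraction. Indels
  are cheap inside regions that are already gap-rich (the variable loops)
  and expensive inside conserved blocks.
* **The default gap extension for profile merges is −0.15** (open −10).
  The families simulated here differ in loop length by up to ~100
  residues; at extension 0.15 such a loop-length difference costs
  11 + 100·0.15 ≈ 26, safely below the ~45 score earned by keeping one
  20-odd-residue helix correctly paired. At the textbook extension of 1
  the same indel costs ~110 and the optimum occasionally prefers to slide
  a helix into a loop corridor instead of paying for the gap — exactly
  the misregistration the pipeline exists to catch, but originating in
  the aligner itself and affecting a whole family at once.

Even so, profile alignment under any fixed scoring occasionally
misregisters one family against the rest (a few percent of simulated
datasets); the culling loop then removes that family wholesale. This is a
known limitation of progressive alignment, not of the refinement logic,
and it is why the recovery guarantees below are stated as averages over
replicate datasets.

The external backend (`backend = "external:<command>"`) shells out to any
tool that accepts a FASTA path and writes aligned FASTA to stdout
(e.g. `mafft --auto --quiet`). Its output is checked against the degap
invariant on every call, and a failed call cannot corrupt pipeline state
(all I/O happens in a throwaway temporary directory).

## Retention filters

Before refinement, sequences pass the conservative screens customary for
receptor datasets, with boundary semantics taken literally:

| filter | default | boundary |
|---|---|---|
| annotator score (local *and* global) | ≥ 10 | exactly 10 keeps |
| ambiguous residues (B/X/Z) | ≤ 1% | exactly 1% keeps |
| posterior cutoff for labels | 0.5 | exactly 0.5 assigns |
| description keywords | partial, low quality, pseudogene | substring, case-insensitive |

Taxonomic filtering is an allow-list of strings matched against the FASTA
description, because the package has no taxonomy service. The parameters
of the upstream homology search that assembles real datasets (5 PSI-BLAST
iterations, e-value 1e−20, 25% identity, ±50% length) are recorded in the
default configuration as documentation only.

## Partitioned-model comparison

`lrt()` compares a partitioned against an unpartitioned fit:
statistic 2·ΔlnL, degrees of freedom equal to the difference in
free-parameter counts, upper-tail chi-square p-value. The engines
disagree about how many free parameters a partition adds (19 frequencies
plus rate multipliers, under one convention), so the operation takes
explicit counts rather than hard-coding a parameterization. Tree
likelihoods themselves are never computed here — that is the external
engine's job.

## Annotation-placement concordance

`concordance_scan()` formalizes reclassification-by-placement: for each
leaf, find the smallest enclosing clade with at least `min_clade` leaves
(default 5) whose non-self, in-vocabulary annotation purity reaches
`min_purity` (default 0.9); if that clade's majority annotation differs
from the leaf's own, propose the majority. Leaves annotated
`uncharacterized`/`unlabeled` always receive their qualifying clade's
majority. Maximal clades whose annotations all fall outside the reference
vocabulary are reported as a single group with proposed class `Unknown`.

The scan is iterated to a fixpoint, excluding previously proposed leaves
from the purity and majority counts of the next pass. The reason is the
same contamination problem the alignment culling solves: when several
misannotated leaves land in one region of the tree, each can hold the
others' clades below the purity floor, and a single pass provably misses
them. Exclusion only ever removes discordant leaves from the
denominators, so clean leaves gain purity and no new proposals can be
manufactured. Rooted trees are scanned over ancestor clades; unrooted
trees over both sides of every bipartition (the clades of all rootings),
with a message.

## The synthetic generator

`sample_family_set()` emulates the structure of a real receptor
superfamily, not its sequences:

* One **shared ancestral architecture**: seven helix lengths drawn once
  (18–28 residues) and never changed — helix indels are not observed in
  this superfamily, so the generator forbids them. All families inherit
  these helices with point substitutions (divergence 0.15 per site),
  keeping cross-family helix columns alignable, which is precisely the
  signal the refinement relies on.
* **Family-specific loops**: lengths drawn per family from wide ranges
  (inner/outer loop 3: 14–120 and 10–120 residues), contents drawn from a
  globular background. Members occasionally redraw a loop's length
  (probability 0.1 per loop) — indels live only in loops.
* **Domain-conditioned composition**: helix residues come from a
  hydrophobic-biased table, loop residues from a background table, so
  structure rather than raw similarity carries the signal.
* **Motifs**: the E/DRY and NPxxY motifs are planted at the TM3/ICL2 and
  TM7/C-terminus boundaries and shielded from substitution.
* **Annotator noise**: posteriors are the true one-hot labels blurred by
  a Dirichlet with the true class at `confidence` (default 0.95) in
  expectation, concentration 60. Classifier scores for genuine receptors
  are N(50, 10) truncated at 15; decoys get U(0, 8) — the literature
  supplies thresholds, not score distributions, so these are the
  package's chosen study conditions.
* **Corruptions**: `corrupt_dataset()` rotates the domain track of
  selected sequences by a fixed shift (sequence untouched — the annotator
  locked onto the wrong register), and appends background-composition
  decoys with uniform low-confidence tracks.

What the generator does **not** emulate: real substitution processes
(no rate heterogeneity, no codon structure), annotator error structure
(real topology predictors err systematically at helix boundaries, not
uniformly), database description conventions, or paralog/ortholog
structure within families. Passing tests therefore demonstrate that the
pipeline's logic is correct under its stated model of the data, not that
any particular biological dataset would be refined perfectly.

## Numerical and design choices

* Ties: tied posteriors → U label; tied column votes → U consensus; a
  tied clade majority disqualifies the clade. Ambiguity never silently
  resolves in favor of a class.
* U-consensus columns go to the EM partition (logged), because the
  engine needs total column coverage and EM is the weaker-constraint
  class.
* Culling removes all at-or-over-threshold sequences simultaneously
  (batch semantics), and the consensus is recomputed from scratch each
  iteration.
* A sequence with zero evaluable residues gets discordance 0 with a
  warning rather than an error: it carries no structural evidence either
  way.
* Deterministic traceback tie-breaks in the aligner (match over gap-in-A
  over gap-in-B) and a fixed guide-tree construction make the builtin
  pipeline byte-reproducible for a fixed seed; all generator randomness
  flows through a single seed argument with RNG state restored afterwards.
* External coordinates (partition files, annotation tables) are 1-based
  inclusive; internal column indexing is 0-based half-open only inside
  the C++ kernel.

## Problem sizes

The validation suite exercises the reference conditions at 200 sequences
(5 families × 40 members, 20 shifted), ten replicate datasets for the
recovery averages, 200-leaf trees with 10 planted mislabels for the
concordance scan, and 1000-column randomized oracles for the consensus
and likelihood arithmetic. These sizes keep the full suite in the
minutes range on a single core while leaving every code path exercised at
realistic shape.

## Limitations

* Progressive alignment misregisters a whole family in a few percent of
  simulated datasets (see above); recovery guarantees are averages.
* The concordance scan assumes misannotations are sparse relative to
  clade structure; a clade that is mostly mislabeled to the same wrong
  class is indistinguishable from a correct clade.
* The domain-annotation dialect is this package's own (the upstream
  annotator's native format is under-documented); an adapter for real
  annotator output is out of the tested surface.
* Bootstrap computation, tree search, and likelihood evaluation are
  delegated to external engines by design.
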