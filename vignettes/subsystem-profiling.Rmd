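---
title: "Subsystem profiling by database reduction: models, parameters, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subsystem profiling by database reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subsysfocus)
```

This vignette is the package's own account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they are,
what the synthetic generator does and does not emulate, and the places where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The pipeline model

A metagenomic read set is profiled in five stages.

**Stage 0 — clustered reference.** The reference is a set of proteins, each
annotated with one subsystem path `(level1, level2, level3, function)`:
level 1 is the broadest biological class, level 3 the specific subsystem,
and the functional role the protein's named activity within it. A protein
annotated into two subsystems is two reference records. Within each level-3
subsystem, proteins are clustered greedily: sequences are visited longest
first (ties by id, which makes runs reproducible), each joins the first
cluster whose representative is at least *c*% identical, else founds a new
cluster. Only representatives are searched; a hit to a representative is
attributed to its own subsystem path. Presets mirror the published
databases: cut-offs 100, 98 (default), 95, 90.

**Identity definition.** The clustering method the reference pipeline
delegates to defines identity as identical residues divided by the shorter
sequence length, but leaves the alignment underspecified. We make it exact:
the alignment is the one *maximizing the number of identical residues*,
with gaps free and end-gaps on the longer sequence free (equivalently, the
longest common subsequence). This has three properties worth the choice:
the optimum value is unique (no tie-broken traceback can change it), it is
independently checkable by a trivial dynamic program — the test suite does
so both with a plain-R oracle and with a Biostrings alignment under a
match-=1/everything-else-=0 scoring — and a full-length substring of a
representative scores 100%, so exact fragments are absorbed at the 100%
cut-off as the preset intends. The cost of ignoring gap penalties is a
slight upward bias for unrelated sequences (random proteins score ~30–40%),
which is irrelevant at the 90–100% cut-offs used. An optional shared-4-mer
prefilter skips hopeless pairs; the suite asserts it never changes results
on family-structured inputs.

**Stage 1 — taxonomic profiling.** The sample's k-mer signature (default
k = 7, both strands counted because sequencing is strand-agnostic, k-mers
containing N skipped) is modelled as a non-negative mixture of per-genus
genome signatures, one column per genus, each the equal-weight average of
its species' signatures. The mixture is recovered by Lawson–Hanson
non-negative least squares (implemented in-package; the environment has no
NNLS library), normalized to the simplex. Genera below `min_reported`
(default 1%) are zeroed and the rest renormalized: taxa that rare are
typically missed by k-mer profilers anyway, and a floor keeps noise genera
from inflating the reduced database. Both k and the floor are configurable,
since there is no canonical published value for either.

**Stage 2 — reduction.** A genus × subsystem presence/absence matrix, built
offline by annotating complete genomes (each protein searched against the
reference; lowest-E-value hits passing the thresholds vote; a genus carries
a subsystem iff at least one of its species does — union, not majority,
because presence is determined *via species-level assignments* and union is
the only reading that needs no extra parameter), gives the subsystems
carried by the reported genera. The database is restricted to their union.
Two guard rails: genera unknown to the matrix are skipped with a warning,
and an empty selection falls back to the full database with a prominent
warning — annotating against nothing is strictly worse than slow-but-right.

**Stage 3 — search.** Reads are translated in all six frames (standard
code, partial codons dropped, N-codons to X, stops to `*`). Exact
amino-acid seeds (length 4 by default; 3 in `sensitive`, 5 in `fast` mode)
shared with a representative are extended by banded affine Smith–Waterman
(BLOSUM62, gap open 11 / extend 1, band = seed diagonals ± 16). Stop
codons are hard barriers: no reported alignment crosses one. Per
(read, subject) the best frame's local alignment becomes one tabular row.
Bit scores use the published gapped-BLOSUM62 Karlin–Altschul constants
(λ = 0.267, K = 0.041), E = m·n·2^−bit. Exact E-value calibration is *not*
a goal: downstream logic uses only E-value ordering within a run and the
1e−5 ceiling, both robust to the constants at desk scale. An exhaustive
(unseeded, unbanded) mode runs the full dynamic program on every pair; it
is the oracle that defines truth annotations. External aligners plug in via
their 12-column tabular output.

**Stages 4–5 — best hits and profiles.** Hits with E ≤ 1e−5, identity ≥
60%, alignment ≥ 15 aa survive (inclusive boundaries); among survivors,
*all* hits tied at the minimum E-value are kept. The read's unit weight is
split equally over its distinct subsystem paths — the best-hit convention
keeps all tied subsystems but fixes no abundance-sharing rule, and the equal
split is the only rule under which every assigned read contributes exactly
1 at every level (counting each tie fully would inflate totals). Ties are
compared on E-values exactly as parsed; aligners that round their printed
E-values can therefore produce different tie sets, which is documented
behaviour, and the built-in aligner prints full precision so its own files
round-trip losslessly. Abundance at a level is summed weight divided by
assigned reads; unassigned counts are reported alongside so the
total-reads normalization is recoverable.

## Evaluation framework

Truth for a read set is the tied best hits of the exhaustive search against
the full 100% database under the default thresholds. Sensitivity is correct
assignments over truth-annotated reads; precision is correct assignments
over classified reads. A read with tied labels on either side counts
correct if the predicted and truth label sets intersect — the weakest rule
consistent with "correct assignment" when ties are recorded without a
matching rule; this choice can only raise both measures relative to
stricter rules, and is applied uniformly to every method compared.
Confusion matrices are row-normalized over truth labels, with an
`unclassified` column and fractional contributions (1/|truth set| ×
1/|predicted set|) for ties. Sample profiles are compared by pairwise
Euclidean distance and agglomerative clustering; no single linkage rule is
canonical for this, so `average` is the default with single/complete/Ward
available.

## The synthetic world

The generator emulates the *structure* the pipeline exploits, with known
truth at every stage: protein families are independent random sequences
(ancestors 80–300 aa, uniform residue usage) with point-substitution
variants at a target identity (±2% from rounding); genera draw random
subsystem subsets; every species carries coding DNA (random synonymous
codons) for proteins from each of its genus's subsystems, so the
genus-level presence table is exactly recoverable; reads are error-free or
substitution-mutated fragments of coding regions, genus-proportional,
strand-random, with an optional random-DNA fraction as negative control.

What it deliberately does **not** emulate: phylogenetic correlation between
families (real subsystems share ancient folds; our families are
independent, so cross-subsystem ties are rare), realistic codon usage and
GC skew (k-mer signatures are easier to separate than for real genomes
with shared composition), indels and platform error profiles (the built-in
aligner does not handle frameshifts, so the substitution-only model
matches its stated scope), and the sheer scale of real references. A green
test therefore establishes the *contracts* — clustering keeps its identity
guarantee, reduction never changes a profile when the true genera are
reported, best-hit logic matches brute force, NNLS recovers mixtures at
the stated read depths — not field-scale sensitivity/precision figures,
which depend on the real SEED database and real metagenomes and are
explicitly out of scope.

## Numerical choices and degenerate inputs

- Greedy clustering order: length descending, then id ascending; ties in
  the join step go to the earliest-founded cluster. Deterministic by
  construction.
- Search output ordering: read input order, then E-value, then subject id,
  so results are invariant to database iteration order.
- NNLS: active-set tolerance 1e−10; the suite checks the solution beats a
  0.01-step grid over the simplex on small instances.
- Thresholds: all inclusive at the boundary (≥/≤).
- Degenerate inputs: empty sequence files warn and yield empty streams;
  reads shorter than 3 nt translate to zero frames with a warning; a
  genome with no passing hit contributes an empty set with a warning; zero
  assigned reads give an empty profile with a warning; an empty reduced
  database is an error (the fallback upstream should make it unreachable).
- Acceptance criterion for profile clustering uses two fixed, clearly
  distinct base profiles over 10 labels (0.30 … 0.01 and its reverse) with
  σ = 0.02 Gaussian noise, clamped and renormalized — fixed as the stated
  world rather than redrawn per seed.

## Known limitations

The built-in aligner is a desk-scale reference implementation: correct and
oracle-checked, but orders of magnitude slower than production translated
aligners, and without frameshift handling or composition-based score
adjustment. E-values are calibrated only up to the published constants.
Function-level profiles on clustered databases below 100% lose resolution
(a representative may stand in for members with different roles); the CLI
warns in that case. Genus signatures average species equally, which
underweights large genomes within a genus.
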