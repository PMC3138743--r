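---
title: "Repeat conservation mapping: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat conservation mapping: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcmap)
```

## The problem and the structural premise

Leucine-rich repeat (LRR) domains are built from ~20–30 residue repeats
that stack into a curved solenoid: one repeat per helical turn, a concave
face formed by short beta strands, and a convex face opposite it. Two
structural regularities make sequence-only functional-site prediction
possible here when it is hopeless for most folds:

1. the consensus residues of the repeat motif (mostly leucines and other
   hydrophobics) are buried in the solenoid core, so they carry structural
   rather than interaction information; and
2. the repetitive architecture fixes the relative spatial position of
   every non-consensus residue — position *p* of repeat *r* sits directly
   "above" position *p* of repeat *r + 1* on the domain surface.

`rcmap` exploits both. It discards consensus positions, lays the
remaining solvent-exposed residues out on a repeats-by-positions grid
that is a faithful flat map of the solenoid surface, scores each grid
cell's conservation across two or more homologous sequences, and smooths
those scores over spatial neighborhoods. Surface patches that evolution
has conserved across functionally related homologs are candidate
interaction sites; in divergence mode the same map is read bottom-up to
find diversified patches in paralog families with distinct specificities.

## Repeat model

A consensus motif such as `xxLxxLxxLxxLxLxxNxLxGxIP` (the generic
24-residue LRR preset, `lrr24`) is tokenized into fixed residues,
alternative positions (`t/s` = T or S, in the plant extracellular preset
`plant`), and `x` wildcards — the variable, surface-exposed positions
that become grid columns. The beta-strand/beta-turn region is located by
matching the nine-position pattern `L-x-x-L-x-L-x-x-N` against the motif
*treated cyclically*, because a repeat motif can be written starting at
any rotation; the two shipped presets are rotations of the same
architecture and both yield exactly five beta-region wildcards. Cells on
this concave face carry the conventional `repeat.position` labels (e.g.
`2.3`, the third variable position of the beta segment in repeat 2).

Repeat detection is a greedy left-to-right scan. At each offset the motif
is placed with at most `indel_budget` (default 2) insertions or deletions,
chosen to maximize the number of matched consensus tokens; a placement is
accepted when at least `min_match_fraction` (default 0.6) of the fixed
and alternative tokens match, with consensus `L` matching any of
L/I/V/F/M (the relaxed-leucine rule, standard practice for LRR
annotation since many "leucine" positions tolerate the other branched
hydrophobics). These defaults reproduce perfect tandem arrays exactly and
are deliberately permissive for real, irregular LRRs; automatic models of
real receptors usually need hand-curation, which is applied as an
explicit table of cell edits (`apply_curation()`) so that every curated
decision is recorded and replayable. Residues not assigned to any repeat
are simply absent from the grid; deleted motif positions become masked
cells, keeping one grid row per repeat.

## Alignment

Families may be supplied pre-aligned (aligned FASTA or Clustal), which is
the recommended route when an external aligner is preferred. The built-in
aligner is a conventional progressive scheme: global pairwise alignment
with affine gap penalties (open 10, extend 0.5, scores from the run's
substitution matrix), neighbor-joining guide tree on pairwise identity
distances, and profile–profile merges in tree order with
expected-substitution-score column scoring. Records are canonically
sorted by identifier before any computation, which makes the output both
deterministic and invariant to input order. The dynamic programming core
is compiled (Rcpp) and verified in the test suite against an exhaustive
enumeration of all global alignments on short strings.

Each reference grid cell is then mapped to the alignment column holding
that reference residue, so every homolog contributes exactly one symbol
(residue or gap) per cell. Homologs with more repeats than the reference
contribute those extra repeats to columns no reference cell maps to; they
are ignored, because the grid is defined by one protein.

## Conservation scores

Three score stages are computed per cell, from the multiset of symbols
across family members:

* **raw** — the mean substitution-matrix score over all unordered member
  pairs. Comparable within a map but confounded by residue identity:
  tryptophan pairs outscore alanine pairs even at equal conservation.
* **weighted** — the mean of normalized pairwise scores
  $w(a,b) = \mathrm{clip}\!\left(\frac{S(a,b) - S_{\min}}
  {\min(S(a,a), S(b,b)) - S_{\min}},\, 0, 1\right)$,
  where $S_{\min}$ is the matrix minimum over the 20 standard residues.
  Identity maps to 1 for every residue and the most dissimilar
  substitution to 0, removing the residue-identity confound and giving
  the heat map well-defined endpoints.
* **regional** — the weighted grid smoothed by the sliding window below;
  this is the value the map displays.

Gap handling: a pair involving a gap scores 0 (weighted) or the matrix
minimum (raw) under the default `score` policy — an indel at an exposed
position is treated as evidence of non-conservation. The `exclude`
policy drops such pairs instead. BLOSUM62 is the default matrix, with
BLOSUM65 (used for the original validation maps) shipped as an option;
the matrix identifier is recorded in every output so maps are never
compared across matrices unknowingly.

## Regional smoothing

Functional surfaces are patches, not single residues, so single-cell
conservation is noisy evidence. The regional score of a cell is the
weighted mean of the cell scores in the window centered on it. The
default kernel is 5×5 — 25 cells spanning 5 repeats — with integer
weights by Chebyshev ring distance from the center: 4 / 2 / 1 for the
center, first and second rings (sum 36, center contributing 11%). This
sits between the two failure modes we can demonstrate on random grids:
a uniform window over-smooths (map variance is provably lowest), while a
center-only window does no regional pooling at all (the map reduces
exactly to the cell grid). Uniform, center-only and Gaussian kernels are
available, and map variance is monotone in kernel flatness across them.

Edges and masked cells use truncated-window renormalization: the score is
averaged over the in-bounds, unmasked window cells only, so border
repeats are colored rather than padded with invented values. The window
is rectangular on the grid with no wrap-around in either direction —
vertical neighbors in the grid are already the spatial neighbors between
solenoid turns, and wrapping columns would join residues that sit on
opposite sides of a repeat.

## Evaluation statistics

For validation against families with known ligand-contact residues,
cells are ranked in descending score order (ties broken by grid position,
so every ranking is deterministic) and split into deciles by
$\lceil 10r/n \rceil$; decile sizes differ by at most one. The reported
statistics are the per-decile contact histogram for each score stage,
the top-decile and top-two-decile contact fractions, and a two-sample
pooled-variance Student's t-test of contact-cell versus remaining-cell
regional scores. The t-test is one-sided (the scientific claim is
directional — contacts score *higher*) and the two-sided p-value is
reported alongside.

## The synthetic family generator

`generate_family()` produces families with known ground truth so every
pipeline claim is testable without downloads. The reference is a perfect
tandem realization of the motif (wildcards drawn uniformly from the
residues unused by the consensus); each other member copies it and
independently resamples every variable cell with probability
`background_mutation_rate`, except the cells of a designated patch,
resampled with `patch_mutation_rate` (default 0: perfectly conserved).
Consensus cells are never touched.

Default study conditions for the validation runs: 20 repeats, 4
sequences, background mutation rate 0.5, and a 3×3 patch placed at the
center rows of the grid on the middle three beta-face columns — where
ligand contacts sit in solved LRR structures. Under these conditions
the acceptance suite checks that the patch mean regional score beats the
background in at least 19 of 20 seeded families, that ≥90% of patch
cells land in the top two deciles on average, that the one-sided t-test
reaches p < 0.005 in ≥90% of seeds, and that the fraction of patch cells
captured in the top decile is non-decreasing across the raw → weighted →
regional stages — the qualitative progression observed on real
crystal-structure validation families. Tests use 20 families per
statistic and a 50-seed panel for the null calibration below; these
sizes give stable estimates of the stochastic invariants while keeping
the default suite fast.

What the generator deliberately does *not* model bounds what passing
tests show about real data. Members are independent draws from the
reference (a star phylogeny): there is no tree structure, so scores are
not inflated by phylogenetic correlation between close relatives, a real
effect visible when mapping very similar orthologs. Wildcards use a
uniform residue distribution rather than natural frequencies (a
frequency-weighted option exists), mutations are substitutions only (no
indels, so alignments are trivially correct and gap policy is never
exercised by the fixtures), and every repeat is regular. Success on
these fixtures therefore validates the scoring and smoothing machinery
and its statistics — not repeat detection on irregular domains, nor
robustness to alignment error, which real applications must assess via
the curation and pre-aligned input paths.

A null control generates families whose "patch" mutates at the
background rate; a placement-permutation test (the observed 3×3 block
mean compared against every possible block placement, preserving the
spatial correlation of regional scores) then rejects at close to its
nominal 5% level, i.e. the pipeline does not manufacture enrichment
where none exists.

## Numerical and design choices

* The exact pairwise weighting scheme of the original server's published
  description is not specified to reproducible precision; the min-self
  normalization above is this package's own definition, chosen so that
  the weighted scale has fixed, interpretable endpoints. Results are
  always labelled with score mode and matrix.
* The original default window weights are likewise unpublished; the
  4/2/1 ring kernel is this package's default for the reasons above, and
  the kernel is recorded in the run manifest.
* All randomness is driven by explicit integer seeds through R's RNG;
  the caller's RNG state is saved and restored, and the seed is recorded
  in the manifest, making every fixture and map bit-reproducible.
* Ties in ranking and decile assignment break by (repeat, column);
  degenerate inputs (no wildcards, zero repeats, fewer than two
  sequences, fewer than ten cells for deciles, empty contact sets) raise
  early, stage-named errors.
* Scores are written to TSV at full precision (`%.17g`), so a written
  map re-reads identically and a manifest re-run reproduces outputs
  bit-for-bit.

## Limitations

The grid is a topological surface model, not geometry: it cannot see
long-range 3D contacts between distant repeats, N/C-terminal capping
domains, or ligands bound across an interface with another protein.
Scores from families of unclear functional equivalence (mixed paralogs)
must be read with the divergence mode in mind — a diversified patch is a
finding, not a failure. And as with the original method, repeat models
for irregular real-world LRRs generally require hand-curation before the
map is trustworthy.
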