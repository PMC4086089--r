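---
title: "Methods: comparative modelling with quality estimation in homomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative modelling with quality estimation in homomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(homomod)
```

## The modelling problem

Comparative (homology) modelling predicts the 3D structure of a target
protein from an experimentally determined structure of an evolutionarily
related protein (the template). The pipeline in this package follows the
classical four steps -- template identification, template selection, model
building, model quality estimation -- and adds two quaternary-level
concerns: whether the template's homo-oligomeric state carries over to the
target, and which of the template's bound small molecules should be carried
into the model.

Everything runs on desk scale: the package ships a fixtures module that
generates the template structures, homolog pairs, decoys and calibration
tables needed to exercise and calibrate every stage, so no database
downloads are involved. The same code paths accept real PDB/mmCIF files.

## Template library

A library entry is one *bio-unit*: the likely biologically relevant
assembly, expanded from the deposition's assembly instructions (REMARK 350
operators in PDB files, `pdbx_struct_assembly_gen`/`pdbx_struct_oper_list`
in mmCIF). Per chain the entry stores the one-letter sequence, a 3-state
secondary-structure string, per-residue relative solvent accessibility, and
detected purification tags.

Annotation choices:

* **Solvent accessibility** uses Shrake-Rupley sphere sampling (probe
  1.4 Å, 256 points per atom by default; library annotation uses 64 points,
  which converges to within 0.02 of the 512-point values on our fixtures).
  Relative accessibility divides by a per-residue-type maximum reference
  area (theoretical values of Tien et al.). Sampling happens in the
  structure's principal-axis frame with an orientation convention taken
  from the atom order, which makes the values exactly invariant under rigid
  motions of the input -- a property the test suite checks.
* **Secondary structure** is assigned from backbone dihedrals: runs of at
  least 4 residues inside a helical phi/psi window (phi in [-100, -30],
  psi in [-80, -5]) become H, runs of at least 3 inside an extended window
  (phi in [-170, -70], psi in [70, 170]) become E, everything else C. This
  replaces hydrogen-bond-pattern assignment deliberately: only 3-state
  agreement fractions are consumed downstream, and the dihedral windows
  need no external binary.
* **Purification tags** are terminal-anchored motif matches (poly-histidine
  runs of 6+, Strep, FLAG, TAP) within a margin of either terminus;
  internal matches are ignored because genuine tags are terminal fusions.

### Ligand annotation

Ligands are classified in two stages. Stage one is rule-based on chemical
identity: a covalent bond to the polymer (any heavy-atom pair below 1.7 Å)
forces `covalent_modification`; otherwise shipped identity lists decide --
solvent ions (potassium, chloride, sulfate, ...) and buffer/cryoprotectant
molecules (glycerol, ethylene glycol, ...) are `non_functional`, cofactors
(heme, nucleotides, flavins, iron-sulfur clusters, ...) and catalytic
metals are `biologically_relevant`. Ligands matching no list default to
`biologically_relevant` with the note `unclassified`: the conservative
choice, because the transfer stage re-examines them geometrically anyway.
Stage two applies curated overrides from a JSON file; an override always
wins over a rule (the canonical example is re-annotating a "solvent"
potassium ion as functional in a potassium channel). The 1.7 Å covalent
threshold sits above typical covalent bond lengths (~1.5 Å C-C) and below
van der Waals contact distances (~3 Å), so neither class bleeds into the
other.

## Template search and ranking (GMQE)

The library is searched with a single affine-gap Smith-Waterman aligner
(BLOSUM62, gap open 11, extend 1) with fully deterministic tie-breaking
(diagonal over vertical over horizontal; first-encountered maximum). A
profile-based search would be more sensitive at low identity; the local
aligner was chosen because it is self-contained and exactly testable
against a brute-force enumerator, and the aligner's normalized score stands
in for a profile-score feature. Each hit yields six features, all computed
over aligned (non-gap) columns -- this is our reading of "normalized by
alignment length", recorded here because the alternative (including gap
columns in the denominator) would only rescale the features nonlinearly:

* sequence identity and sequence similarity (fraction of positive-scoring
  pairs),
* normalized aligner score (raw score / aligned columns),
* secondary-structure agreement between the *predicted* target state
  (sliding-window Chou-Fasman propensities) and the template's assigned
  state,
* burial agreement between predicted target burial (windowed
  Kyte-Doolittle hydropathy, buried above 0) and template relative
  accessibility binarized at 0.25,
* target coverage.

For ranking, each feature is turned into a conditional probability density
of the *realized* structural similarity: calibration records are binned
into 10 equal-count bins of the feature value, and within each bin the
similarity labels get a Gaussian kernel density with Silverman bandwidth,
reflected at 0 and 1 so no mass leaks outside the unit interval. Stored
grid densities (101 points on [0, 1]) are renormalized to integrate to
exactly 1. A feature's relevance is the absolute Spearman correlation
between feature and label over the calibration set; degenerate (constant)
features get relevance 0 and a flat density. The joint log-density is the
relevance-weighted sum of per-feature log-densities, and the global model
quality estimate (GMQE) is the grid argmax, with ties resolved towards the
lower similarity. The grid argmax is verified against a 10x-resolution
scan in the tests.

The structural-similarity label used for calibration is the global lDDT of
the model a template can produce (its coordinates mapped through the true
alignment) against the known target structure. This ties the estimate to
the same score used for evaluation.

On fixture benchmarks the joint estimate ranks realized model quality
better than raw sequence identity alone -- the motivation for combining
several features. We calibrate on 300 generated pairs and evaluate on 100
held-out pairs; these sizes keep the per-bin densities stable (30 labels
per bin) while the whole experiment stays in the two-minute range.

## Model building

Building is conservative coordinate transfer:

1. **Backbone**: aligned target residues take the template's N, CA, C, O
   coordinates. Deletions are skipped; insertions stay unmodelled.
2. **Side chains**: identical residues copy the template side chain;
   substituted residues are truncated to a CB placed with ideal tetrahedral
   geometry (1.53 Å bond); glycine gets no CB. No rotamer optimization is
   attempted -- the per-residue provenance states
   (`aligned_copied`, `substituted_truncated`, `interpolated`,
   `unmodelled`) make the simplification visible to scoring.
3. **Short gaps**: insertions of up to 3 residues between modelled anchors
   get evenly spaced interpolated CA positions with idealized N/C/O along
   the segment; longer insertions remain open and are reported as chain
   breaks. This stands in for loop modelling, which is out of scope.
4. **Oligomer**: if the interface decision (below) predicts conservation,
   the monomer is superposed onto every template polymer chain by Kabsch
   superposition over shared CA pairs and one rigid copy is emitted per
   chain. Homo-oligomeric templates are assumed to share residue numbering
   across chains.
5. **Ligands**: only `biologically_relevant` ligands are considered. The
   coordinating residues are the template polymer residues with any heavy
   atom within 4.0 Å of the ligand; transfer requires *every* coordinating
   residue to be aligned to an identical target residue (strict "all
   conserved" reading, chosen deliberately as the conservative variant).
   The ligand keeps its template-frame coordinates and is accepted only if
   no model heavy atom comes within 2.2 Å (clash) and at least one lies
   within 4.5 Å (contact); 2.2/4.5 Å bracket the expected range of van der
   Waals and water-mediated interactions. All three distances are
   arguments with these defaults. Rejections carry machine-readable
   reasons, and mutating any coordinating residue can only flip a
   placement to a rejection, never the reverse (tested).

## Oligomeric state prediction

Each inter-chain interface of the template assembly (chains sharing a
heavy-atom contact within 5.0 Å) is described by four features: sequence
identity and similarity restricted to aligned interface residues, mean
Kyte-Doolittle hydrophobicity of the interface residues, and the consensus
fraction -- how many other template hits contain an equivalent interface,
where equivalence means at least 50% of the interface's aligned target
positions are shared. A random forest (200 trees, seeded) maps these
features to a conservation probability; its training labels come from the
synthetic interface table generator (a logistic link on identity and
consensus), and users can retrain on their own labeled tables. The final
decision takes the size-weighted average of per-interface probabilities
(sizes = interface residue counts) and predicts the template's oligomeric
state when the average strictly exceeds a threshold of 0.5. Both the
cutoff and the threshold are arguments; 5.0 Å is the customary heavy-atom
contact definition and 0.5 is the natural probability midpoint.

## Quality estimation

Three potentials of mean force are trained by inverse Boltzmann statistics,
`-log((observed + 1)/(reference + 1))` per bin with pseudocount 1 (so no
bin is infinite and uniform counts give exactly zero):

* **distance**: CB-CB (CA for glycine) pairs at sequence separation >= 3,
  0.5 Å bins on 0-20 Å, conditioned on the unordered residue-type pair,
  against a type-agnostic reference. The CB-only representation keeps the
  statistics dense enough for small training sets; an all-atom term is an
  extension point.
* **torsion**: phi/psi in 30-degree bins per residue type against a uniform
  reference. Chain continuity follows residue numbering, not geometry: a
  distorted peptide bond still has torsions, and they should score badly
  rather than be skipped.
* **burial**: relative-accessibility bins of 0.1 per residue type against a
  type-agnostic reference.

Bin indices round the quotient before flooring so that values sitting
exactly on a bin edge (common in ideal-geometry fixtures) cannot flip bins
under numeric jitter from rigid motions.

Per-residue raw terms are averaged over a centred window of 9 residues
(truncated at termini) and combined through a logistic into a reliability
score in [0, 1]; higher is better. The default weights (0, -1, -1, -1)
simply negate the pseudo-energies; `fit_weights()` refits them by logistic
regression of a good/bad indicator (true per-residue lDDT >= 0.6) on the
windowed terms of a decoy battery. The decoy battery alternates globally
and locally perturbed structures, because locally confined errors are what
a windowed per-residue score must resolve; with only globally noised decoys
the three terms are nearly collinear across residues and the fit does not
generalize. The global score is the mean per-residue score, and the
Z-score relates it to a battery of well-formed reference structures using
the population standard deviation (so the reference members themselves
standardize to mean 0, sd 1). A combined estimate
`logistic(w0 + w1 * GMQE + w2 * global)` with non-negative slopes merges the
alignment-based and structure-based estimates; the slopes are truncated at
zero after fitting so the combined score is always monotone in both inputs.

## Evaluation

Model-vs-reference comparison uses the local Distance Difference Test: all
reference heavy-atom pairs from different residues within a 15 Å inclusion
radius are assessed at thresholds 0.5, 1, 2, 4 Å; a distance is preserved
when the model reproduces it within the threshold, and missing model atoms
count as violations. Per-residue scores average over the thresholds and the
distances involving that residue; the global score aggregates over all
assessed distances. The implementation is superposition-free and hence
exactly invariant under rigid motions, which the tests verify together
with a brute-force recount on 4-residue toys. The stereochemistry-violation
exclusion of the original formulation is omitted -- a documented
simplification appropriate for fixtures without side-chain chemistry.
Kabsch superposition (SVD with reflection guard) is provided for
visual-comparison use cases and the oligomer assembly step.

## The fixture generator

`make_toy_structure()` builds ideal-geometry backbones (helix -57/-47,
strand -119/113, loop -120/60; Engh-Huber-like bond lengths and angles)
with CB stubs, sequences drawn from fold-element-biased residue pools so
that sequence-based property prediction has genuine signal.
`make_homolog()` derives a template by conservative substitutions (drawn
from each residue's highest-scoring BLOSUM62 exchange partners), short
deletions, and Gaussian coordinate noise, recording the true alignment and
the realized lDDT label. `make_benchmark()` couples substitution rate,
deletion rate and coordinate noise to a common divergence draw with
independent lognormal jitter on each channel -- the way sequence and
structural divergence co-vary in real homolog sets; the defaults (ceilings
of 0.5 substitutions per site, 0.06 deletion starts per site, 2.6 Å noise)
give labels spanning roughly 0.2-1.0. `make_complex()` packs helix copies
around an axis at a deterministically searched offset so adjacent chains
share at least 5 residue contacts at 5 Å, and can nest a small ligand
against an outward helix face with at least 3 coordinating residues within
4 Å at a clash-free distance.

What the fixtures do *not* emulate: real side-chain chemistry and rotamers,
compact tertiary packing of long loops, hetero-oligomers, experimental
noise models (B-factors, missing density), and the breadth of real fold
space. Passing tests therefore demonstrate internal correctness and the
stated statistical properties of the methods on controlled inputs, not
modelling accuracy on natural proteins.

## Problem sizes and numerical choices

The shipped experiments use: 300/100 calibration/evaluation pairs for
GMQE, 20 training structures for potentials, 20 native/decoy pairs for
discrimination, a 500-row interface table, and SASA sampling at 48-64
points for annotation (256 for user-facing calls). These sizes were chosen
so each experiment completes in minutes on one core while leaving the
statistical conclusions stable across seeds. Degenerate inputs are handled
explicitly: empty alignments and single-class training tables raise
errors; constant calibration features get zero relevance; empty potential
bins are covered by the pseudocount; interfaces whose residues are entirely
unaligned are excluded from the oligomer decision with a warning, and a
target with no scoreable interface defaults to a monomer prediction.

## Indexing convention

All sequence and residue positions in the package are 1-based and
inclusive, the R convention (and that of bio3d and Biostrings). Author
residue numbering from input files is preserved alongside and used in all
written output.
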