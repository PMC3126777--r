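---
title: "paraloop: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{paraloop: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cyclin-dependent kinase 4 (Cdk4) is the paralog of the Cdk4/Cdk6/Cdk2
family whose loss protects against epithelial carcinogenesis, yet kinase
inhibitors directed at it have underperformed — which motivates looking for
a *kinase-independent* functional site: a region conserved across Cdk4
orthologs within mammals but divergent both in non-mammalian orthologs and
in the sister paralogs. `paraloop` implements that discovery route as a
reusable pipeline:

1. **Sequence stage** — build or ingest a multiple alignment of grouped
   sequences; score per-column conservation inside the target in-group;
   scan for windows that are conserved in-group but divergent against every
   contrast row. On a Cdk4-style family this surfaces a proline/arginine
   rich 12-residue window whose central hexamer is Pro-Arg-Gly-Pro-Arg-Pro.
2. **Structure stage** — build a comparative (homology) model of the target
   on a template, assign secondary structure, compute solvent
   accessibility, and find exposed coil segments.
3. **Nomination** — intersect divergent windows with exposed surface loops
   and rank the candidates.

The package also covers the tabular biology around such a site: an
anchored co-expression regression screen across a cell-line panel, an
expression-ratio-shift biomarker, and compound-response tables with dose
normalisation and structure-activity rules.

## Sequence scanning

Conservation is **mean pairwise identity** per alignment column (not
entropy): a gap paired with anything scores 0, gap-gap pairs are excluded
from the denominator, and an all-gap column scores 0 and is flagged. This
mirrors the informal identity language used when such regions are described
("well conserved" / "little or no conservation") and keeps every score in
\[0, 1\]. Profiles are smoothed with a 5-column moving average by default.

The scan statistic per column is `d = c_in - c_cross`, where `c_in` is
in-group conservation and `c_cross` the mean identity between the in-group
consensus and each contrast row. Windows (default 12 columns) are scored by
the mean of `d`; windows at or above `min_score` (default 0.5) are merged
into maximal runs. A merged run is then **trimmed to its divergent core**:
the outermost columns whose own `d` meets `min_score`. Without trimming,
any window overlapping a strongly divergent 12-mer by six or more columns
also passes the threshold, and the merged report would smear the site over
roughly twice its true width; trimming recovers the implanted span exactly
while still collapsing overlapping hits into one report. `min_score = 0.5`
is recorded in the interface and was chosen so that a strongly divergent
window (in-group conservation near 1, contrast identity near background)
passes while background fluctuation does not.

The progressive aligner builds a guide tree from 3-mer distances with
average-linkage clustering and aligns profiles with an affine-gap global
dynamic program (BLOSUM62, gap open -10, gap extend -0.5; a gap run of
length L scores `open + ext * L`). Ties in the tree are broken by input
order, so the result is deterministic. The DP core is compiled code; the
two-row case is verified in the tests against an independent
Needleman-Wunsch implementation.

## The reduced structural model

Models carry backbone N, CA, C, O plus a **reduced linear side chain**: CB
and the unbranched chi chain of each residue type (for example lysine CB-CG-
CD-CE-NZ with chi1-chi4; valine CB-CG1 with chi1). Branch atoms are
omitted. This keeps every torsion well defined and the energy cheap while
preserving the features the pipeline actually uses — excluded volume,
exposure, chi statistics. Proline's ring is not closed covalently; its chi
angles are fixed and the CD-N contact lives in the nonbonded exclusion
graph only.

The energy model is deliberately reduced (three different published force
fields were used at different steps of the original protocol; reproducing
any of them literally is neither possible at this scale nor needed, and
absolute energies are explicitly not comparable):

* harmonic bond and angle terms to the builder's own ideal values
  (so an ideally built fragment has exactly zero strain);
* a 3-fold chi torsion term and a 2-fold omega restraint;
* a soft, repulsive-only nonbonded term engaged below 0.85 times the summed
  van der Waals radii, with 1-2/1-3/1-4 bonded paths excluded as in
  standard force-field practice;
* a Kabsch-Sander hydrogen-bond term (27.888 kcal/mol/A electrostatic
  form, amide H built geometrically, bond threshold -0.5 kcal/mol).
  Approaches compressed below 2.7 A (O...N) or 1.8 A (O...H) are treated
  as steric clashes, not bonds — with real amide hydrogens present they
  would be impossible — and each donor contributes at most one bond and
  each acceptor at most two, so the term is bounded and cannot reward
  bifurcated pile-ups.

**Which terms each minimiser sees.** The torsion-space minimiser is a
derivative-free cyclic coordinate search (coarse full-circle scan plus
golden-section refinement per torsion, chi angles before backbone angles),
so it optimises the *full* energy including the hydrogen-bond term — that
term is what makes native secondary structure a minimum in a model with no
attractive dispersion. The Cartesian steepest-descent finisher uses
analytic gradients and therefore minimises the differentiable subset; its
role is local regularisation (bond lengths, angles, clashes) after loop
insertion. Secondary-structure-preserving refinement optimises the strain
terms plus a penalty (default 10 kcal/mol) per *lost* input hydrogen bond:
it preserves the bond network rather than chasing deeper bond energies,
which would otherwise compress helices away from ideal geometry. Each
minimiser is monotone non-increasing in its own objective, and that is the
property the tests assert.

## Loop modelling

"Random tweak" closure is realised as random torsion sampling followed by
cyclic coordinate descent (CCD): loop phi/psi are drawn from a coil-like
region (phi in (-155, -45), psi in (-60, 170)), the span plus the
downstream anchor backbone is rebuilt at ideal geometry, and CCD rotates
each torsion in turn to bring the rebuilt anchor N/CA/C onto its fixed
position (closed-form optimal rotation per torsion). A conformer is
accepted when the anchor RMSD is at or below 0.3 A. Conformers are ranked
by the full model energy of the closed backbone; side chains are built on
the winner only, as in the original protocol. A second round resamples
within +/-20 degrees of the winning torsions and keeps the better result,
followed by a short Cartesian touch-up that regularises the closure-junction
peptide bond. Defaults: 200 samples in round one, half in round two; all
sampling is bit-reproducible for a fixed seed.

The comparative-model driver runs: thread onto the template (conserved
residues copy atoms, mutations keep the backbone, insertions stay unbuilt,
deletions leave an annotated break) → rotamer side-chain placement →
torsion minimisation → loop modelling of unbuilt spans and break junctions
→ secondary-structure refinement → Cartesian finish, iterating until the
relative energy improvement drops below 1e-4 or 10 cycles. Side chains are
placed *before* the first backbone minimisation so clash relief is bought
with chi rotations, not backbone motion.

## Rotamer library

The library is built by chi enumeration — chi1 on a 30-degree grid, higher
chi angles at the three staggered states — pruned of rotamers that clash
with the residue's own backbone in an ideal dipeptide context. A full
10-degree enumeration over up to four chi angles would be combinatorial
(36^4 entries per type) without changing any behaviour the pipeline
depends on; the bin widths and the realised library size are recorded as
metadata rather than claimed to match any external count. Placement
assigns each residue its lowest-local-energy rotamer (repulsion against
the fixed environment plus the chi term, with the same bonded-path
exclusions as the global energy), sweeping residues buried-first until no
assignment changes or 10 sweeps.

## Structure evaluation

* **Secondary structure** is three-state: helix from runs of at least two
  consecutive i→i+4 turns, strand from Kabsch-Sander bridge patterns,
  otherwise coil. The eight-state refinement adds nothing the pipeline
  uses (loop identification and bond-preserving refinement).
* **Accessible surface area** is Shrake-Rupley sampling (default 960
  points per atom, probe 1.4 A) computed in a canonical principal-axes
  frame with moment-based sign fixing, which makes the sampled area
  *exactly* invariant under rigid-body motion rather than invariant only in
  the many-points limit. Relative exposure divides by extended Gly-X-Gly
  maxima computed with the same reduced atom model, so the normalisation is
  self-consistent.
* **Superposition** is the closed-form Kabsch SVD solution with the
  reflection guard.
* **The threading score** is a distance-binned (1 A bins, 3-15 A) CB-CB
  mean-force potential over residue pairs at least 3 apart in sequence.
  Because no curated experimental training set ships with the package, the
  default potential is compiled from a deterministic *synthetic*
  mini-reference set: helix-pair fragments whose sequences follow burial
  (hydrophobic interface, polar surface). It ranks a compact fold above
  its sequence-shuffled rethreading in at least 90 percent of shuffles —
  the property the pipeline needs — but its absolute values are not
  comparable to potentials trained on real structures, and the quality
  report says nothing else with it.
* **The quality report** computes the full assessment battery: threading
  score, total energy, backbone RMSD to the template, structure Z-scores
  (packing from CB neighbour counts, Ramachandran favoured-region
  fraction, chi-to-nearest-rotamer deviation, phi/psi basin log-likelihood;
  positive means better than the reference average) and RMS Z-scores (bond
  lengths, bond angles, omega, side-chain planarity of sp2-terminated
  chains, the CA chirality improper, and the hydropathy-classed
  inside/outside exposure; near 1 means reference-like spread). Reference
  means and SDs ship as a versioned JSON file computed once from a
  deterministic synthetic ensemble (jittered helices, buried-interface
  helix pairs, helix-loop structures with library rotamers perturbed by
  8-degree noise). The Z-scores therefore measure "distance from this
  package's reference ensemble", with the same directionality as the
  published batteries but magnitudes of their own.

## Site nomination

A divergent window becomes a candidate site when its mapped residue span
overlaps an exposed coil run (length >= 6, mean relative ASA >= 0.25) by at
least half the window; the site spans the overlap. The rank score is
`divergence x mean relative ASA x (1 + Pro/Arg composition)` — the
multiplicative form is this package's own quantification of evidence that
the source analysis combined verbally, and it is monotone in each evidence
stream. The N-lobe/C-lobe tag uses a configurable boundary defaulting to
two thirds of the chain, matching the "C-terminal third" framing.
Exposure thresholds are stand-ins: no numeric definition of "solvent
accessible in all models" exists to inherit.

## Synthetic data: what it does and does not emulate

The family generator draws a uniform ancestor, implants the in-group
window sequence (default the 12-mer at residues 249-260 of a 300-residue
chain, mirroring the Cdk4 narrative), keeps it fixed in-group, and mutates
by uniform replacement — background rate 0.05 per site, contrast-row
divergence 0.9 inside the window (expected in-group identity about 0.90,
window cross-identity below 0.2). There are no indels, no rate matrix and
no phylogenetic correlation, so alignment-error robustness is *not* what
the recovery tests demonstrate; they demonstrate that the scan statistic
finds a genuinely divergent window against realistic background noise.
Expression panels are log-normal (densitometry is positive and
right-skewed) with partners constructed as anchor-plus-noise, the noise SD
solved for the target correlation; the panel defaults (16 lines, anchor
CDK1, one r = 0.9 partner) reproduce the study design qualitatively — the
underlying densitometry values were never published, so the quantitative
pattern (only the correlated partner significant after Bonferroni) is the
claim under test. Toy structures are built from ideal geometry and
specified torsions; they contain no experimental noise, missing atoms or
alternate conformers.

## Numerical choices and degenerate inputs

* Closure tolerance 0.3 A (anchor N/CA/C RMSD); spans that cannot
  geometrically reach the anchor (3.8 A per residue plus one bond) error
  out before sampling.
* Torsion line search: 12-point coarse scan plus 10 golden-section
  iterations; a torsion already optimal on the coarse grid is skipped.
* Steepest descent: backtracking halving with 1.2x growth on acceptance;
  termination on gradient norm 1e-4, step exhaustion, or the step budget
  (default 500).
* Ties everywhere break deterministically: equal-score windows by start
  column, equal-energy rotamers by lowest library index, consensus ties
  alphabetically, hexamer ties by most-central-then-leftmost start.
* Duplicate ids, non-standard residues (anything outside the 20 codes plus
  X), unitless doses and unknown viability codes are rejected with
  positions; empty files yield empty objects with a warning.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state.

## Problem sizes used in the checks

The shipped checks run on deliberately small instances chosen to exercise
every code path with comfortable margins: 16-sequence x 300-column
families (50 seeds for the recovery rate), 16-line panels (100 seeds for
the flag rate, 1000 for the null), an 18-residue self-modelling target, a
30-residue template with a 12-residue insertion for the end-to-end build
(100 loop samples, 2 cycles), and 240-point ASA sampling where the area
enters a threshold rather than a closed-form comparison. These sizes are
the package's validation design, not limits of the implementation.

## Known limitations

* The reduced side-chain representation cannot measure true rotamer
  statistics of branched residues, ring planarity, or aromatic packing.
* The energy model has no attractive dispersion or electrostatics beyond
  the hydrogen-bond term; folds are maintained by hydrogen bonds and
  excluded volume, which suffices for refinement around a template but not
  for ab initio folding.
* The statistical potential and the quality-report reference statistics
  are trained on synthetic ensembles; their absolute values are
  package-internal scales.
* Chain chirality follows a single internal convention; all scoring is
  distance-based and therefore chirality-blind.
* The aligner is a textbook progressive method without iterative
  refinement; for deeply divergent families a dedicated aligner will do
  better, and pre-aligned input is accepted everywhere.
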