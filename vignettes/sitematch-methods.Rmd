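---
title: "Matching ligand binding sites into scaffolds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching ligand binding sites into scaffolds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitematch)
```

## The matching model

A binding site is a ligand plus the protein residues that form favorable
interactions with it, treated as one rigid body: all of its heavy atoms move
under a common rotation and translation, and its internal geometry (the
original side-chain rotamers) is never re-sampled. Matching a site into a
scaffold asks whether the scaffold backbone can hold the site's residues in
their observed geometry; the scaffold's own side chains are assumed
redesignable and are ignored beyond C&beta;.

`fast_match_site()` enumerates every (site residue, scaffold residue) anchor
pair. For each anchor, the site-residue N/C&alpha;/C triad is superposed onto
the scaffold residue's triad by least squares, the rest of the site follows
rigidly, and the placement passes four gates in order:

1. every site residue must find a scaffold C&alpha; within
   `ca_distance_cutoff` (2 Å), with an injective nearest-residue mapping;
2. the joint least-squares superposition of all site N/C&alpha;/C atoms onto
   their mapped scaffold counterparts must reach RMSD
   &le; `backbone_rmsd_cutoff` (1 Å) — the placement is updated to this
   optimal superposition;
3. every pair of corresponding C&alpha;&rarr;C&beta; unit vectors must have
   cosine > `cb_cosine_cutoff` (0.7), so that redesigned side chains will
   point the right way;
4. the ligand and site side-chain heavy atoms must not clash with backbone
   heavy atoms (N, C&alpha;, C, O) of scaffold residues outside the
   correspondence, a clash being a distance below `clash_scale` (0.6) times
   the sum of the two Lennard-Jones radii.

Accepted placements are deduplicated by correspondence, keeping the
lowest-RMSD representative; rejection stages are tallied for diagnostics.
Design choices worth stating: the correspondence must be injective because
two site residues cannot be designed onto one scaffold position; the anchor
superposition is a true 3-point least-squares fit (not a frame alignment),
consistent with the later full-backbone superposition; C&beta; is excluded
from the scaffold "backbone" in the clash gate because it belongs to the
designable side chain; glycine and residues missing C&beta; get an ideal
constructed C&beta; (1.521 Å bond, tetrahedral geometry, L-chirality) so
the direction gate and the burial cone are defined for every residue.

Superposition itself is the closed-form SVD (Kabsch) solution with the
determinant correction that forbids reflections. Degenerate inputs (fewer
than 3 points, collinear point sets) are rejected rather than silently
fitted.

### Scale and iteration order

`match_library()` iterates scaffolds in a seed-shuffled order and records,
per site, the 1-based index of the first successful scaffold (the
first-encounter number). Encounter numbers depend on that order, so the seed
is part of the result and is recorded in the matrix's column order. With
`stop_at_first` the remaining scaffolds are skipped and marked untested;
statistics that need a complete matrix (subset resampling) refuse untested
cells.

## The interaction-score proxy

Library construction needs a per-residue interaction score to decide which
contact residues belong to a site. The package ships a documented proxy on
heavy atoms with three components:

* **attraction** — a 6-12 well `eps * ((rmin/d)^12 - 2 (rmin/d)^6)` with
  `rmin` the sum of the two element radii, truncated at 8 Å and capped at
  zero, so the term is attractive-only (well depth `lj_eps` = 0.5 energy
  units); the positive (repulsive) part is tracked separately;
* **electrostatics** — Coulomb with a distance-dependent dielectric,
  `coulomb_k * q_i q_j / d²` (`coulomb_k` = 33.2), over a minimal charge
  table: carboxylate oxygens −0.5, lysine N&zeta; +1, arginine NH1/NH2 +0.5,
  metal ions at ionic charge, and element-level partial charges on ligand
  atoms;
* **hydrogen bonds** — a bonus of up to −1 for N/O⋯N/O pairs between 2.4 and
  3.5 Å, distance-ramped and gated by the angle at the ligand partner's
  covalent neighbor.

A residue joins a site when its total is below `include_threshold` (−1) and
is discarded as poorly modeled when total + repulsion exceeds
`residue_quality_cutoff` (+50) or when heavy atoms are missing. The proxy's
*scale* is its own: these thresholds are configurable precisely because the
proxy is not a calibrated molecular-mechanics energy, and site counts
extracted from real structures will not numerically reproduce counts
obtained with such an energy function. The scorer is an argument
(`params`) everywhere, so a different implementation can be substituted
without touching the extraction logic. The remaining extraction filters are
exact numbers, not proxy-dependent: resolution better than 2 Å, 1–100 ligand
heavy atoms, mean heavy-atom B-factor &le; 60 Å², contacts within 5 Å, at
least 2 residues per site, one site per distinct ligand per structure
(deduplicated by ligand name and binding-residue composition).

Multi-chain sites are kept for matching but `mean_sequence_distance()`
refuses them, since a primary-sequence separation across chains is
undefined; this keeps the sequence-distance statistic clean without silently
dropping sites.

## Burial layers and secondary structure

The burial measure is side-chain independent: residue *i*'s weighted
neighbor count sums, over all other residues *j*, a distance factor
`1 / (1 + exp(d - 9))` (d = C&alpha;ᵢ–C&alpha;ⱼ in Å) times an angle factor
`((cos θ + 0.5) / 1.5)²` (θ between C&alpha;ᵢ&rarr;C&beta;ᵢ and
C&alpha;ᵢ&rarr;C&alpha;ⱼ, clamped to 0 for cos θ &le; −0.5). Counts below 2
are surface, above 5.2 core, otherwise boundary; the thresholds are
arguments with those defaults. A matched site's depth score is the number of
boundary positions plus twice the number of core positions among its matched
scaffold residues — 0 for a fully surface-exposed match, 6 for a 3-residue
site matched entirely into the core.

Secondary structure labels are a deliberate simplification: a residue is
helix for φ ∈ [−100°, −30°], ψ ∈ [−80°, 0°], strand for φ ∈ [−170°, −90°],
ψ ∈ [90°, 180°], else loop, with termini and short chains loop. This is a
dihedral heuristic, not a hydrogen-bond-based assignment, and will disagree
with DSSP near element boundaries; it exists to support descriptive
summaries, not structure assignment.

## Ligand fingerprints and clustering

Ligands are compared by 1024-bit fingerprints at Tanimoto distance
(1 − |a∧b|/|a∨b|; two empty fingerprints have distance 0 by convention) and
clustered with Butina's greedy leader algorithm at a distance cutoff of
0.65: neighbor lists at the cutoff, candidates sorted by neighbor count
(ties by ligand id, which also makes the output independent of input
order), largest neighborhood first, members within the cutoff of their
centroid by construction. The default fingerprint backend hashes, for each
atom, the multiset of (element, binned distance) pairs inside growing radial
shells — deterministic, and invariant under rigid motion because it uses
only interatomic distances. It is a backend, not a standard: fingerprints
are not comparable across backends, and an implementation of a published 3D
fingerprint can be plugged in where available. The scientific content —
distance definition, cutoff, clustering algorithm — is independent of the
backend.

## Statistics

`fit_power_law()` fits ordinary least squares in (log₁₀ n, log₁₀ count); the
exponent is the slope, `predict()` extrapolates. OLS on the log-log scale is
the appropriate estimator here because the quantity of interest is the slope
of the log-log plot itself. `overlap_test()` compares the observed number of
sites matched by two scaffold sets against the independence expectation
n_a·n_b/N with a 2×2 chi-squared test (1 df, no continuity correction);
degenerate margins return statistic 0 rather than NaN.
`resample_subsets()` draws scaffold subsets without replacement,
independently across replicates, deterministic per seed.

## Synthetic fixtures: what they emulate, and what they do not

`make_scaffold()` builds poly-alanine backbones with ideal covalent geometry
from internal coordinates (helix −57/−47, strand −120/+120, and an
antiparallel two-helix bundle with a 10.2 Å axis offset and a chain break
between the helices). `dihedral_sigma` draws per-residue φ/ψ around the
canonical values, deforming medium-range geometry smoothly while keeping
bonds and angles ideal — the package's emulation of geometric variation
within a fold family. `plant_site()` copies chosen residues and grows a
carbon pseudo-ligand chain that touches every site residue within 5 Å,
keeps 3.2 Å clearance from non-site backbone (comfortably above the 2.4 Å
carbon–carbon clash threshold), stays out of the repulsive wall of the site
residues, and is re-drawn until every site residue scores below the library
inclusion threshold — so planted sites are recoverable by extraction and
self-match by construction. `perturb()` adds seeded isotropic Gaussian
noise; `make_match_matrix()` gives Bernoulli matrices for testing the
statistics layer in isolation.

What passing tests on these fixtures shows: the geometry, the gates, the
bookkeeping and the statistics are correct. What it does not show: behavior
on real structures — real side chains beyond C&beta;, non-ideal covalent
geometry, alternate conformations, waters and metals in sites, and fold
families whose variation is richer than dihedral jitter. Library counts and
match rates on real data additionally depend on the interaction-score proxy
(above).

## The synthetic matching study

`scripts/acceptance.R` fixes the study conditions: two families of ten
members each (26-residue helices, 40-residue bundles; dihedral jitter 4°,
members re-drawn until free of steric self-overlap between
sequence-distant residues — the synthetic analogue of designability
filtering of scaffold libraries); twelve planted sites, half on helix faces
(sequence-local (i, i+3, i+4) and spread (i, i+3, i+6) variants, ligands of
1–7 atoms) and half spanning the bundle groove, where the member-specific
helix packing makes cross-matching selective; extraction and top-3 reduction
through the default filters; all-against-all matching without early exit.
These sizes keep the full study under a minute on one CPU while leaving
every statistic non-degenerate (helix-face sites match broadly, groove
sites selectively). The seed is the only source of randomness.

## Numerical choices and degenerate inputs

* Ties in the nearest-residue search go to the lower scaffold index; ties in
  top-k selection to (score, sequence index) ascending; ties in Butina to
  the lexicographically smaller ligand id.
* `superpose()` requires &ge; 3 non-collinear points and never returns a
  reflection; identical point sets give the identity transform.
* PDB reading resolves altlocs to the highest-occupancy conformer, drops
  hydrogens and waters, renumbers residues 1..n per chain (author numbering
  and insertion codes are discarded — all sequence-distance statistics use
  contiguous counting), and flags residues missing N/C&alpha;/C as
  non-matchable instead of failing.
* Coordinates round-trip through PDB at format precision (10⁻³ Å); tests
  assert equality at that tolerance only.
* Distance computations guard against zero division (d clamped at 10⁻⁶ Å in
  the scorer; zero-length direction vectors are an error, not NaN).

## Known limitations

Single-conformer, rigid-ligand matching only; no rotamer re-sampling (by
design — the protocol screens; a rotamer-based matcher consumes the emitted
constraint files for confirmation). No mmCIF input, no NMR multi-model
handling, nucleic acids are not scaffolds. The secondary-structure assigner
is not DSSP. The interaction proxy is ordinal rather than calibrated:
suitable for ranking residues within a site and for thresholding with its
own defaults, not for comparing energies across systems.
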