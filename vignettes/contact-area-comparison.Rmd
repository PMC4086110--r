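---
title: "Contact-area comparison of macromolecular structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-area comparison of macromolecular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadscorer)
```

## The model

Superposition-based similarity measures (RMSD and its descendants) compare
two structures of the same molecule after fitting them as rigid bodies,
which makes them sensitive to hinge and loop motions that are biologically
unremarkable.  `cadscorer` instead compares the *physical interactions*
within each structure: the set of residue–residue contacts and their
strengths, expressed as contact areas.  Two structures that preserve the
same contacts with the same areas are considered identical regardless of
how the rigid pieces are arranged, so the score requires no superposition
at all.

### Contact areas

Atoms are modelled as balls of van der Waals radius.  For each heavy atom a
*contact sphere* is constructed with radius equal to the vdW radius plus
the standard water probe radius of 1.4 Å.  The surface of this sphere is
partitioned: a surface point belongs to neighbouring atom $j$ if the point
lies inside $j$'s own expanded sphere (meaning a water molecule cannot fit
between the two atoms there) and $j$ minimises the additively weighted
distance $d(p, c_j) - r_j$ — the Voronoi-of-balls criterion.  Points
claimed by no neighbour are solvent-accessible.  The area of each region,
in Å², is the interatomic contact area; summed over atom pairs grouped by
residue it gives the residue–residue contact areas.  Interatomic contacts
corresponding to the covalent bond between sequence-adjacent residues
(the peptide C–N bond, the phosphodiester O3'–P bond) are excluded, since
they are present in any conformation and carry no signal.

### The score

Let $T_{(i,j)}$ and $M_{(i,j)}$ be the contact areas of the directed
residue pair $(i,j)$ in the target (reference) and model, with
$M_{(i,j)} = 0$ when the pair is not in contact in the model, and let $G$
be the set of pairs with $T_{(i,j)} > 0$ (optionally restricted by an
evaluation mode).  The global score is

$$\mathrm{CAD} = 1 -
\frac{\sum_{(i,j) \in G} \min(|T_{(i,j)} - M_{(i,j)}|,\, T_{(i,j)})}
     {\sum_{(i,j) \in G} T_{(i,j)}}$$

Bounding each per-pair difference by the target area keeps the score in
$[0,1]$: 1 means identical contacts; 0 means every reference contact is
entirely lost or overshot by at least its own area.  The score is
deliberately asymmetric — $G$ always comes from the first argument.

Per-residue *raw local errors* $\delta(i)$ sum the bounded differences
over residue $i$'s outgoing pairs, and *normalized local errors*
$\varepsilon(i) = \delta(i) / \sum_j T_{(i,j)}$ lie in $[0,1]$.  Both can
be smoothed along the sequence with a window of $w \in \{0,1,2,3\}$
residues on each side; the smoothed normalized error is a ratio of
windowed sums, not a mean of per-residue ratios, so large-contact residues
dominate the windowed value just as they dominate the global score.

### Subset variants

Contacts can be restricted to atom subsets on either side: all atoms (A),
main chain / backbone (M), or side chain / base (S), giving the variants
A-A, A-M, A-S, M-M, M-S and S-S.  For nucleic acids the base–base (S-S)
contacts are further split into stacking and non-stacking geometry.
Ligand (HETATM) residues have no main/side split and therefore only
participate in the A-A variant.

## Tunable parameters

* `waterRadius` (Å, default 1.4): the water probe radius added to every
  vdW radius.  1.4 Å is the standard rolling-probe value.
* `samplingDensity` (points per sphere, default 2000): the surface
  quadrature resolution.  Each point carries $4\pi R^2/n$ Å², about
  0.06 Å² for a carbon contact sphere, so individual areas at the default
  density are accurate to a few tenths of Å²; density 2000 keeps a
  20-residue comparison around a second while staying within ~2 % of
  closed-form two-atom areas.
* vdW radii: a bundled per-element table (C 1.70, N 1.55, O 1.52, P 1.80,
  S 1.80, default 1.80 Å), overridable in `assignRadii()`.  The method
  compares like with like, so scores are insensitive to the exact radius
  dialect as long as target and model use the same table.
* Stacking thresholds (`classifyStacking()`): base-plane normals within
  30° and centroid offset within 40° of a normal.  The stacking/
  non-stacking split is standard for nucleic acids but its geometric
  criterion is not canonical; these defaults separate face-to-face
  stacks from coplanar Watson–Crick pairing cleanly on idealized
  geometry and are exposed as arguments.

## Numerical choices

The Voronoi-style partition is realized by deterministic surface
quadrature (a Fibonacci sphere lattice) rather than an exact Apollonius
diagram.  The quantities the method needs are *areas on the contact
sphere*, which the quadrature approaches with known resolution; the
partition is exhaustive and exclusive by construction, so per atom the
contact and solvent areas always sum to exactly $4\pi R^2$, and the
self-comparison score is exactly 1 at any density.  Ties in the weighted
distance are broken toward the lowest atom index, making output fully
deterministic.  Two atoms with identical centers make the partition
degenerate and are rejected.  An empty reference set (e.g. interface mode
on a single chain, or S-S on a glycine-only chain) yields an explicit
"undefined" status — never silently 0 or 1.  At chain termini the
smoothing window truncates to the residues that exist and renormalizes by
the actual count and actual area sums; windows never cross chain
boundaries.

Residues present in the target but missing from the model lose all their
contacts ($M = 0$); model residues absent from the target are ignored.
Model/target correspondence is by chain, residue number and insertion
code; residue-name disagreements abort scoring unless mismatches are
explicitly tolerated (point-mutant comparisons).

## The synthetic generators

The package ships deterministic generators used throughout its tests:

* `makeTwoAtomSystem()` — two isolated balls, for which the contact area
  has a closed form (a spherical cap, `sphericalCapArea()`).
* `makeToyPeptide()` — an extended poly-alanine chain with idealized
  covalent geometry (C–N ≈ 1.33 Å) and CB side chains, plus a small
  seeded jitter (≤ 0.05 Å) so different seeds give distinct structures.
* `makeToyDuplex()` — a two-chain ladder of planar six-membered base
  proxies with minimal backbones: consecutive bases within a chain are
  parallel planes 3.4 Å apart (stacking geometry), paired bases across
  chains are coplanar (non-stacking geometry).
* `perturbStructure()` — per-atom uniform displacement in
  $[-m, m]^3$.  Uniform rather than Gaussian noise: bounded support makes
  degradation orderings robust, and only orderings are asserted, never
  absolute scores.
* `bruteForceContactOracle()` — an independent, prune-free implementation
  of the sphere partition run at very high density, used only to
  cross-validate the engine.

These fixtures emulate the *contact topology* of real molecules —
covalent adjacency, main/side subsets, chain interfaces, base stacking —
but not real chemistry: no torsional preferences, no hydrogen-bond
geometry, no realistic packing density.  Passing tests therefore
demonstrate the correctness of the geometry, scoring and selection
machinery, not predictive performance on experimental structures.

## Problem sizes and verification

The test suite verifies, among others: two-atom areas against the
closed-form cap across a radius/distance grid (within 2 % relative or
0.5 Å², the quadrature floor, at density 2000); engine/oracle agreement
on random 3–5 atom clusters (5 % or 0.5 Å²); exact per-atom area
conservation; exact self-comparison identity; the algebraic identity
between the global score and the aggregated local errors (to 1e-12);
score range on 100 randomized target/model pairs; and strict decrease of
the mean A-A score of a 20-residue peptide over 10 seeds across
perturbation magnitudes 0, 0.25, 1 and 3 Å.  These sizes keep the whole
suite under a minute while leaving every property at full strength —
scores on toy peptides of 8–20 residues are already well away from both
endpoints of the scale.

## Known limitations

* Quadrature, not algebra: individual contact areas carry sampling noise
  of a few lattice quanta; the *score* is far less sensitive because
  numerator and denominator share it, but single tiny contacts
  (< ~0.5 Å²) are at the resolution limit at the default density.
* The stacking criterion is a documented geometric stand-in, not a
  community-standard definition.
* One altloc ('A' or blank) and the first MODEL only; no structure
  repair, no symmetry expansion, no mmCIF.
* Disulfides and other non-backbone cross-links are *not* excluded as
  covalent contacts; only the sequence-adjacent backbone bonds are.
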