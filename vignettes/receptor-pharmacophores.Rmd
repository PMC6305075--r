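---
title: "Receptor-only pharmacophore generation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-only pharmacophore generation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apophore)
```

## The problem and the model

A pharmacophore is the abstract ensemble of steric and electronic features a
molecule must present to bind a target: hydrogen-bond donors (HBD) and
acceptors (HBA), positive and negative charge centres, hydrophobic regions
and aromatic rings. Ligand-derived pharmacophores require a solved complex
and inherit one observed binding mode; `apophore` instead derives the model
from the receptor's binding pocket alone, so it works on apo structures and
describes every interaction the pocket could in principle make.

Two independent lines of evidence are combined:

* **Energetic evidence** — a probe map. Each of five probe types is scored on
  a lattice filling the pocket against the complementary receptor atoms
  (donor probe vs acceptor atoms, positive probe vs anionic groups, and so
  on). High-scoring clusters mark locations where a ligand atom of that
  chemistry would sit well.
* **Geometric evidence** — hybridization projection. Each polar or charged
  pocket atom projects the positions a partner atom would ideally occupy,
  from its SP2 or SP3 geometry: in-plane lone pairs at 120° for carbonyl and
  carboxylate oxygens, the exterior bisector for two-neighbour ring
  nitrogens, π normals for planar cations, a tetrahedral fan for hydroxyls
  and ammonium nitrogens. Hydrogens are never read from the file; apo
  crystal structures rarely have them, so ideal directions stand in.

A polar feature enters the final model only when both lines agree to within
3 Å. Hydrophobic features need no directional confirmation and pass through;
hydrophobic points surrounded by enough aromatic atoms, near a ring whose
plane faces the pocket, additionally carry an aromatic feature. The result is
a compact six-type model; `prune_model()` reduces it further to the
strongest features per type when a minimal query is wanted.

### The hydrogen-bond cone

The action scope of a projected hydrogen-bond site is a cone: the donor-bound
hydrogen at the apex, the site centre P1 at distance `d + e` from the donor
heavy atom (`d` the covalent X–H length, `e` the hydrogen-to-partner reach),
and a base circle of radius `c` bounding the lateral tolerance. The derived
quantities are the slant `a² = (d+e)² + c²`, the apex half-angle
`tan(A) = c/(d+e)`, and the half-angle seen from the hydrogen `tan(C) = c/e`,
which caps the acceptable deviation from linearity: the D–H···A angle must be
at least `B = 180° − C`. With the operating values `c = 1.5` Å and
`e = 2.0` Å this gives `C ≈ 37°` and `B ≥ 143°` (boundary inclusive, since
the minimum is stated as attainable). The looser physical floor — hydrogen
bonds break as the angle approaches 90° — is subsumed by this stricter bound.
`d` is not separately fixed by the operating point; we default to 1.0 Å, a
typical N–H/O–H covalent length, and expose it in `cone_geometry()`.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| score thresholds | 0.15 (HBD/HBA), 0.2 (hydrophobic), 0.5 (POS/NEG) | score | stage-1 filter; values strictly below are zeroed |
| neighbour thresholds | 30/30/40/5/5 | count | stage-2 filter; survival needs strictly more same-type nonzero neighbours |
| `neighbor_radius` | 2.0 | Å | neighbour-counting radius |
| `representative_radius` | 2.5 | Å | non-maximum-suppression radius |
| `merge_radius` | 3.0 | Å | pt1/pt2 agreement distance (inclusive) |
| `aromatic_search_radius` | 4.5 | Å | aromatic-atom count and ring association |
| `min_aromatic_atoms` | 6 | count | aromatic upgrade requirement |
| `aromatic_max_angle` | 60 | deg | ring-normal-to-pocket-centre half-cone |
| `c`, `d`, `e` | 1.5, 1.0, 2.0 | Å | cone geometry (above) |
| `probe_sigma` | 0.8 | Å | Gaussian well width of the probe scorer |
| `probe_cutoff` | 5.0 | Å | probe interaction cutoff |
| `clash_factor` | 0.7 | — | clash when distance < 0.7 × (vdW sum) |
| `bin_width`, `tol` | 0.5, 1.5 | Å | triangle-hash bin and match tolerance |

The score and neighbour thresholds, the 2.5 Å suppression radius, the 3 Å
merge, the 4.5 Å / n ≥ 6 aromatic rule and `c`/`e` are the method's operating
point; the remaining values are this implementation's documented defaults.
The neighbour-count radius is not part of the published operating point; 2.0
Å (a four-cell radius at the default 0.5 Å lattice pitch, ~250 cells) makes
counts of 30–40 geometrically attainable and is config-exposed.

## The probe scorer

The scorer is deliberately transparent rather than force-field-grade. Each
complementary atom within the cutoff contributes a Gaussian well
`g(r) = exp(−(r − r_ideal)² / 2σ²)` centred at the ideal contact distance
(2.9 Å heavy-to-heavy for hydrogen bonds, 3.5 Å for charge contacts, the
vdW-radius sum for hydrophobic contact). Contributions combine as a
complementary product (noisy-OR), `1 − ∏(1 − gᵢ)`: the score stays in
[0, 1] — so the published thresholds read directly as fractions of a perfect
contact — reduces to `g` for a single atom, and is strictly monotone in every
pair term. We chose the complementary product over hard saturation of a sum
because saturation creates exact-tie plateaus wherever two atoms are
simultaneously near-ideal; a degenerate arg-max makes representative
selection depend on tie-breaking and destroys the rotation-covariance the
pipeline otherwise has. The scorer sits behind a single interface
(`build_probe_map()`) so a calibrated energy function can be substituted
without touching the filter.

No angular weighting is applied at this stage: directionality is enforced
downstream by the projection and merge, which keeps the two stages
independently testable.

## Determinism and numerical choices

* **NMS ordering.** Points are processed by score descending, ties broken by
  lexicographic (x, y, z), then grid index; output is therefore independent
  of grid-point input order.
* **Boundary conventions.** Score threshold keeps the boundary (strictly
  below is zeroed); neighbour count requires strictly greater; suppression,
  merge, aromatic count and the 143° angle are boundary-inclusive, each with
  a 1e-9 guard against floating-point grazing.
* **"In at 2.5 Å"** is read as a suppression radius (greedy NMS), not as
  2.5 Å clustering followed by a centroid; the representative is an observed
  maximum, not an average.
* **Containment.** A projected site counts as inside the pocket when it lies
  within one lattice pitch of some grid point — the simplest testable
  definition that needs no surface construction.
* **Merge semantics.** "Intersected within 3 Å" keeps the pt1 coordinate and
  score (the energetic evidence) and copies the nearest pt2 direction (the
  geometric evidence); Figure-style single spheres per region follow from
  NMS spacing, which the merge preserves (pt3 ⊆ pt1), so no re-suppression
  is run.
* **Feature naming** is ligand-side throughout: a receptor donor projects an
  HBA feature (the region where a ligand acceptor should sit), a receptor
  anionic group projects a POS feature, and the probe names follow the same
  convention, so the merge compares like with like.
* **Degenerate inputs.** An empty PDB parses to an empty structure; an empty
  pocket is an error (a pocket must have ≥ 1 point); an empty model is valid
  (with a warning) and serializes to valid JSON; collinear feature triples
  are indexed but never seed a superposition; matching with fewer than three
  features returns fit 0.
* **EF conventions.** `N_sampled` uses the ceiling; ranking ties are broken
  by ligand id. Both are unstated in the usual definition and fixed here for
  determinism.
* **Fit normalization.** `fit_score = n_matched / n_model_features`, so a
  fragment matching three of six features scores 0.5 and partial ligands
  cannot trivially reach 1.0. Multi-conformer input is scored per conformer,
  keeping the maximum.

His ring nitrogens are treated as both donor and acceptor (protonation is
not modelled); a configuration switch marks the ring cationic instead. The
residue→role tables are a documented, editable default
(`apophore:::AROMATIC_RING_ATOMS` and relatives in `R/structure.R`); vdW
radii are Bondi-style and matter only through the clash test, since the
empirical `e = 2.0` Å absorbs them in the projection.

## What the synthetic generator emulates — and what it does not

`make_toy_pocket()` builds a spherical cavity (default radius 6 Å, lattice
pitch 0.5 Å) ringed by side-chain fragments whose functional groups face
inward: a His imidazole (donor + acceptor through its ring nitrogens, whose
two-neighbour exterior bisector projects straight into the pocket), an Asp
carboxylate, an Arg guanidinium with its π normal inward, a Leu isopropyl
fork and a Phe ring facing the cavity. Each environment contributes
ground-truth entries (expected type, approximate position, tolerance: 3.5 Å
for polar/charged sites, 3.0 Å for hydrophobic/aromatic — the slack between
a grid-derived representative and the idealised interaction site). A small
rigid per-residue jitter (σ = 0.05 Å, seeded) breaks the lattice's mirror
symmetries so arg-maxima are unique and determinism is testable. Arg rather
than Lys is the default cationic wall: the guanidinium's on-axis π
projection makes the 3 Å merge geometrically well-posed, whereas an
ammonium's tetrahedral fan leaves an uncovered gap along the bond axis wider
than the merge radius; Lys remains available as an environment.

`make_screening_fixture()` emulates an active/decoy benchmark at desk scale:
actives are the model's feature set under seeded Gaussian noise (default
σ = 0.3 Å, well inside the 1.5 Å match tolerance) and a random rigid motion;
decoys keep the feature count but permute types and resample positions in
the model's bounding box. Defaults are 20 actives and 100 decoys, a 1:5
ratio that caps EF at 6.

Passing tests on these fixtures demonstrates the pipeline's internal
correctness — recovery of planted chemistry, determinism, equivariance,
metric definitions — not performance on real proteins: the fixtures have no
backbone solvation, no competing sub-pockets, no conformational strain, and
their decoys are not property-matched the way a curated decoy directory's
are. Real-data behaviour also depends on the upstream cavity detection,
which is an input here, and on the probe scorer's calibration.

## Problem sizes in the shipped tests

The default test run uses the 6 Å toy pocket (~7,200 lattice points, ~30
receptor atoms; model generation ≈ 2 s), 100 random ≤ 200-point probe maps
for the filter oracle, and twenty 120-ligand seeded libraries for the
screening check. These sizes were chosen to exercise every code path at
interactive speed; the pipeline itself is vectorised over grid points and
scales to larger pockets linearly in points × atoms, with the neighbour
filter quadratic in the nonzero points per type.

## Known limitations

* Protonation states, tautomers and pKa shifts are not modelled; role tables
  are fixed templates.
* The probe scorer is a surrogate, not a calibrated energy; absolute scores
  should not be compared across receptors.
* Ligands are rigid single conformers at screening time; no conformer
  generation is included.
* Pocket size matters: very large cavities (several times a typical ligand
  volume) produce many features, which dilutes the fit-score normalisation —
  prune or sub-divide such pockets.
* Water-mediated interactions are deliberately ignored (the method works
  from the dry receptor), so features that require a bridging water will not
  be found.
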