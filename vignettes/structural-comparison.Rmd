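---
title: "Comparative structural analysis of troponin crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative structural analysis of troponin crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

The cardiac troponin complex — TnnC (calcium binding), TnnI (inhibitory)
and TnnT (tropomyosin binding) — is the sarcomere's calcium switch.
Deletion of lysine 210 in TnnT2 (K210del) causes dilated cardiomyopathy
through decreased calcium sensitivity, and the structural route from a
deleted residue on TnnT to impaired calcium handling on TnnC is an
allosteric one: a local lesion at the deletion site remodels a hinge
(TnnT 220–228, TnnI 82–91), shifts the TnnI/TnnT coiled-coil (ITarm),
rotates the TnnC N-lobe that carries the activation EF-hand, and finally
distorts the Ca²⁺ coordination sphere itself, flipping the S69 side chain
out of the pocket so that one coordination bond is lost and the remaining
bonds lengthen. A drug that re-establishes the wild-type hinge
conformation restores the coordination geometry.

`tncomp` packages the measurements needed to make each link of that chain
quantitative and reproducible from coordinates alone:

1. **Residue pairing across a deletion** (`pair_residues`): global
   Needleman–Wunsch alignment (match +1, mismatch −1, gap −2; ties prefer
   the diagonal, then the gap in the longer chain) so that author
   numbering offsets created by the deletion never contaminate any
   downstream per-residue comparison.
2. **Superposition with outlier rejection** (`kabsch`,
   `iterative_align`): closed-form least-squares rotation (SVD with
   reflection correction), then cycles that discard residue pairs
   deviating more than `reject_sigma` standard deviations and refit —
   the procedure behind "r.m.s.d. X Å over N of M Cα" statistics.
3. **Backbone geometry difference profiles** (`chain_geometry`,
   `geometry_diff`): φ/ψ/ω dihedrals and the three backbone bond angles
   per residue, differenced with circular wrapping and standardised to
   z-scores per chain; residues with any |z| above a threshold are
   flagged.
4. **Metal coordination** (`find_metal_sites`, `coordination_sphere`,
   `compare_sites`, `sidechain_flip_metric`): calcium ions located and
   labelled (Ca1 = activation site near TnnC 60–80; Ca2/Ca3 = C-lobe
   structural sites), oxygen ligands enumerated with exact distances, and
   sites differenced so a side-chain flip appears as a lost or regained
   ligand with its χ1 change.
5. **Contact networks** (`classify_contacts`, `contact_diff`): ionic,
   hydrogen-bond and hydrophobic contacts by distance criteria, keyed per
   residue pair and type, with gained/lost sets mapped through the
   pairing.
6. **Domain rotation** (`domain_rotation`): superpose a rigid core, fit
   the domain separately, and read the angle/axis off the relative
   rotation matrix.
7. **Calcium titrations** (`fit_hill`, `normalize_fluorescence`,
   `compare_pca50`): variable-slope sigmoid fits in pCa with pCa₅₀ and
   Hill-slope extraction and error propagation for sensitivity shifts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `reject_sigma` | 2.0 | σ | conventional 2-sigma outlier rule for iterative superposition |
| `cycles` | 5 | – | enough for the retained set to stabilise on structures this size |
| `min_deviation` | 0.01 | Å | floor below which pairs are never rejected (numerical noise) |
| coordination `cutoff` | 3.2 | Å | Ca–O coordination distances are 2.3–2.9 Å; 3.2 captures weak ligands while excluding second-shell atoms |
| ionic / hbond / hydrophobic cutoffs | 4.0 / 3.5 / 4.5 | Å | standard literature distance criteria |
| `z_threshold` | 2.0 | σ | conventional flagging threshold |
| `core_selection` | TnnT 199–272 + TnnI 40–135 | – | the ITarm coiled-coil, the most rigid shared scaffold |
| `domain_selection` | TnnC 1–89 | – | the N-lobe carrying the activation EF-hand (D67/S69/E76 ligands) |

Residue numbering is author numbering throughout (K210, S69, hinge
220–228/82–91 are author-numbered labels); alternate locations resolve to
the highest-occupancy conformer (ties to the alphabetically first
altloc); waters are excluded from protein coordination counts and from
contact analysis.

Where a published comparison leaves its parameters unstated (rejection
settings behind specific retained-Cα counts; the coordination cutoff
behind specific bond counts), the defaults above are this package's
documented operationalisation, and the acceptance checks against
deposited structures calibrate within narrow, stated windows (cycles
3–10, sigma 1.5–2.5; cutoff 2.8–3.5 Å) rather than treating any single
setting as uniquely correct.

## Numerical choices

* **Rejection statistic.** Per-pair deviations are departures from a
  perfect fit, so the "deviation standard deviation" used for rejection
  is taken about zero (the RMS deviation). The standard deviation about
  the *mean* collapses toward zero on near-perfect alignments and ejects
  well-fitted pairs wholesale; an absolute floor of 0.01 Å guards the
  same degenerate regime.
* **Dihedral convention.** IUPAC: cis = 0°, trans = ±180°, sign by the
  right-hand rule. Angular differences are wrapped into (−180°, 180°], so
  Δ(179°, −179°) is 2°, never 358°.
* **Ramachandran regions.** A simplified four-region box partition
  (alpha, beta, left-alpha, other), documented in
  `chain_geometry`, rather than probability contours — the comparisons
  here need only qualitative region shifts. "Planarity" is
  operationalised as mean |ω − 180°| (`omega_planarity`).
* **Rotation angle and axis.** Angle from the trace of the relative
  rotation matrix, axis from its antisymmetric part; axes of rotations
  under 0.5° are flagged unreliable because the antisymmetric part
  degenerates.
* **Hill fitting.** `y = bottom + (top − bottom)/(1 + 10^(s·(x −
  pCa₅₀)))` fitted by Levenberg–Marquardt from a deterministic 5-point
  pCa₅₀ start grid; the best convergent start by residual sum of squares
  wins, and the fit is reported in the canonical orientation top >
  bottom. With 7 titration points and 4 parameters there are 3 residual
  degrees of freedom, so 95% confidence intervals use the t quantile
  (≈3.18·SE); a ±2·SE band is only an ~86% interval at that sample size.
* **Degenerate inputs.** Collinear point sets, chains without backbone
  atoms, constant titration series, sub-5-point series and all-rejected
  alignments raise errors rather than returning numbers.

## What the synthetic generators emulate — and what they do not

`build_two_protomer_complex` reproduces the *layout* of the troponin
crystal asymmetric unit: two protomers of a TnnC/TnnT/TnnI triple related
by a known rigid motion, chains spanning the crystallised construct's
author numbering (TnnC 1–161, TnnT 183–288, TnnI 32–166), an optional
single-residue deletion that leaves the numbering gap in place exactly as
K210del does, an optional rigid rotation of the TnnC N-lobe (default
conditions use 4°, the magnitude of the published mutant-versus-wild-type
lobe rotation), and optional isotropic coordinate noise.
`build_metal_site` reproduces the *geometry* of an EF-hand coordination
sphere — serine-like oxygen ligands at exact distances in octahedral or
pentagonal-bipyramidal arrangements, mirroring the 6-bond/2.6 Å intact
and 5-bond/2.9 Å distorted activation sites. `build_titration` evaluates
the exact Hill model plus seeded Gaussian noise (R's Mersenne-Twister via
`rnorm`, so any reimplementation can match distributions, not bit
streams).

These fixtures are deliberately idealised: chains are mathematical
helices without side-chain packing, protomers are exact rigid copies, and
deformations are applied surgically. Tests passing on them demonstrate
that the *measurements* are correct — that a 10° rotation is reported as
10.00°, that a deleted residue is localised exactly, that a flipped
serine appears as precisely one lost ligand — not that real crystal
structures will show any particular value. The checks against the
deposited troponin structures (8FMM, 8FMN, 8FMO, 1J1D) close that gap;
they require the coordinate files locally (see the note at the top of
`tests/testthat/test-acceptance.R`) because depositions are too large to
bundle and the test suite never downloads.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on generated
fixtures: two-protomer complexes of 2×402 residues (backbone atoms only),
50-point clouds for the superposition oracle (20 seeds), a 500-replicate
Hill Monte Carlo at 7 points per titration with noise at 3% of the
response amplitude, and 8-case parameter sweeps per generator. These
sizes give stable statistics (Monte-Carlo SE of the recovered pCa₅₀ mean
≈ 0.001) while keeping the whole suite around a minute on one CPU.

## Known limitations

* Hydrogen positions are absent from crystallographic models at these
  resolutions, so hydrogen bonds use a distance criterion only; no
  donor–H–acceptor angle term is applied.
* Histidine is treated as charged for ionic contacts (protonation is not
  knowable from coordinates); a neutral mode is available.
* Protomer grouping assumes compact chain triples; heavily interdigitated
  assemblies would need an explicit chain-to-protomer map.
* No sequence-independent structural alignment, hinge localisation along
  the chain, bond-valence scoring, or assembly generation from symmetry
  operators — these are outside the package's scope.
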