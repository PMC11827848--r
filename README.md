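# tncomp

Comparative structural analysis of troponin crystal structures.

## What this is for

The cardiac troponin complex — TnnC, TnnI, TnnT — is the calcium switch
of the sarcomere, and single-residue troponin mutations cause dilated
cardiomyopathy by blunting calcium sensitivity. The K210 deletion in
TnnT2 is the archetype: the lesion sits on TnnT, but its consequence is
allosteric, reaching across the complex to distort the activation
Ca²⁺-binding EF-hand of TnnC (the S69 side chain flips out of the
coordination pocket, one Ca–O bond is lost, the remaining bonds
lengthen), and a structural corrector drug reverses exactly these
changes. Establishing each link of that chain from coordinates requires a
specific toolkit of measurements, and `tncomp` provides them as one
tested, scriptable pipeline for structural biologists comparing a mutant
(or drug-bound) structure against a reference:

* gap-aware **residue pairing** across a deletion (Needleman–Wunsch,
  deterministic tie-breaks), so author-numbering offsets never corrupt
  per-residue comparisons;
* **Kabsch superposition with iterative outlier rejection**, producing
  the "r.m.s.d. X Å over N of M Cα" statistics used to compare protomers
  and structures;
* per-residue **backbone dihedral/bond-angle difference profiles** with
  per-chain z-scores and outlier flagging;
* **calcium coordination-sphere** enumeration, site labelling
  (activation Ca1 vs structural Ca2/Ca3), differential ligand sets and a
  side-chain flip metric (χ1 + O→metal distance);
* **contact classification** (ionic / hydrogen bond / hydrophobic) with
  gained/lost contact sets between structures;
* **rigid-body domain rotation** of the TnnC N-lobe after superposing
  the ITarm core (angle and axis from the relative rotation matrix);
* **Hill fitting** of calcium-titration fluorescence and force–pCa data
  (variable-slope sigmoid in pCa, pCa₅₀ ± SE, sensitivity differences
  with propagated errors).

The Hill model is `y = bottom + (top − bottom) / (1 + 10^(s·(x −
pCa₅₀)))` with `x` in pCa; superposition minimises `Σ‖a_i − (R b_i +
t)‖²` over proper rotations via SVD.

A synthetic-fixture module (`build_helix`, `build_metal_site`,
`build_two_protomer_complex`, `build_titration`) generates
coordinate models with known ground truth — engineered deletions, exact
domain rotations, exact coordination geometries — so the entire analysis
surface is testable offline.

## Worked example

```r
library(tncomp)

# a two-protomer troponin-like complex, and a variant carrying the K210
# deletion plus a 4-degree rotation of the TnnC N-lobe, with 0.1 A
# coordinate noise
wt  <- build_two_protomer_complex(seed = 1)
mut <- build_two_protomer_complex(
  deletion_at = list(role = "TnnT", resseq = 210),
  domain_rotation_deg = 4, noise_sd = 0.1, seed = 1)

pair_residues(wt, mut, chain_a = "T", chain_b = "T")
#> residue_pairing: 105 pairs, 1 unpaired in A, 0 unpaired in B
#>   unpaired A: T:LYS210

pp <- pair_protomers(wt, mut, assign_roles(wt), assign_roles(mut))
iterative_align(wt, mut, pp)
#> alignment_result: rmsd 0.176 A over 316 of 401 pairs (CA atoms, 4 rejection cycle(s))

domain_rotation(wt, mut, pp)
#> domain_rotation: 4.05 deg about [-0.007 -0.008 1.000] (core rmsd 0.179 A over 168 CA; domain 89 CA)

site <- build_metal_site(6, 2.6, "octahedral")
coordination_sphere(site, find_metal_sites(site)$serial[1])
#> coordination_site [unassigned]: 6 protein bond(s), mean 2.60 A (cutoff 3.20 A)
```

Reading: the pairing isolates exactly the deleted lysine; the iterative
alignment reports the deviation statistic over the residues that
superpose rigidly (the rotated N-lobe and deletion-adjacent residues are
rejected as outliers, which is the point — they are the signal); the
domain-rotation stage recovers the engineered 4° to within the noise;
and the coordination sphere returns the exact constructed ligand count
and mean distance. `run_comparison()` chains all stages over real PDB or
mmCIF files and writes a JSON report with full parameter provenance; the
same stages are exposed as subcommands of
`inst/scripts/tncomp.R` (`align`, `geomdiff`, `casite`, `casite-diff`,
`contacts`, `contacts-diff`, `domainrot`, `hillfit`, `fixtures`,
`compare`).

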