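Package: tncomp
Title: Comparative Structural Analysis of Troponin Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing crystal structures of the cardiac troponin
    complex (TnnC/TnnT/TnnI), built around the question of how a single-residue
    deletion in one chain propagates allosterically to the calcium-binding
    machinery of another. Provides gap-aware residue pairing across a deletion,
    Kabsch superposition with iterative outlier rejection, per-residue backbone
    bond-angle and dihedral difference profiles with z-score flagging, calcium
    coordination-sphere enumeration and differential comparison, inter- and
    intra-chain contact classification (ionic, hydrogen bond, hydrophobic) with
    gained/lost contact sets, rigid-body domain rotation quantification after
    core superposition, and variable-slope sigmoid (Hill) fitting of calcium
    titration and force-pCa data. A synthetic-fixture generator produces
    coordinate models (ideal helices, metal sites, two-protomer complexes with
    engineered deletions and domain rotations) so every analysis is testable
    without downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
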