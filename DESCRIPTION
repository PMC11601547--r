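Package: steerkit
Title: Physics-Steered Diffusion Sampling and Evaluation for Biomolecular
    Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference-time steering of diffusion samplers for biomolecular
    structure generation and the surrounding data-pipeline and evaluation
    machinery.  Implements Feynman-Kac sequential Monte Carlo particle
    resampling with gradient guidance over seven flat-bottom constraint
    potentials (chirality, bond stereochemistry, double-bond planarity,
    ligand distance-geometry bounds, steric clash, chain overlap, covalent
    cross-chain bonds), Kabsch-aligned reverse-diffusion interpolation,
    symmetry-aware all-atom LDDT scoring with greedy chain and ligand-atom
    assignment, PoseBusters-style physical-quality checks, pocket-aligned
    ligand RMSD, dense taxonomy-based MSA pairing, unified spatial and
    contiguous cropping, and robust pocket conditioning.  A synthetic-fixture
    module generates toy complexes with injectable physical violations and
    toy denoisers so every operation runs without trained model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    bio3d,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
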