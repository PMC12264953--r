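Package: scaffhop
Title: Scaffold Hopping with a Reward-Steered SMILES Language Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Generative scaffold hopping for medicinal chemistry. A recurrent
    SMILES language model is steered by reinforcement learning toward designs
    that keep a reference ligand's peripheral decorations and 3D
    shape/pharmacophore profile while replacing its core scaffold. The package
    implements a fuzzy decoration-matching scaffold decomposition algorithm, a
    staged reward combining 2D scaffold dissimilarity (ECFP Jaccard distance)
    with 3D shape and pharmacophore-color overlay similarity through a
    weighted harmonic mean, an augmented-likelihood policy-gradient training
    loop with a Bemis-Murcko diversity filter and inception memory, and
    design-set evaluation metrics including Scaled Shannon Entropy scaffold
    diversity and scaffold retrieval curves. Chemistry primitives are backed
    by OpenBabel through ChemmineR/ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: OpenBabel command-line tools (obabel) for 3D conformer
    generation and minimization.
Config/testthat/edition: 3
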