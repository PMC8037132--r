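Package: pepmpc
Title: Peptide Association with Monolayer-Protected Gold Nanoclusters
Version: 0.1.0
Authors@R:
    person("pkg", "maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale modelling toolkit for the association of short
    catalytic peptides with cationic monolayer-protected gold nanoclusters
    (Au-MPCs). Builds coarse bead models of peptides and an idealized
    Au144(L)60 cluster with formal-charge accounting and counterion
    bookkeeping, performs flexible Brownian-dynamics docking with a
    screened-electrostatics plus desolvation interaction energy, Metropolis
    conformer exchange and GROMOS-style pose clustering, and provides the
    full trajectory analysis suite used for such systems: centre-of-mass
    association profiles with change-point stage segmentation, shape
    descriptors (SASA, radius of gyration, end-to-end distance, dihedrals),
    mean-squared-displacement and rotational diffusion fitting,
    ligand-contact statistics, pair correlation functions, hydrogen-bond
    counting, conformational clustering and Go-model native-contact
    analysis. Synthetic trajectory generators with known ground truth
    (free and rotational diffusion, staged association, conformer
    switching, bound complexes with persistent contact patches) support
    end-to-end validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
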