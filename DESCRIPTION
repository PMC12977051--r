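Package: condact
Title: Conditional Activity Analysis of Kinetic Correlations in Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies time-resolved kinetic correlations (conditional
    activity) between residues of proteins and nucleic acids from molecular
    dynamics trajectories.  Side-chain chi1 (protein) and glycosidic (DNA)
    dihedral angles are discretized into rotamer states; the resulting
    transition times act as per-residue kinetic clocks from which persistence
    times, exchange times, the directional conditional-activity matrix,
    per-residue dynamical memory, principal-eigenvector domain scores,
    a mutual-information baseline, circular-shift permutation significance
    and distance-resolved coupling profiles are computed.  Includes a
    renewal-process simulator for generating synthetic transition records
    and noisy dihedral series with known kinetic structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
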