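Package: ecdyn
Title: Essential Collective Dynamics Analysis of Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segment-wise principal component analysis of molecular dynamics
    trajectories and the essential collective dynamics (ECD) descriptors built
    on it: projected per-atom images in principal-component space, main-chain
    flexibility profiles of C-alpha atoms, and dimensionless pair-correlation
    maps, with segment averaging over a trailing analysis window.  Includes a
    deterministic builder for unfolded alpha-synuclein monomer, dimer (HH/HT)
    and tetramer starting constructs, a harmonic-network overdamped Langevin
    generator of synthetic fluctuation trajectories with closed-form stationary
    covariance (the validation oracle), mean shortest-distance maps, RMSD
    traces, and secondary-structure occupancy statistics from externally
    assigned DSSP-style timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
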