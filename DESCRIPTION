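Package: hydrofilm
Title: Lattice Spin-Model Simulation of Hydrophobin Film Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained modelling of class II hydrophobin (HFBI/HFBII)
    film formation at the air-water interface. Implements a triangular-lattice
    spin model in which each site is vacant or carries one of six protein
    orientations, with trimer, P6-docking and metastable low-density
    P3-docking interactions, Metropolis Monte Carlo dynamics built from
    protein-mimicking trial moves (adsorption/desorption, monomer diffusion,
    rigid trimer diffusion), and cluster-growth analytics (connected
    components over attractive bonds, percolation detection, linear versus
    exponential growth-law classification, coarsening exponents). Also
    provides the continuous-space hexagonal-lattice geometry used to reason
    about the six-protein unit cell, reference P6 and P3 crystal tilings,
    synthetic fixture generators, and an end-to-end scenario runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
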