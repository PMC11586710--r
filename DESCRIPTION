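Package: suGaussRPB
Title: Regularized Super-Gaussian Poisson-Boltzmann Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implicit-solvent electrostatics with a smooth, atom-packing
    dependent super-Gaussian dielectric model. Implements the
    density-dependent surface function, the regularized linearized
    Poisson-Boltzmann equation in which the singular Coulomb component is
    removed analytically, a finite-difference successive-over-relaxation
    solver with Dirichlet (Coulombic or dipolar) boundary conditions, and
    the reaction-field polar solvation free energy of a solute transferred
    from vacuum to water. Reads and writes PQR structures, exports
    volumetric fields in OpenDX format, and provides deterministic
    synthetic fixtures (Born ion, two-atom system, synthetic peptides) for
    validation against closed-form limits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, Matrix, Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
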