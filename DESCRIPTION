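Package: carpalfem
Title: Reduced Proximal-Carpal-Row Finite-Element Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and solves a reduced finite-element model of the proximal
    carpal row (radius, scaphoid, lunate, capitate) for studying the
    stabilizing role of the scapholunate interosseous ligament (SLIL).
    Provides parametric surrogate anatomy with ligament attachment landmarks,
    tetrahedral meshing with quality control, linear-elastic bone and
    compressible Mooney-Rivlin soft-tissue materials, a ligament spring
    network, motion-derived boundary conditions, a small implicit nonlinear
    tet4 solver with mechanism (under-constraint) detection, hydrostatic
    pressure post-processing, and linear stiffness estimation from uniaxial
    load-displacement curves with literature comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, jsonlite, Rcpp, stats, utils, graphics, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
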