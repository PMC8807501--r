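Package: osteoFE2
Title: Coupled Mechano-Electro-Magnetic Multiscale Modeling of Cancellous Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-scale (FE2) finite element modeling of cancellous bone with
    full coupling of mechanical, electric and magnetic effects. The microscale
    is a periodic two-phase representative volume element (piezoelectric
    cortical bone struts embedded in viscoelastic, electrically conducting
    marrow) discretized with trilinear hexahedra carrying seven degrees of
    freedom per node: displacement, electric scalar potential and magnetic
    vector potential. The transient coupled system is integrated with the
    JWH generalized-alpha scheme, homogenized effective tangents are obtained
    by numerical perturbation under periodic boundary conditions, and a
    macroscale driver simulates a cylinder benchmark across osteoporosis
    stages parameterized by the cortical bone volume fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
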