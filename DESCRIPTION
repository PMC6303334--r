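Package: nestsym
Title: Procrustes ANOVA for Nested Symmetries in Geometric Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decomposition of landmark-based shape variation in biological
    structures with simple or hierarchically nested symmetries (matching
    symmetry, object symmetry, and bilateral object symmetry nested within
    rotational matching symmetry). Provides partial generalized Procrustes
    alignment with tangent-space projection, symmetry-group bookkeeping
    (transform-and-relabel copies, symmetric/asymmetric subspace projectors),
    the corresponding mixed-model Procrustes ANOVA designs with Goodall's
    F tests and shape degrees of freedom, MANOVA with Pillai's trace on a
    generalized inverse, restricted permutation tests, centroid-size ANOVA,
    recovery of per-effect covariance matrices from expected mean squares
    with PCA of the resulting matrices, and a seeded synthetic-data
    generator for lantern-structured datasets with known variance
    components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, MASS, yaml
Suggests: testthat (>= 3.0.0), vegan, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
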