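Package: footform
Title: Form and Function Analysis of Normal and Bound Foot Archetypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated musculoskeletal biomechanics pipeline for studying
    how plantar loading shapes foot bone form and density. Provides a
    parametric synthetic-foot generator for normal (NF), half-bound (HB) and
    full-bound (FB) archetypes (superellipsoid bone surfaces, lattice
    tetrahedral meshes, Pedar-like plantar-pressure series, density phantoms);
    plantar-pressure gait analytics (regional peak and mean pressure, vertical
    ground reaction force, normalised centre-of-pressure trajectories, and a
    permutation cluster test for one-dimensional stance curves); rigid
    iterative-closest-point alignment, closest-point correspondence,
    statistical shape models and Hausdorff error maps for bone surfaces; a
    linear-elastic constant-strain tetrahedral finite-element solver with
    plantar pressure loads, plantar-fascia spring connectors and Achilles
    loading; and an iterative strain-adaptive bone-remodelling simulation with
    a lazy zone and density-modulus coupling. File I/O covers STL (ASCII and
    binary), an Abaqus .inp subset, pressure CSV, VTK and PLY.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
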