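Package: molcraft
Title: Headless Molecular Editing, Quantum Orbital Evaluation and
    Isosurface Extraction
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable core for building and analysing molecular
    structures without a graphical interface. Provides an editable
    molecule document with bonds, unit cells and derived properties;
    readers and writers for Chemical Markup Language (CML), XYZ,
    Gaussian cube and a minimal PDB subset; editor semantics such as
    valence-based hydrogen adjustment and fragment insertion;
    measurement, alignment and bond-centric geometry manipulation;
    parsing of Gaussian formatted-checkpoint output with evaluation of
    molecular orbitals and electron density on arbitrary grids;
    marching-cubes isosurface extraction with gradient normals; and
    export of ball-and-stick, stick, wireframe and van der Waals scene
    descriptions to POV-Ray.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
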