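Package: spinefem
Title: Parametric Lumbosacral Finite-Element Simulation of Spondylolisthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric finite-element analysis of isthmic spondylolisthesis
    progression at the lumbosacral junction. Builds a landmark-based model of
    the thoracolumbar spine and pelvis whose pelvic incidence, sacral slope
    and slip percentage can be varied, meshes the L4-pelvis segment with
    linear-elastic hexahedra (beam elements for the thoracic spine,
    tension-only springs for ligaments), applies a body-weight follower load
    tangent to the spinal curve, and maps normal and shear stress onto the
    L5 growth-plate local frame. A constrained factorial campaign driver with
    one-way ANOVA and correlation analysis relates spino-pelvic parameters to
    growth-plate and disc stresses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
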