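Package: phyllotrunk
Title: Recovering Phyllotactic Patterns from Tomographic Trunk Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Isolates the juvenile phyllotactic pattern embedded in the
    secondary growth of a tree trunk from a stack of tomographic slices.
    Provides seeded flood-fill pith tracking, Sobel-based trunk radius
    estimation, polar unwrapping of slices, construction of a cylindrical
    boundary image, Otsu segmentation of epicormic trace blobs, and the
    lattice mathematics of cylindrical phyllotaxy: divergence angle and
    rise statistics, Adler visibility intervals in exact rational
    arithmetic, parastichy families and intersection angles, conspicuous
    parastichy pairs and phyllotactic fractions, contact parastichies via
    periodic Delaunay triangulation on the cylinder, and detection of
    insertion-order permutation motifs. A synthetic trunk phantom
    generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    deldir,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'volume-io.R'
    'pith.R'
    'radius.R'
    'polar.R'
    'blobs.R'
    'lattice.R'
    'divergence.R'
    'parastichy.R'
    'cylinder-voronoi.R'
    'rational.R'
    'fibonacci.R'
    'motifs.R'
    'phantom.R'
    'phyllotrunk-package.R'
    'summary.R'
    'pipeline.R'
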