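Package: ringtier
Title: Quantitative Tier Geometry, Interface Burial and Native-MS
    Stoichiometry for Ring-Shaped Helicase Assemblies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative structural analysis of hexameric replicative
    helicase assemblies and their loader complexes. Fits planes and
    pseudo-helical parameters (rise, twist, pitch, radius) to ordered
    domain centers of mass, measures inter-tier angles, breach gaps,
    chamber diameters and subunit rotations; computes solvent-accessible
    and buried surface areas and interface residue footprints; performs
    native mass spectrometry stoichiometry arithmetic (average masses of
    proteins and single-stranded DNA, bounded composition decomposition,
    charge-series mass inference); and validates crosslinking-MS distance
    restraints against an atomic model. A synthetic-assembly generator
    provides ground-truth fixtures so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
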