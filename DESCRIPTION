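Package: c2netms
Title: Mass-Difference Network Annotation and Temporal Analysis of
    C2-Addition Chemistry in Ultrahigh-Resolution Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Untargeted analysis of evolving abiotic reaction mixtures from
    FT-ICR mass-spectrometry peak lists. Provides replicate filtering and
    spectral preprocessing, elemental-formula assignment by mass-difference
    network propagation (with a brute-force enumeration oracle),
    classification of 13C-labelling degrees from stable-isotope channels,
    compound-class reasoning over heteroatom subspaces (including sodium
    adduct logic for dicarboxylic acids and C2-homologous-series detection),
    construction of a time-resolved molecular network over six reaction mass
    differences, and self-organizing-map clustering of temporal intensity
    profiles. A synthetic-data generator emulating acetylene/CO/NiS
    C2-addition chemistry makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
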