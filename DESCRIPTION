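Package: covadduct
Title: Covalent-Adduct Chemoproteomics: Spectral-Count Enrichment,
    Crosslink Mass Search and Phosphatase Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping covalent cysteine adducts of electrophilic
    drugs such as sulforaphane. Implements peptide-spectrum-match (PSM)
    spectral-count differential enrichment with volcano-style significance
    gating, strict tryptic in-silico digestion with monoisotopic mass
    arithmetic, non-cleavable-linker crosslink candidate enumeration with
    MS1 precursor matching and b/y fragment annotation (used to localize a
    dithiolethione bridge between two cysteines of the phosphatase Shp2),
    a DiFMU standard-curve and one-phase exponential-decay inhibition fit,
    and seeded synthetic-data generators that plant known ground truth in
    every input format the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
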