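Package: lipropen
Title: Amino Acid Propensities for Protein-Lipid Contacts at Atomic Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects residue-phospholipid atomic contacts in protein
    structures with HBPLUS-style geometric criteria (hydrogen bonds, van
    der Waals contacts and salt bridges), partitions lipid atoms into
    hydrophilic head and hydrophobic tail groups from the molecular bond
    graph, and derives per-chain amino acid contact propensity scores for
    each group, both from single crystal structures (binary binding flags)
    and from multi-frame trajectories (fractional occupancies). Pooled
    counts are tested for over- or under-representation with a signed
    one-cell chi-square statistic, and propensity vectors are compared with
    each other and with experimental lipophilicity scales using Pearson
    correlation with jackknife standard errors. A synthetic-data module
    generates protein-lipid complexes and trajectories with known contact
    geometry for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
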