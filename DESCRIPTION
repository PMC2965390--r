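Package: clockcost
Title: Structural and Evolutionary Correlates of Protein Expression Cost
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the determinants of the protein molecular
    clock in bacteria: structure-derived descriptors (residue contact maps,
    contact density and contact order, Shrake-Rupley solvent accessible
    surface area, burial and residue-class fractions, secondary-structure
    loop fraction), ortholog and paralog evolutionary-rate analysis via
    Nei-Gojobori Ka/Ks estimation on codon alignments, rank-based
    association and partial-association statistics against gene expression,
    and growth-rate and synthesis-rate estimation from optical-density and
    band-intensity time series. Includes seeded synthetic-data generators
    (toy protein structures, diverged codon pairs, Gaussian-copula gene
    tables, paralog families, exponential growth curves) with known ground
    truth, so the whole pipeline is testable end to end without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
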