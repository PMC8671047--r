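Package: breakjoin
Title: Simulation and Analysis of Class Switch Recombination Junction Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing Smu-Salpha double-strand-break junctions from
    HTGTS-style (high-throughput genome-wide translocation sequencing) single-end
    read libraries. Provides a locus model for the IgH switch-region geometry, a
    generative simulator of class-switch junction libraries under classical
    non-homologous end joining (c-NHEJ) and alternative end joining (A-EJ) repair
    presets with per-read ground truth, a junction caller (bait anchoring, germline
    filtering, exhaustive prey mapping, microhomology and insertion resolution,
    deduplication), and summary statistics: deletion versus inversion orientation
    classification, binned junction landscapes, long-resection fractions,
    microhomology spectra, replicate-level t-tests and normalized class-switch
    efficiencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
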