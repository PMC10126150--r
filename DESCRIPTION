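Package: adscreen
Title: Analysis of Massively Parallel Aptamer-Switch Screens on Sequencing Flow Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links sequencing genotypes (FASTQ reads carrying tile and x/y
    coordinates) to per-cycle cluster fluorescence phenotypes (binary locs
    and intensity files), filters and ranks target-responsive aptamer-switch
    candidates by fold change with replicate RSD filters, characterizes top
    switching domains by complementarity mapping and Smith-Waterman local
    alignment against the parent aptamer, and fits one-site and two-site
    independent binding isotherms to plate-reader titrations. Includes a
    synthetic flow-cell screen generator with planted ground truth so every
    pipeline stage can be exercised and validated without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
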