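Package: cytobead
Title: Quantification of Stem Cell Interactions with Localised Ligand Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how single embryonic stem cells interact with a
    localised ligand source presented on a microbead: membrane position dynamics
    of the bead (distance-to-radius ratio, zone assignment, windowed means),
    cell and bead motility as mean squared displacement, bead retention versus
    dropping over a fixed post-uptake window, cytoneme number/length and
    population-level contact kinetics, mitotic spindle orientation relative to
    the bead with rose-plot binning and randomised-null testing, asymmetric
    cell division scoring from daughter-cell fluorescence partitioning, and
    qPCR fold changes. Includes a seeded synthetic-data generator that emulates
    manually tracked time-lapse microscopy output, CSV readers/writers for the
    four table formats, and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
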