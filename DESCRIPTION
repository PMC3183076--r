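Package: meihdna
Title: Crossover, Non-Crossover, and Heteroduplex DNA Calling from Meiotic
    Octad and Tetrad Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of meiotic recombination
    intermediates in two-parent fungal hybrids. Reads marker genotype tables
    for octads (mother/daughter cell pairs from each of the four spores,
    giving strand-level genotypes in mismatch-repair deficient crosses) or
    tetrads, calls per-marker segregation ratios (4:4, 5:3, 6:2, aberrant
    4:4*), segments them into strand-transfer tracts, and identifies
    crossover and non-crossover events with their heteroduplex DNA patterns.
    Pattern strings are classified into mechanistic classes (canonical and
    complex synthesis-dependent strand annealing, trans heteroduplex from
    double-SDSA or double Holliday junction dissolution, DSBR-compatible
    crossovers). Includes a strand-resolution meiosis simulator covering the
    major repair pathways with ground-truth logging for caller validation,
    plus summary statistics (class fraction tables, tract-length medians,
    exact rank-sum tests, chromosome-size regressions) and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
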