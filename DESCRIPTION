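Package: sryevol
Title: Molecular Evolution of Therian SRY: Stem-Branch Substitutions and
    Binding-Energy Bookkeeping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the molecular evolution of the mammalian
    sex-determining gene SRY and its SOX relatives. Provides amino-acid
    alignment handling (HMG-domain windows, clade similarity, complete
    deletion), pairwise Nei-Gojobori dN/dS on codon sequences,
    neighbor-joining tree construction with bootstrap support, Fitch
    parsimony ancestral-state reconstruction with mapping of substitutions
    onto stem branches (therian, marsupial, eutherian), exact 2x2 tests for
    substitution-tempo comparisons, MM/PB-SA binding-free-energy aggregation
    over molecular-dynamics snapshot energy tables, and seeded simulators
    that generate alignments, codon sets and energy tables with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
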