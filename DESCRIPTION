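Package: cistrans
Title: Cis- and Trans-Regulatory Divergence from Allele-Specific
    Expression in Subspecies Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to dissect regulatory divergence between closely related
    subspecies using RNA-seq of parents and their F1/backcross hybrids.
    Calls fixed diagnostic SNPs from parental allele observations, assigns
    hybrid reads to a parent of origin, and classifies genes into six
    regulatory-divergence categories (conserved, cis-only, trans-only,
    cis-and-trans, compensatory, ambiguous) with exact binomial and Fisher
    tests under Benjamini-Hochberg FDR control.  Also classifies hybrid
    expression inheritance (transgressive, additive, non-differential),
    computes per-chromosome target densities, goodness-of-fit tests and
    gene-cluster calls, and screens two-subspecies nucleotide and protein
    alignment panels for fixed differences, within-subspecies polymorphisms
    and subspecies-diagnostic haplotypes.  A negative-binomial/binomial
    simulator with known ground truth makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
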