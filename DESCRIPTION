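Package: hrcoreg
Title: Coordinated Expression Analysis of BRCA1/2 and Homologous
    Recombination Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying coordinated expression of BRCA1/2 and
    homologous-recombination (HR) genes in tumor expression panels:
    nCounter-style count normalization (negative-control background
    adjustment, positive-control scaling, housekeeping normalization,
    probe exclusion, replicate averaging), rank-based Welch differential
    expression with Bonferroni correction, complete-linkage hierarchical
    clustering on Spearman correlation distances, a subset-permutation
    co-regulation statistic with Fisher-Z pooling and empirical p-values,
    positional-rule classification of premature termination codons for
    nonsense-mediated decay, and Poisson-based droplet digital PCR
    quantitation with reference-gene normalization.  Includes
    synthetic-data generators that emulate the cohort and droplet
    structure these methods assume, so the full pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, Biostrings, IRanges, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
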