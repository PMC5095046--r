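Package: esnpgsea
Title: Expression-SNP Integrated Pathway Enrichment Analysis for Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pathway-level analysis of case-control genome-wide association
    studies using expression-related SNPs (eSNPs). Genes are represented by a
    surrogate eSNP (the gene's expression-associated SNP most strongly
    associated with disease), per-study logistic-regression associations are
    combined by fixed-effect inverse-variance-weighted meta-analysis, and
    pathways are tested with a weighted Kolmogorov-Smirnov-like running-sum
    enrichment score against a within-study phenotype-permutation null, with
    normalized enrichment scores and a permutation-based false discovery rate.
    Includes a synthetic-data generator (multi-study dosage cohorts, eQTL
    summary tables, gene-set collections with planted effects) so every stage
    of the pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
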