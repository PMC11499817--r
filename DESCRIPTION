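Package: rudx
Title: Inheritance-Aware Exome Variant Prioritization for Rare Undiagnosed
    Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a diagnostic exome triage
    pipeline for rare undiagnosed disease cohorts. From multi-sample VCFs,
    pedigrees, variant annotation tables, pre-called copy-number calls and
    Human Phenotype Ontology term lists, the package applies technical,
    consequence, population-frequency and cohort-recurrence filters,
    generates candidate variants under autosomal recessive (homozygous and
    compound heterozygous), autosomal dominant and X-linked inheritance
    models with trio-based de novo detection, builds phenotype-driven
    virtual gene panels, derives a consensus ACMG interpretation per
    variant, categorizes each proband as solved, suggestive, partially
    informative or uninformative, and summarizes cohort-level diagnostic
    yield including logistic-regression models of yield predictors. A
    synthetic-cohort generator with planted causal variants makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
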