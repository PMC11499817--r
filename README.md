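# rudx — inheritance-aware exome variant prioritization for rare undiagnosed disease cohorts

Rare-disease programs sequence undiagnosed probands as trios, duos or
solos and must reduce tens of thousands of annotated exome variants to a
short, clinically interpretable candidate list. `rudx` implements that
triage pipeline as a tested R package:

* **Filtering** — read-support (depth ≥ 3), consequence-class exclusion
  (synonymous, deep intronic, intergenic, UTR), recessive-model frequency
  rules (MAF > 0.005 in any population source, or ExAC hom+hemi count ≥ 10,
  excluded), dominant-model rules (MAF > 0.001 or allele count > 5 in
  gnomAD/internal database excluded), and cohort recurrence (variants in
  ≥ 2 unrelated families excluded), each with a full audit trace.
* **Inheritance models** — stepwise review AR → AD → XL: homozygotes,
  trans-configured compound heterozygotes (including CNV–SNV pairs over a
  parental deletion), dominant heterozygotes, X-linked hemizygotes, and
  trio-confirmed de novo calls guarded by parental read depth.
* **Phenotype panels** — HPO terms expanded through the ontology build
  virtual gene panels and gate "informative" findings on phenotype
  consistency; terms group into organ systems (depth-1 branches under the
  phenotypic-abnormality root) for the cohort covariates.
* **Interpretation** — consensus ACMG class per variant (ClinVar verbatim
  when present, else the modal resource class, ties → VUS) and per-proband
  categorization: *solved* (P/LP meeting the inheritance-mode genotype
  requirement, with recessive genotypes requiring both trans alleles P/LP),
  *suggestive* (VUS-based), *partially informative* (single allele for a
  recessive condition), *uninformative*.
* **Cohort statistics** — detection rates per sequencing strategy,
  distinct-variant tallies, demographic summaries, and bivariate +
  multivariate binomial GLMs of diagnostic yield with Wald 95% CIs.
* **Synthetic cohorts** — `simulate_cohort()` generates families, VCFs,
  annotations, CNV calls, phenotypes and ground truth with planted causal
  variants spanning all inheritance modes, so the full pipeline is
  testable offline.

## Worked example

Simulate a small cohort, run the pipeline, and compare with the
generator's ground truth:

```r
library(rudx)

sim <- simulate_cohort(simulation_config(n_families = 20,
                                         background_n = 60), seed = 7)
res <- run_cohort(sim)
table(res$results$category)
#>        solved    suggestive uninformative
#>             5             1            14

ev <- evaluate_against_truth(res, sim$truth)
ev$recall               # 1   — every planted variant recovered
ev$category_agreement   # 1   — every category as expected from class+mode
ev$by_mode
#>           mode recall n
#> 1    AD_denovo      1 3
#> 2 AD_inherited      1 1
#> 3          CNV      1 2
```

Six of twenty probands carried a planted cause; the pipeline recovered
all of them (recall 1.0), called the five P/LP plants *solved* and the
VUS plant *suggestive*, and left the other fourteen probands
uninformative — background variants either fail a filter or sit in genes
with no disease association.

The bundled informative-variant table (47 probands, 55 variants) drives
the cohort-level tallies:

```r
fx  <- informative_results(read_informative_table())
tal <- variant_tallies(fx$candidates)
c(tal$n_distinct, tal$n_snv, tal$n_cnv, tal$n_de_novo, tal$n_clinvar)
#> [1] 55 50  5 25 26
solved_split(fx$records)
#> $n_solved [1] 31   $AD [1] 23   $AR [1] 4   $XL [1] 4
```

File-based workflows use the readers directly (`read_vcf`,
`read_pedigree`, `read_annotations`, `read_cnv`, `read_phenotypes`,
`read_ontology`, `read_gene_map`) or the thin command-line front end in
`inst/cli/rudx` (`rudx simulate | run | stats`).

See `vignettes/variant-prioritization-methods.Rmd` for the model,
parameter defaults, design decisions and limitations.

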