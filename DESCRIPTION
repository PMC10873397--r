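Package: admetmr
Title: Life-Course Analysis of Alzheimer's Disease Genetic Liability and
    Circulating Metabolites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reverse Mendelian-randomization analyses that treat
    genetic liability to Alzheimer's disease as the exposure and circulating
    NMR metabolites as outcomes across the life course. Provides weighted
    genetic risk scores with allele harmonization, proxy substitution and
    missing-genotype policies; APOE epsilon-diplotype classification and
    carrier contrasts; rank-based inverse normal transformation; an
    individual-level association engine (GRS-metabolite regression, per-SNP
    metabolite GWAS within age strata, confounder checks); a from-scratch
    two-sample MR estimator suite (Wald ratio, IVW, MR-Egger, weighted
    median, weighted mode) with per-doubling-of-liability scaling; a
    synthetic cohort and summary-statistics generator for testing; and an
    age-stratified pipeline producing forest-plot-ready results tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
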