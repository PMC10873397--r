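---
title: "Methods: reverse MR of AD liability on the blood metabolome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse MR of AD liability on the blood metabolome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admetmr)
```

## The design

Classical Mendelian randomization asks whether a biomarker causes disease.
This package implements the reverse question: treating *genetic liability
to Alzheimer's disease* as the exposure and circulating NMR metabolites as
outcomes, it asks which metabolic features already differ in people with
higher liability, and from what age. Because germline genotype is fixed at
conception, such differences cannot be caused by preclinical disease in
childhood cohorts, making the design informative about the early footprint
of liability across the life course.

Two arms serve different data situations:

* a **GRS arm** for individual-level cohorts with metabolites measured at
  several ages (childhood through young adulthood), where a weighted
  genetic risk score gives better power at modest n;
* a **two-sample MR arm** for large adult biobanks analysed as summary
  statistics, stratified into age tertiles, where the formal instrumental
  variable machinery permits pleiotropy-robust sensitivity estimators.

Both arms express results in SD units of the transformed metabolite per
doubling of genetic liability, so estimates are directly comparable across
arms, ages and metabolites.

## Models

### Genetic risk score

With external weights $w_j$ (log odds of AD per effect allele) and dosages
$g_{ij} \in [0,2]$, the score is $S_i = \sum_j w_j g_{ij}$. For each
metabolite $M$ (rank inverse-normal transformed within timepoint) we fit

$$M_i = \alpha + \beta S_i + \delta_1 \,\mathrm{age}_i +
\delta_2\,\mathrm{sex}_i + \varepsilon_i$$

by OLS and report $\beta \cdot \ln 2$, i.e. the SD difference per doubling
of liability, with SE and normal-quantile 95% CI scaled identically. Two
score variants are always available: with the two APOE-defining SNPs and
without them, to separate APOE-driven from polygenic effects.

Missing genotypes (scores are computed for anyone with at least one
observed instrument SNP) are handled by a selectable policy. The default
rescales the observed weighted sum by
$\sum_j |w_j| / \sum_{j \in \mathrm{obs}(i)} |w_j|$, which keeps scores on
one scale across missingness patterns; `sum_observed` (raw sum) and
`mean_impute` (impute $2 \cdot \mathrm{eaf}$) are available because cohort
pipelines differ on this point and the choice is not empirically settled.

### Two-sample MR estimators

Given harmonized per-SNP effects $\hat\gamma_j$ (SNP → AD) and
$\hat\Gamma_j$ (SNP → metabolite) with SEs $\sigma_{\gamma j},
\sigma_{\Gamma j}$:

* **Wald ratio** (single SNP): $\hat\Gamma/\hat\gamma$, first-order SE
  $\sigma_\Gamma/|\hat\gamma|$ (second-order delta-method SE optional).
* **IVW**: $\hat\beta = \sum_j w_j \hat\gamma_j \hat\Gamma_j / \sum_j w_j
  \hat\gamma_j^2$ with $w_j = \sigma_{\Gamma j}^{-2}$. The default SE is
  multiplicative random effects: the fixed-effects SE times
  $\max\!\big(1, \sqrt{Q/(J-1)}\big)$ with Cochran's $Q$ about the fitted
  slope. We default to this variant (with the floor at 1) because it is the
  prevailing two-sample default: it concedes variance to heterogeneity when
  present without ever reporting less than the fixed-effects uncertainty.
* **MR-Egger**: weighted regression of $\hat\Gamma$ on $\hat\gamma$ *with*
  intercept after flipping each SNP's pair so $\hat\gamma_j > 0$ (the model
  is invariant to such flips). The intercept estimates average directional
  pleiotropy; the slope is consistent under InSIDE. SEs carry the same
  floored inflation with $J-2$ degrees of freedom. Note one subtlety
  exercised in the tests: if pleiotropy is a constant per *effect allele*,
  the positive-$\gamma$ orientation flips its sign for negative-weight
  SNPs, so exact intercept recovery holds only for all-positive-weight
  instruments; with one protective SNP among 25 the bias is well under 10%.
* **Weighted median**: order the Wald ratios, form normalized
  inverse-variance weights $w'_j$ (first-order ratio variances), cumulative
  midpoints $p_k = \sum_{i \le k} w'_i - w'_k/2$, and linearly interpolate
  the ratio at $p = 0.5$. Consistent when valid instruments carry over half
  the weight.
* **Weighted mode**: the argmax of the weighted Gaussian KDE of the
  ratios. Bandwidth is modified Silverman,
  $h = \varphi \cdot 0.9 \min(\mathrm{SD}_w, \mathrm{IQR}_w/1.349)
  J^{-1/5}$ with $\varphi = 1$ by default; the density is scanned on a
  512-point grid spanning the ratios $\pm 3h$ and the argmax is refined by
  golden-section search between its grid neighbours. Identical ratios (zero
  bandwidth) return that common ratio.

Median and mode SEs come from a seeded parametric bootstrap (default 1000
replicates): both betas of every SNP are redrawn from
$N(\hat\beta, \mathrm{se}^2)$, the estimator recomputed with re-derived
weights, and the SD across replicates reported. The bootstrap size and seed
travel with the result row.

### Harmonization, proxies, APOE

Summary rows are aligned to the instrument's effect alleles: swapped
alleles flip the beta sign and reflect the EAF; opposite-strand rows are
base-complemented first. Palindromic (A/T, C/G) SNPs are strand-ambiguous;
by default they are aligned through allele frequency when both tables are
informative (frequency at least 0.08 from 0.5, a conventional window —
closer to 0.5 the frequency cannot distinguish strands) and dropped
otherwise. Harmonization is idempotent, which the suite checks.

Instrument SNPs absent from a dataset may be replaced by user-supplied
proxies (defaults: r² ≥ 0.8 within 10,000 kb), carrying the original
weight. The package consumes a proxy *mapping*; it does not search LD
reference panels.

APOE ε diplotypes are the standard lookup on hard-called counts of
rs429358-C and rs7412-T; dosages further than 0.1 from an integer are
unclassifiable (a diplotype is discrete; 0.1 keeps only essentially-certain
imputed calls). ε4 carriers and ε2 carriers are each contrasted against
ε3/ε3 with the opposite allele's carriers omitted, so ε2/ε4 heterozygotes
join neither contrast; (1,2), (2,1), (2,2) combinations imply rare
recombinant haplotypes and are excluded. Carrier contrasts are mean
differences of the transformed metabolite and are deliberately *not*
ln2-scaled, since the exposure there is carriage, not liability dose.

### Rank inverse-normal transformation

Metabolites are mapped to $\Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$
with the Blom offset $c = 3/8$ and average ranks for ties, within each
timepoint or age stratum, never pooled across ages. Blom is the prevailing
convention in genetic-epidemiology pipelines and the offset is
configurable, since sources rarely state which constant they used. The
transform is monotone and invariant to positive affine rescaling, so
platform units never matter downstream.

## The synthetic-cohort generator

The generator exists so that every stage — scoring, harmonization, both
association arms, the estimator suite, the pipeline — can be tested against
known truth. It draws:

* dosages Binomial(2, $f_j$) independently per SNP (Hardy–Weinberg,
  linkage equilibrium), **except** the APOE pair, drawn as two haplotypes
  over (ε2, ε3, ε4) with default frequencies 0.08 / 0.77 / 0.15 (UK-typical
  values), so diplotype classification sees realistic joint genotypes;
* liability $L_i = \sum_j w_j g_{ij}$ and metabolites
  $\theta L_i + \sum_j \alpha_j g_{ij} + \mathrm{age}\cdot s_a +
  \mathrm{sex}\cdot s_x + N(0, \sigma^2)$, with per-allele direct effects
  $\alpha_j$ available to inject directional pleiotropy (constant
  $\alpha_j$ satisfies InSIDE by construction);
* four childhood/young-adult timepoints (around ages 8, 16, 18, 25) plus
  one adult timepoint uniform over 39–73, mirroring the two cohort designs
  the arms target;
* completely-at-random genotype missingness, with every sample guaranteed
  one observed SNP (no mechanism beyond MCAR is modelled).

Default calibration choices (there are no published per-SNP metabolite
effect sizes to copy): $\theta = 0.1$ SD per log-odds, residual SD 1, age
slope 0.01 SD/yr and sex difference 0.2 SD (both absorbed by the adjusted
models), and a synthetic 25-SNP instrument with field-typical APOE log
odds ratios (rs429358-C +1.2, rs7412-T −0.47) plus 23 small-weight SNPs.
rs7412 is coded for its ε2-defining T allele with a negative weight so the
same dosage column feeds the score and the diplotype lookup; scoring and
harmonization are sign-agnostic.

Paired two-sample summary statistics are generated analogously:
$\hat\gamma_j = w_j + N(0, \mathrm{se}_j^2)$,
$\hat\Gamma_j = \theta w_j + \alpha_j + N(0, \mathrm{se}_j^2)$, with the
standard GWAS variance approximation
$\mathrm{se}_j = 1/\sqrt{2 f_j (1-f_j) n}$, and outcome alleles emitted
with randomized orderings and strands so harmonization is always
exercised.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: LD beyond the APOE pair, imputation
uncertainty, population stratification and relatedness (eligibility is
assumed handled upstream), non-linear or age-varying metabolite effects,
informative missingness, and the correlated error structure of a real NMR
panel.

## Numerical and design choices

* 95% CIs use the normal quantile 1.959964 (not t), matching the reporting
  convention of the GWAS/MR tools this interoperates with; at the sample
  sizes involved the difference is negligible. Configurability was not
  worth the interface surface.
* OLS uses the QR decomposition with listwise deletion and classical SEs;
  robust SEs are not fitted since none of the downstream consumers expect
  them.
* Age tertiles are assigned by rank with stable tie-breaking; remainder
  samples go to the youngest strata, so sizes differ by at most one.
  Boundaries are always reported from the data, never hard-coded.
* No multiple-testing adjustment is applied in primary output — results
  are interpreted through interval estimates; a Benjamini–Hochberg column
  can be added trivially by the caller from the emitted p-values.
* Degenerate inputs fail loudly and early: monomorphic SNPs yield missing
  GWAS rows (logged), all-identical metabolite vectors refuse the INT,
  zero-γ SNPs refuse a Wald ratio, identical exposure effects refuse
  Egger, samples with no observed genotype are excluded and reported.
* Replicated simulations seed one RNG stream per replicate and draw all
  quantities for that replicate consecutively from it. Seeding two parallel
  streams per replicate with a constant offset was observed to produce
  correlated draws (a Mersenne-Twister seeding artefact), which distorted a
  null rejection rate until restructured.
* The calibration checks in the test suite and `scripts/acceptance.R` use
  200 replicates for recovery/coverage (two-sample J = 25 at GWAS sample
  size 20,000; GRS cohorts of 20,000), 400 for null calibration at cohort
  size 1,000, and 100 for the APOE-attenuation property — sizes at which
  Monte-Carlo error is small relative to the property bands being checked.
* The function-level API plus `run_pipeline()` (list or YAML config) *is*
  the interface; no shell wrapper is shipped, since users of this kind of
  package work in R and a wrapper would only re-expose `run_pipeline`.

## Known limitations

The MR arm's per-SNP GWAS is plain OLS per stratum; very large biobanks
normally use mixed models for relatedness, which this package delegates to
its inputs. The proxy module consumes, rather than discovers, LD proxies.
Bootstrap SEs for median/mode assume approximate normality of the per-SNP
estimates. And the generator's independence assumptions above mean that
real-data artefacts (LD leakage between instruments, panel-wide correlated
measurement error) are out of scope for what the test suite can certify.
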