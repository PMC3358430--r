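# tissueqtl

Cross-tissue *cis*-eQTL mapping at GWAS-implicated SNPs, with the full
cohort plumbing a genetics study needs around the regression itself:
genotype and sample quality control, GWAS-catalog inclusion filtering,
expression detection filtering, covariate-adjusted allelic-dosage
regression in a ±500 kb cis window, Benjamini–Hochberg FDR control,
cross-tissue sharing classification (shared, blood-specific,
brain-specific, expression-restricted), conditional proxy-SNP analysis,
and closed-form plus Monte-Carlo power under the additive model.

It is written for analysts comparing eQTL architecture between peripheral
blood and brain regions (frontal cortex, cerebellum) — the setting where
one tissue is easy to sample and the question is how well it proxies the
other — and for anyone who needs a fully testable eQTL pipeline: a
synthetic-cohort generator with a *known planted architecture* (HWE
genotypes, imputation-quality dosage noise, covariate confounding,
duplicates, ancestry outliers, tissue-restricted expression) makes every
stage verifiable without any external data.

## The model

For probe expression $y$ and SNP dosage $d \in [0,2]$ (expected
minor-allele count), each tissue is fit by OLS:

$$ y = \mu + \beta d + \gamma^\top c + \varepsilon $$

with covariates $c$ = age at death, gender, PMI, tissue bank,
hybridization batch, and two MDS ancestry components; two-sided t-tests on
$\hat\beta$; BH-FDR at 5% within tissue and analysis track. Power for a
per-allele effect of $Z$ phenotype SD at MAF $p$ is
$\Phi(\lambda - z_{\alpha/2}) + \Phi(-\lambda - z_{\alpha/2})$ with
$\lambda = Z\sqrt{n\,2p(1-p)}/\sigma_e$.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated two-hundred-sample, three-tissue cohort with six planted eQTLs
(two shared, one blood-specific, one brain-specific, two
expression-restricted):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_quality_control.R
Rscript analysis/03_map_eqtls.R
Rscript analysis/04_tissue_comparison.R
Rscript analysis/05_power_analysis.R
```

`03_map_eqtls.R` prints:

```
Samples: 200 simulated -> 196 after QC
Cis pairs: 30; tested per tissue: blood=27 frontal_cortex=27 cerebellum=27
Non-null sharing calls:
   snp_id     probe_id                        call
 rs000002 ILMN_0000002                  shared_all
 rs000003 ILMN_0000003                  shared_all
 rs000005 ILMN_0000005              blood_specific
 rs000007 ILMN_0000007              brain_specific
 rs000009 ILMN_0000009 blood_restricted_expression
 rs000011 ILMN_0000011 brain_restricted_expression
Planted effects recovered with the expected call: 6 of 6
```

Four samples were removed by QC — the two planted ancestry outliers, one
member of the planted duplicate pair, and the duplicate's MDS twin — and
per tissue two SNPs fell to the fewer-than-3-minor-homozygotes rule and
one probe to detection filtering (the restricted-expression probes by
construction); all six
planted effects come back with exactly the planted sharing class.
`05_power_analysis.R` prints:

```
Calibrated two-sided alpha = 1.4e-05 (residuals -1.8e-05, 4.6e-06)
Power at n=501: 0.988 ; at n=399: 0.939
```

i.e. from the two published cohort powers alone, root-finding recovers a
single Bonferroni-scale significance level that reproduces both to three
decimals (see the methods vignette for why this pins down the variance
convention too). Tables land under `results/`; bulky regenerable
intermediates (the dosage VCF, expression matrices) under `scratch/`.

In R, the pieces compose directly:

```r
library(tissueqtl)
f <- fit_eqtl(y = c(1, 2, 2), dose = c(0, 1, 2))
f$beta            # 0.5, the per-allele expression change
bh_fdr(c(0.01, 0.03, 0.04))$q   # 0.03 0.04 0.04
analytic_power(power_spec(n = 501, maf = 0.2, Z = 0.5))  # 0.988
```

## Layout

* `R/` — the package: `simcohort` (generator), `qc`, `catalog`, `exprqc`,
  `cismap`, `tissuecomp`, `power`, `pipeline`, plus VCF/TSV/BED I/O.
* `analysis/` — the numbered workflow scripts above.
* `vignettes/cross-tissue-eqtl-methods.Rmd` — model, conventions,
  calibration choices, generator realism and limitations.
* `tests/testthat/` — oracle-checked unit tests (exact HWE enumeration,
  normal-equations OLS, hand step-up BH), property tests, and an
  end-to-end statistical acceptance suite.
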