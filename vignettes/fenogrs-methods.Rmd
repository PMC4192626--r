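---
title: "Methods: pedigree-aware GRS analysis of lipoprotein subfractions and treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware GRS analysis of lipoprotein subfractions and treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenogrs)
```

## The scientific question

NMR spectroscopy resolves plasma lipoproteins into fourteen subfraction
measures: particle concentrations (nmol/L) of small, medium and large VLDL,
LDL and HDL subclasses, the total particle numbers per fraction, and the
average particle diameters (nm) of VLDL, LDL and HDL. Variants previously
associated with fasting levels of these measures can be combined into a
per-phenotype genetic risk score (GRS). Two linked questions arise in a
family-based drug trial: does each phenotype's GRS predict its fasting
(baseline) level, and does the same GRS predict how the level *responds* to a
short course of fenofibrate, a fibrate indicated in hypertriglyceridemia?

`fenogrs` implements this analysis end to end for family samples in which
relatedness must be modelled: genotype QC with Mendelian-error family
counting, unweighted GRS construction with direction-of-effect allele
recoding, phenotype preparation (selective log transforms, pre/post response
ratios, triglyceride stratification, paired change tests), pedigree linear
mixed models fitted by REML, and Bonferroni-corrected reporting with Cohen's
d effect sizes. Because cohort data of this kind are access-restricted, the
package ships a gene-dropping simulator whose output exercises every stage
with known ground truth.

## Statistical model

For a phenotype $y$ (transformed per the policy below) on $n$ individuals,
the association model is

$$ y = X\beta + g + e, \qquad
   g \sim N(0, \sigma^2_g A), \qquad e \sim N(0, \sigma^2_e I), $$

where $X$ contains an intercept, the predictor of interest (the phenotype's
GRS, or a single SNP), and the covariates age, sex, BMI, current smoking and
field center. $A$ is the expected additive relationship matrix (twice the
kinship coefficient) computed from the pedigree by the recursive tabular
method: founders are unrelated and non-inbred, $A_{ii} = 1 + A_{f_i m_i}/2$,
and $A_{ij} = (A_{f_i j} + A_{m_i j})/2$ for a non-founder $i$. $A$ is
block-diagonal across families, which the fitter exploits.

Variance components are estimated by restricted maximum likelihood. Writing
$\lambda = \sigma^2_g/\sigma^2_e$ and rotating the model through the
eigendecomposition $A = U D U'$ turns the covariance into the diagonal
$\sigma^2_e(\lambda D + I)$, so the REML criterion is profiled down to a 1-D
function of $\lambda$, maximized by bounded scalar search on
$\log \lambda$ (tolerance $10^{-8}$, search range $[10^{-8}, 10^{6}]$), with
the boundary $\sigma^2_g = 0$ and the upper endpoint checked explicitly.
Fixed effects are the GLS estimates at the optimum. Test statistics are Wald
F: $(\hat\beta/\mathrm{se})^2$ for a single coefficient, the joint quadratic
form divided by its degrees of freedom for a categorical genotype.

Two conventions deserve explanation:

* **Residual df is $n-2$** for the F reference distribution and for the
  effect-size conversion $d = 2\sqrt{F/(n-2)}$, regardless of how many
  covariates the model carries. This is the convention under which the
  conversion reproduces published F-to-$\delta$ tables for analyses of this
  design, and it is applied uniformly so that the `cohens_d` column is always
  reconstructible from `f_value` and `n`.
* **Random-effect structure.** The default is the full pedigree relationship
  matrix. A family-indicator random intercept (`random_effect = "family"`,
  i.e. a within-family constant-covariance block) is provided as an
  alternative, since published descriptions of such analyses often say only
  that "dependencies within families" were modelled. The kinship default is
  the structure under which the effect-size conversion and calibration
  checks behave as documented.

## Phenotype preparation

* **Response definition.** Fenofibrate response is the ratio
  pre/post, so a decrease on treatment gives a ratio above 1. On the log
  scale the response is exactly the difference of the log endpoints.
* **Transform policy.** Skewed measures are natural-log transformed. At
  baseline the untransformed exceptions are small LDL concentration, HDL
  total particles, large and small HDL concentrations, LDL diameter and HDL
  diameter; for the response the exceptions are LDL total particles, LDL
  diameter and HDL diameter. The base of the logarithm does not change test
  statistics or p values; natural log is used. The policy is a first-class
  object (`default_transform_policy()`) and is recorded in the output of
  `apply_transforms()`.
* **TG stratification.** Samples split at baseline fasting triglycerides of
  150 mg/dL — the hypertriglyceridemia indication threshold — with the
  boundary in the high stratum. Samples with missing TG are excluded from
  the strata but never from the full-sample analysis.
* **Paired change tests** (`paired_change_test`, `change_report`) are
  two-sided paired t tests of post versus pre, run on raw values by default
  because change tables conventionally report raw means; a switch tests the
  transformed scale. Note that for log-normally distributed measures a null
  effect on the log scale is *not* null for raw means (the raw post mean is
  shifted by a Jensen factor $e^{\sigma^2/2 - \mu}$), which matters when
  constructing null fixtures.

## Genotype QC

Exclusions apply in a fixed order: monomorphic (no variation among observed
calls), call rate (typed SNPs with fewer than 96% non-missing calls;
exactly 96% is retained — the rule is strict), then a MAF-stratified rule on
the number of families containing a Mendelian error: MAF ≥ 20% tolerates
errors in up to 3 families, 10–20% up to 2, 5–10% up to 1, and below 5% none.
Strata are half-open with the boundary in the upper stratum. A family is
counted once however many inconsistent calls it contains. Trios are checked
by transmissible-allele logic; duos (one genotyped parent) are checked for
the opposite-homozygote configuration, on by default and switchable, since
duo scope is a policy choice rather than a mathematical necessity. Dosages
are never checked (imputed values are not Mendelian-constrained), and
missing genotypes never create errors. The stratification MAF is computed on
all non-missing samples by default, with a founders-only switch.

## GRS construction

The GRS of phenotype $p$ for sample $i$ is the unweighted sum of recoded
contributions over the manifest entries retained for $p$:
the contribution of a SNP with published positive effect is its minor-allele
dosage $x \in [0,2]$; with a negative published effect the major allele
becomes the coded allele and the contribution is $2 - x$. A SNP listed for
several phenotypes contributes to each, possibly recoded differently. Scores
therefore lie in $[0, 2k]$ for $k$ contributing SNPs, and flipping every
sign reflects the score about $k$ — both properties are tested exactly.

Allele orientation is frozen when genotypes are loaded (from the file's
alleles plus observed frequencies, ties broken toward the ALT allele for VCF
and alphabetically for PLINK text); the manifest refers to SNPs by id only
and its signs are assumed pre-harmonized to the minor allele. Missing hard
calls exclude the sample from that phenotype's score by default
(complete-case); mean imputation is available as an explicit option.
Manifest accounting (entries dropped as unavailable or QC-failing) is
reported by `filter_manifest()` so the path from a published association
list to the analysed set is auditable.

Hard calls enter the GRS additively (0/1/2), not as categorical classes;
the categorical coding is offered for *single-SNP* models
(`run_single_snp_associations(coding = "categorical")`), where a
three-class genotype is a defensible alternative and costs one extra df.

## Multiple testing

Significance is $\alpha/m$ with $m$ the number of phenotypes with a
nonempty GRS (14 with the default manifest), giving $0.05/14 = 0.003571…$,
conventionally displayed as 0.004. Decisions always use the exact value: a
p value of 0.0038 is *not* significant even though it is below the rounded
display. No additional correction is applied across TG strata, matching the
single stated correction of the replicated design.

## The synthetic study generator

`simulate_study()` emulates a two-center family intervention study.
Defaults are fixed study conditions, not tuning knobs:

* **Pedigrees:** 91 families, three generations, sibship sizes 2–4
  (eligibility requires a sibship of at least two), giving ≈ 820
  individuals; each family is assigned wholly to one of two centers.
* **Genotypes:** 60 SNPs in linkage equilibrium, MAF uniform on
  (0.05, 0.5), gene-dropped: founder allele copies are Bernoulli(MAF),
  children inherit one uniformly chosen allele per parent, so the clean
  matrix provably contains no Mendelian inconsistencies. 77% of SNPs are
  carried as imputed dosages, mirroring the typed share of a hybrid
  genotyped-plus-imputed panel. Artifact injection adds typed-call
  missingness (1%), typed-call corruption (0.1%, resampled uniformly from
  the two wrong genotypes) and truncated-Gaussian dosage noise (sd 0.05),
  with a per-call corruption log for sensitivity tests.
* **Manifest:** 189 SNP-phenotype entries allocated across the 14
  phenotypes with random published-effect signs; 26 entries are flagged
  unavailable and 3 QC-failing (grouped by SNP via an exact subset-sum
  placement), leaving 160 retained — the accounting a real association list
  goes through.
* **Phenotypes:** on a latent SD-unit scale, baseline =
  covariate effects + $\beta_{\text{GRS}} \times$ (centred true GRS) +
  polygenic value + residual, where polygenic values flow down the pedigree
  (child = parental mean + Mendelian-sampling noise of variance
  $\sigma^2_g/2$) with $h^2 = 0.4$, a typical lipid heritability, and
  $\beta_{\text{GRS}} = 0.1$ SD/allele. Observed measures are
  $\exp(\mu + s \cdot \text{latent})$ for log-policy phenotypes and
  $\mu + s\cdot\text{latent}$ otherwise, with $(\mu, s)$ loosely matched to
  typical adult fasting values; identity-policy scales are capped at a
  quarter of the mean so measures stay positive. Treatment response is
  generated on the log pre/post scale with a null genetic effect by default
  ($\beta_{\text{response}} = 0$), per-phenotype mean ratios near typical
  treatment effects, residual sd 0.2, and a *pedigree-transmitted* familial
  response effect (sd 0.1). The familial response effect is polygenic rather
  than a household block deliberately: the analysis model's random effect
  spans kinship-structured covariance only, and the generator is specified
  to stay inside the model family the analysis fits, so null-calibration
  tests measure the fitter rather than a generator/analysis mismatch.
  Triglycerides are log-normal with 31% of samples at or above 150 mg/dL and
  3% missing, reproducing the usual shortfall of stratified totals relative
  to the full sample.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (the GRS treats SNPs additively and independently, so LD
adds nothing testable here), ascertainment of hypertriglyceridemic probands,
household/shared-environment covariance, genotyping batch effects, and
postprandial phenotypes. Tests passing on this generator therefore
demonstrate correctness of the *pipeline and its statistics under the stated
model*, not robustness to every feature of real cohort data.

## Numerical choices and degenerate inputs

* Eigendecomposition is performed per family block when a family grouping is
  available, making fits at $n \approx 2000$ cheap; eigenvalues below zero
  by rounding are clipped at zero, and matrices with materially negative
  eigenvalues are rejected.
* The REML optimum is compared against the explicit $\lambda = 0$ (pure
  residual) boundary; $\hat\sigma^2_g = 0$ is a legitimate outcome.
* Collinear designs raise an error naming the offending columns; constant
  predictors (e.g. a monomorphic dosage within a stratum) yield a row
  flagged `estimable = FALSE` rather than an error, as do strata below the
  minimum size (default 30).
* A noise-free response drives $\hat\sigma^2_e \to 0$ and the Wald F to
  infinity; the single-df F is computed as $\hat\beta^2/\mathrm{var}(\hat\beta)$
  so this path degrades gracefully.
* Paired tests with zero-variance differences are signalled explicitly,
  except the all-zero case which is reported as $t = 0$, $p = 1$.
* Ties in allele-frequency orientation break deterministically (ALT kept as
  minor in VCF; alphabetical in PLINK text and the generator), so repeated
  loads freeze the same orientation.

## Problem sizes used by the test suite

The shipped tests run the calibration study at 1000 replicates of $n = 400$
(100 two-generation families), REML-versus-grid comparisons at $n \le 200$,
Monte-Carlo kinship checks at $10^5$ gene drops on pedigrees of up to 12,
and parameter-recovery and end-to-end analyses at $n \approx 2000$ (220
three-generation families). These sizes were chosen to make Monte-Carlo
bands tight enough to be meaningful while keeping the default suite quick to
run.

## Known limitations

* The Wald F with $n-2$ reference df is an approximation in mixed models;
  its type-I calibration is verified empirically (the binomial band test)
  rather than derived.
* Complete-case GRS handling discards samples with any missing contributing
  hard call; with many typed SNPs per score and nontrivial missingness the
  per-phenotype n can shrink noticeably (mean imputation is available).
* Allele harmonization between a published association list and the local
  genotype data is assumed done upstream: the manifest's signs must already
  refer to the local minor allele.
* X-chromosome inheritance is not modelled; all SNPs are treated as
  autosomal, in QC and in gene dropping alike.
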