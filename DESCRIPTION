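Package: fenogrs
Title: Pedigree-Aware Genetic Risk Score Analysis of NMR Lipoprotein
    Subfractions and Their Fenofibrate Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based pharmacogenetic analyses of NMR-measured
    lipoprotein subfraction phenotypes. Reads pedigree (PLINK .fam), genotype
    (VCF GT/DS, PLINK .ped/.map, dosage TSV), SNP-phenotype manifest and
    phenotype tables; applies Mendelian-error-aware genotype quality control
    with MAF-stratified family-error rules; builds unweighted, direction-of-
    effect recoded genetic risk scores per phenotype; prepares analysis
    phenotypes (selective log transforms, pre/post treatment-response ratios,
    triglyceride stratification, paired change tests); and fits pedigree-aware
    linear mixed models by restricted maximum likelihood with Wald F tests and
    Cohen's d effect sizes. A gene-dropping simulator generates multigeneration
    family studies with known genetic architecture so the whole pipeline is
    testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
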