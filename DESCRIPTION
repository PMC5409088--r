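Package: ancestryMeth
Title: Local-Ancestry-Aware Analysis of Population-Specific DNA Methylation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies CpG sites whose methylation differs by local
    ancestral context in admixed cohorts. Converts phased per-SNP local
    ancestry calls into windowed ancestry proportions around each CpG,
    fits per-site linear models of M-values on Native American and African
    ancestry proportions with covariates, and tests them with a 2-df
    likelihood ratio test under Benjamini-Hochberg FDR control. Further
    stages compare genotype against local-ancestry models per CpG-SNP pair
    by AIC, assess cross-tissue replication and effect concordance,
    compute permutation-based enrichment for genomic context and GWAS
    proximity, count effective sample sizes of majority-pure individuals,
    and estimate power by two-population subsampling. A seeded generator
    of synthetic admixed cohorts (Balding-Nichols allele frequencies,
    Poisson ancestry tracts, conditional genotypes, methylomes with known
    causal structure) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
biocViews: DNAMethylation, Epigenetics, Regression, StatisticalMethod,
    GeneticVariability, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'ancestryMeth-package.R'
    'crosstissue.R'
    'enrichment.R'
    'io.R'
    'ledger.R'
    'mvalues.R'
    'pipeline.R'
    'scan.R'
    'simulate.R'
    'subsample.R'
    'windows.R'
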