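---
title: "Local-ancestry-aware analysis of population-specific methylation"
author: "ancestryMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-ancestry-aware analysis of population-specific methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryMeth)
```

# The statistical model

In a three-way admixed cohort (European / Native American / African), each
individual's genome is a mosaic of ancestral tracts. For a CpG at position
$l$, the *local ancestral context* of individual $j$ is the triple
$\pi = (\pi_{EUR}, \pi_{NAM}, \pi_{AFR})$: among the SNPs falling in a
window centred at $l$, the fraction of ancestry-$i$ calls across both
haplotypes. The counts are integers over $2 \times n_{snps}$ alleles, so
the three components sum to one exactly; European ancestry is treated as
the reference and omitted from the design.

The scan fits, per site and on the M-scale
($M = \log_2 \beta / (1-\beta)$),

$$ M_j = \beta_0 + b_{NAM}\,\pi_{NAM,j} + b_{AFR}\,\pi_{AFR,j}
         + \gamma^\top x_j + \varepsilon_j,
   \qquad \varepsilon_j \sim N(0, \sigma^2), $$

by ordinary least squares and tests $H_0: b_{NAM} = b_{AFR} = 0$ with a
2-df likelihood ratio test against the covariate-only model, followed by
Benjamini–Hochberg adjustment across all tested sites (default
$\alpha = 0.01$). The coefficients are interpretable as the mean
methylation difference between a hypothetical pure-European and
pure-NAM / pure-AFR individual in the same environment.

Assumptions worth keeping in mind:

* the cis effect is linear in the ancestry *proportion* (a haplotype-dosage
  model);
* residuals are Gaussian on the M-scale with constant variance across
  ancestry contexts;
* local-ancestry calls are taken at face value — inference error in the
  upstream caller is not modelled (the generator exposes an optional
  symmetric mislabeling rate, default 0, to probe sensitivity);
* relatedness and cell-composition heterogeneity are handled only through
  fixed covariates.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `omega` | 500000 | bp, **total** window size | matches the cis scale at which methylation heritability is typically localised; the sweep (`scanSweep`) exposes the trade-off: smaller windows sharpen localisation but drop sites whose window holds no SNP |
| `minSnps` | 1 | SNPs | only sites without any in-window marker are excluded |
| `fdrAlpha` | 0.01 | — | stringent FDR for modest cohort sizes |
| `threshold` (effective N) | 0.75 | proportion | "more than three quarters" pure, strict inequality; values $\le 1/3$ are rejected because the one-population reading would no longer be unique |
| ledger `distance` | 500000 | bp | a SNP "within 500kb" of a site spans a 1Mb total window — deliberately *not* the same convention as the scan's `omega` (total size); both are documented and configurable |
| `nDraws` | 10000 | draws | permutation null; with the add-one correction the smallest reportable p is $1/(nDraws+1) = 10^{-4}$ |
| GWAS `distance` | 50000 | bp | "proximal" = within 50kb, i.e. a 100kb window centred on the site |

On the window convention: the window is *symmetric and centred* on the
site, and `omega` is its **total** size, so the half-width is
$\lfloor\omega/2\rfloor$ and the interval $[l - \omega/2,\, l + \omega/2]$
is closed on both ends (boundary SNPs count). `windowIsTotalSize = FALSE`
switches `omega` to a half-width for users who prefer the other reading.
Windows never span chromosomes, and coordinates are 1-based throughout.

# Numerical choices

**Exact versus asymptotic p-values.** The Gaussian log-likelihood is
evaluated at the MLE variance, so the LRT statistic is
$n \log(RSS_{red}/RSS_{full})$. For nested OLS models this statistic is a
monotone function of the partial F statistic, whose finite-sample null
distribution is known exactly. At cohort sizes around 100–200 the
$\chi^2_2$ reference is visibly anticonservative (type-I error near 0.057
at nominal 0.05 for $n = 150$), which distorts FDR calibration, so the
scan defaults to the exact p-value (`pMethod = "exact"`), with
`pMethod = "chisq"` available for strict asymptotic comparability. The
reported `lrt` statistic is identical either way, and `lrt2df()` exposes
the plain $\chi^2_2$ tail ($e^{-stat/2}$).

**Degenerate designs.** A site whose full design is rank deficient —
a cohort with no ancestry variation, or perfectly collinear
$\pi_{NAM}, \pi_{AFR}$ — is skipped with a logged reason rather than
silently tested with fewer degrees of freedom; the LRT df stays fixed at
2\. In the pair models, a constant dosage marks the genotype and joint
models unavailable and the AIC choice proceeds among the rest.

**AIC and ties.** $AIC = 2k - 2\log L$ with $k$ counting intercept,
covariates, genetic terms *and* the residual variance; the variance
parameter is common to all models so rankings are unaffected, but the
absolute values are comparable to other software that counts it. Exact
AIC ties (at $10^{-9}$ resolution) are broken toward the model with fewer
parameters, so pure-noise pairs resolve to the null model.

**Beta/M conversion.** Betas of exactly 0 or 1 are clipped to
$[10^{-6}, 1-10^{-6}]$ with a warning before the logit2 — the common
array practice; values outside $[0,1]$ are an error.

**BH adjustment** uses `stats::p.adjust(method = "BH")`; the step-up
equivalence is asserted against an enumeration oracle in the tests. The
adjustment is applied once per tissue and window size over all tested
sites; the genotype and ancestry analyses of the ledger are each adjusted
separately.

**Missing data.** Covariate cells are never imputed: samples with
incomplete covariates are dropped (with counts logged) before fitting;
readers fail fast on malformed files, undeclared ancestry codes (the
offending token and line are named) and duplicated identifiers. All
stages operate on the intersection of the sample sets of their inputs,
reported at run time.

# The synthetic-data generator

The generator's defaults define the study conditions the package is
validated under: 132 individuals, one synthetic chromosome of 100 Mb /
1 Morgan with a uniform recombination map, genome-wide ancestry
$\alpha = (0.55, 0.35, 0.10)$ (EUR/NAM/AFR — a plausible Colombian-like
admixture profile; cohort-specific values should be supplied when known),
admixture age $g = 8$ generations, and Balding–Nichols differentiation
$F = (0.15, 0.25, 0.15)$ — continental-scale $F_{ST}$, with extra drift
for the Native American reference.

What it emulates:

* **Tracts** — per haplotype, switch points follow a Poisson process of
  rate $g$ per Morgan (drawn as exponential gaps; the chromosome-crossing
  gap is retained in the diagnostic record so the pooled gap law is
  exactly exponential), with i.i.d. segment ancestries from $\alpha$ — a
  pulse-admixture approximation with closed-form checks.
* **Genotypes** — reference-allele frequencies per population from the
  Balding–Nichols Beta around a Uniform(0.05, 0.95) ancestral frequency;
  haplotype alleles Bernoulli given the local ancestry.
* **Methylomes** — per-site baseline + fixed covariate effects + cis
  signal + Gaussian noise. Mechanisms: `ancestry_cis` (effects
  $b_{NAM}, b_{AFR}$ on the true windowed proportions),
  `common_variant` (effect on the dosage of an in-window panel SNP
  segregating in all three populations), `popspecific_variant` (effect on
  a variant private to one population, simulated from the true tracts at
  the site but **left out of the genotype panel**; its nearest panel SNP
  is recorded as the tag), and `null`. Effect magnitudes are
  `effectScale` residual SDs with random signs. A second tissue reuses
  the causal sites and (a configurable fraction of) the effects while
  redrawing baselines and noise.
* **Manifest** — gene-context relations at roughly 450K-like marginal
  frequencies and a single island relation per site;
  `contextEnrichment` multiplies the placement weight of causal sites in
  named categories so enrichment detection has a known positive case.

The hidden-variant design of `popspecific_variant` is what makes the
genotype-versus-ancestry comparison meaningful: with no linkage
disequilibrium in the generator, an observed panel SNP can tag the hidden
causal variant only through its local ancestry, so the local-ancestry
model wins the AIC comparison at nearby SNPs — exactly the signature the
ledger analysis is designed to detect. Were the causal variant genotyped,
the dosage model would trivially win.

What it does **not** emulate: coalescent genealogies, linkage
disequilibrium within populations, realistic recombination maps,
reference-panel misspecification, array measurement error structure, or
batch effects. Passing tests on this generator therefore demonstrate the
correctness and calibration of the *statistics*, not robustness to every
artefact of real array data — upstream QC and normalisation are assumed
done before the package is entered.

# Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force window scans, hand tallies, enumeration BH, normal-equation
solves) and then checks end-to-end statistical behaviour on simulated
cohorts; the sizes are chosen so the whole suite runs in minutes on one
CPU:

* null calibration: $10^4$ sites, $n = 150$ — scan p-values pass a KS
  test against Uniform(0,1) and the 5% rejection rate sits in its 99%
  binomial interval;
* FDR and power: 5000 sites, 5% causal at twice the noise SD, $n = 200$,
  10 seeds — empirical FDR within 1.5× nominal at 1% and 5%, power above
  0.8;
* effect recovery: 50 seeds at $n = 300$ — mean bias below 0.05 residual
  SDs;
* mechanism discrimination: 50 matched seeds per regime at $n = 300$ —
  the ancestry model wins for private variants and the genotype model for
  shared variants in over 80% of seeds;
* cross-tissue, enrichment and subsampling properties at comparable
  scales.

`scripts/acceptance.R` re-runs the pipeline end to end at the default
study conditions and writes every main quantity it computes as JSON; the
seed argument drives all randomness.

# Known limitations

* No mixed models or kinship adjustment; nominally unrelated individuals
  are assumed.
* No reference-free cell-composition correction — cell proportions enter
  only as fixed covariates, and only for the blood-like tissue (one
  proportion, granulocytes, is dropped to break the sum-to-one
  collinearity).
* Age enters linearly; the recruitment-city reference level is the most
  frequent category. Both are reporting conventions, not findings.
* The cross-tissue correlation is Pearson by default (Spearman available
  via `method`); the choice is surfaced in the output metadata because
  rank- and moment-based concordance can differ for heavy-tailed effect
  estimates.
* Permutation p-values are not multiplicity-adjusted across categories;
  they are reported raw with their null intervals.
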