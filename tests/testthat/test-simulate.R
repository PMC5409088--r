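test_that("Balding-Nichols frequencies have the right moments", {
    # F -> 0: population frequencies concentrate at the ancestral frequency
    p0 <- simParams(nSnps = 10000L, fst = c(EUR = 1e-4, NAM = 1e-4,
                                            AFR = 1e-4))
    f0 <- simulateFrequencies(p0, seed = 5)
    anc <- attr(f0, "ancestral")
    expect_lt(mean(abs(f0[, "EUR"] - anc)), 0.02)
    # F = 0.2: Var[freq] ~ F p (1 - p) within 10%
    p2 <- simParams(nSnps = 100000L, fst = c(EUR = 0.2, NAM = 0.2,
                                             AFR = 0.2))
    f2 <- simulateFrequencies(p2, seed = 6)
    anc2 <- attr(f2, "ancestral")
    ratio <- mean((f2[, "NAM"] - anc2)^2) / mean(0.2 * anc2 * (1 - anc2))
    expect_lt(abs(ratio - 1), 0.1)
    expect_true(all(f2 > 0 & f2 < 1))
    expect_error(simParams(fst = c(EUR = 0, NAM = 0.2, AFR = 0.2)),
                 "fst")
})

test_that("frequency and cohort generation are deterministic in the seed", {
    p <- simParams(nSnps = 50L, nSites = 10L, nIndividuals = 6L,
                   causalMechanism = "null")
    expect_identical(simulateFrequencies(p, seed = 9),
                     simulateFrequencies(p, seed = 9))
    c1 <- simulateCohort(p, seed = 4)
    c2 <- simulateCohort(p, seed = 4)
    expect_identical(assay(c1$meth, "M"), assay(c2$meth, "M"))
    expect_identical(assay(c1$ancestry, "hap1"), assay(c2$ancestry, "hap1"))
    expect_false(identical(assay(c1$meth, "M"),
                           assay(simulateCohort(p, seed = 5)$meth, "M")))
})

test_that("tracts: no admixture generations means single-ancestry haplotypes", {
    p <- simParams(nIndividuals = 30L, nSnps = 50L, generations = 0)
    la <- simulateTracts(p, seed = 2)
    oneAncestry <- function(h) all(apply(h, 2, function(x)
        length(unique(x)) == 1))
    expect_true(oneAncestry(assay(la, "hap1")))
    expect_true(oneAncestry(assay(la, "hap2")))
})

test_that("tract switch process is Poisson(g) with exponential gaps", {
    p <- simParams(nIndividuals = 1000L, nSnps = 10L, generations = 8,
                   chromLengthMorgans = 1)
    la <- simulateTracts(p, seed = 3, keepSegments = TRUE)
    segs <- metadata(la)$segments
    nSwitch <- vapply(segs, function(s) length(s$switches), numeric(1))
    # mean switch count over 2000 haplotypes ~ g within 3 MC SDs
    expect_lt(abs(mean(nSwitch) - 8), 3 * sqrt(8 / 2000))
    # pooled gap draws (including each haplotype's chromosome-crossing gap,
    # so the collection is unbiased for the renewal law) are Exponential(g)
    gaps <- unlist(lapply(segs, `[[`, "gaps"))
    ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 8))
    expect_gt(ks$p.value, 0.01)
})

test_that("genome-wide ancestry recovers the configured admixture proportions", {
    p <- simParams(nIndividuals = 500L, nSnps = 60L)
    la <- simulateTracts(p, seed = 8)
    gp <- globalProportions(la)
    expect_true(all(abs(colMeans(gp) - p$globalAlpha) < 0.02))
})

test_that("genotypes follow local ancestry exactly at degenerate frequencies", {
    p <- simParams(nIndividuals = 40L, nSnps = 10L)
    la <- simulateTracts(p, seed = 11)
    freqs <- matrix(rep(c(1 - 1e-12, 1e-12, 1e-12), each = 10), 10,
                    dimnames = list(NULL, ancestryLabels()))
    g <- simulateGenotypes(la, freqs, seed = 12)
    # EUR haplotypes carry the reference allele, NAM/AFR never do
    expect_true(all((assay(g, "hap1") == 1) ==
                    (assay(la, "hap1") == 1)))
    expect_true(all((assay(g, "hap2") == 1) ==
                    (assay(la, "hap2") == 1)))
    expect_identical(simulateGenotypes(la, freqs, seed = 12), g)
    expect_error(simulateGenotypes(la, freqs[1:5, ], seed = 1),
                 "SNP mismatch")
})

test_that("sample allele frequencies match the ancestry-weighted mixture", {
    p <- simParams(nIndividuals = 1000L, nSnps = 20L)
    la <- simulateTracts(p, seed = 21)
    freqs <- simulateFrequencies(p, seed = 22)
    g <- simulateGenotypes(la, freqs, seed = 23)
    alphaHat <- colMeans(globalProportions(la))
    expectFreq <- as.vector(freqs %*% alphaHat)
    obsFreq <- rowMeans(assay(g, "dosage")) / 2
    expect_lt(max(abs(obsFreq - expectFreq)), 0.05)
})

test_that("null methylomes carry no causal sites and clean covariates", {
    p <- simParams(nIndividuals = 20L, nSnps = 100L, nSites = 30L,
                   causalMechanism = "null")
    co <- simulateCohort(p, seed = 13)
    expect_length(co$truth$causalSites, 0)
    expect_false(anyNA(co$covariates))
    expect_true(all(co$covariates[c("CD4T", "CD8T", "NK", "Mono",
                                    "Gran", "B")] >= 0))
    p1 <- simParams(nIndividuals = 20L, nSnps = 100L, nSites = 30L,
                    causalFraction = 0.01)
    expect_warning(simulateMethylation(co$ancestry, co$genotypes,
                                       co$covariates, co$manifest, p1,
                                       seed = 1),
                   "zero causal sites")
})

test_that("noiseless ancestry-cis sites are a perfect linear system", {
    p <- simParams(nIndividuals = 50L, nSnps = 200L, nSites = 20L,
                   causalFraction = 0.05, noiseSd = 0, effectScale = 2)
    co <- simulateCohort(p, seed = 17)
    site <- co$truth$causalSites[1]
    wa <- windowedProportions(co$ancestry, co$manifest)
    fit <- fitSite(assay(co$meth, "M")[site, ],
                   ancestryProportion(wa, "NAM")[site, ],
                   ancestryProportion(wa, "AFR")[site, ],
                   co$covariates, covariateNames = colonCovars)
    expect_false(fit$skipped)
    expect_equal(fit$bNam, co$truth$effects$b_nam[1], tolerance = 1e-8)
    expect_equal(fit$bAfr, co$truth$effects$b_afr[1], tolerance = 1e-8)
})

test_that("moderate-noise effect estimates land near the truth", {
    p <- simParams(nIndividuals = 500L, nSnps = 300L, nSites = 10L,
                   causalFraction = 0.1, noiseSd = 1, effectScale = 1)
    co <- simulateCohort(p, seed = 19)
    site <- co$truth$causalSites[1]
    wa <- windowedProportions(co$ancestry, co$manifest)
    fit <- fitSite(assay(co$meth, "M")[site, ],
                   ancestryProportion(wa, "NAM")[site, ],
                   ancestryProportion(wa, "AFR")[site, ],
                   co$covariates, covariateNames = colonCovars)
    expect_lt(abs(fit$bNam - co$truth$effects$b_nam[1]), 0.2)
})

test_that("context enrichment biases where causal sites land", {
    p <- simParams(nIndividuals = 10L, nSnps = 400L, nSites = 2000L,
                   causalFraction = 0.1,
                   contextEnrichment = c(Sea = 3))
    co <- simulateCohort(p, seed = 23)
    isl <- mcols(co$manifest)$island_relation
    seaCausal <- mean(isl[names(co$manifest) %in% co$truth$causalSites]
                      == "Sea")
    seaAll <- mean(isl == "Sea")
    expect_gt(seaCausal / seaAll, 1.3)
    # no enrichment configured: causal category distribution matches tested
    p0 <- simParams(nIndividuals = 10L, nSnps = 400L, nSites = 2000L,
                    causalFraction = 0.1)
    co0 <- simulateCohort(p0, seed = 23)
    isl0 <- mcols(co0$manifest)$island_relation
    sea0 <- mean(isl0[names(co0$manifest) %in% co0$truth$causalSites]
                 == "Sea")
    expect_lt(abs(sea0 - mean(isl0 == "Sea")), 0.1)
})

test_that("second-tissue methylomes share causal structure", {
    p <- simParams(nIndividuals = 40L, nSnps = 200L, nSites = 50L,
                   causalFraction = 0.2)
    co <- simulateCohort(p, seed = 29, tissues = 2)
    expect_identical(co$truth$causalSites, co$truth2$causalSites)
    expect_identical(co$truth$effects$b_nam, co$truth2$effects$b_nam)
    # noise is redrawn
    expect_false(identical(assay(co$meth, "M"), assay(co$meth2, "M")))
})
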