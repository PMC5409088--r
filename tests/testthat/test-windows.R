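# brute-force oracle: indices of same-chromosome SNPs within the closed
# window, by a plain linear scan
windowOracle <- function(sitePos, siteChrom, snpPos, snpChrom, omega,
                         total = TRUE) {
    h <- if (total) omega %/% 2 else omega
    which(snpChrom == siteChrom & snpPos >= sitePos - h &
          snpPos <= sitePos + h)
}

test_that("window boundaries are closed and 1-based", {
    sites <- makeSites(1000)
    snps <- makeSites(c(700, 750, 1250, 1251), ids = paste0("s", 1:4))
    got <- windowSnps(sites, snps, omega = 500)
    expect_equal(as.integer(got[[1]]), c(2L, 3L))  # bounds 750..1250
    # window larger than the chromosome captures every same-chromosome SNP
    expect_equal(as.integer(windowSnps(sites, snps, omega = 1e9)[[1]]),
                 1:4)
    # half-width interpretation doubles the reach
    expect_equal(as.integer(windowSnps(sites, snps, omega = 500,
                                       windowIsTotalSize = FALSE)[[1]]),
                 1:4)
})

test_that("in-window SNP sets match a brute-force scan on random draws", {
    set.seed(101)
    snpPos <- sort(sample.int(1e6, 300))
    snpChrom <- sample(c("chr1", "chr2"), 300, replace = TRUE)
    o <- order(factor(snpChrom), snpPos)
    snpPos <- snpPos[o]; snpChrom <- snpChrom[o]
    snps <- GenomicRanges::GRanges(snpChrom,
                                   IRanges::IRanges(snpPos, width = 1))
    names(snps) <- sprintf("s%d", 1:300)
    for (rep in 1:100) {
        pos <- sample.int(1e6, 1)
        chrom <- sample(c("chr1", "chr2"), 1)
        omega <- sample.int(2e5, 1)
        got <- windowSnps(makeSites(pos, chrom), snps, omega)[[1]]
        expect_equal(as.integer(got),
                     windowOracle(pos, chrom, snpPos, snpChrom, omega))
    }
})

test_that("windowed proportions are direct haplotype call fractions", {
    # 3-SNP window: hap1 = AFR,AFR,EUR; hap2 = NAM,EUR,EUR
    la <- makeAncestry(hap1 = matrix(c(3L, 3L, 1L)),
                       hap2 = matrix(c(2L, 1L, 1L)),
                       pos = c(100, 200, 300))
    wa <- windowedProportions(la, makeSites(200), omega = 500)
    expect_equal(ancestryProportion(wa, "EUR")[1, 1], 3 / 6)
    expect_equal(ancestryProportion(wa, "NAM")[1, 1], 1 / 6)
    expect_equal(ancestryProportion(wa, "AFR")[1, 1], 2 / 6)
    # all calls EUR
    laE <- makeAncestry(matrix(1L, 3, 1), matrix(1L, 3, 1),
                        pos = c(100, 200, 300))
    waE <- windowedProportions(laE, makeSites(200), omega = 500)
    expect_equal(ancestryProportion(waE, "EUR")[1, 1], 1)
    expect_equal(ancestryProportion(waE, "AFR")[1, 1], 0)
})

test_that("proportions equal an independent brute-force tally", {
    p <- simParams(nIndividuals = 25L, nSnps = 300L, nSites = 100L,
                   causalMechanism = "null")
    la <- simulateTracts(p, seed = 31)
    man <- simulateManifest(p, seed = 32)
    wa <- windowedProportions(la, man, omega = 400000)
    h1 <- assay(la, "hap1"); h2 <- assay(la, "hap2")
    pos <- start(rowRanges(la))
    set.seed(33)
    for (i in sample(which(isTested(wa)), 50)) {
        inWin <- which(abs(pos - start(man)[i]) <= 200000)
        for (j in sample(25, 3)) {
            calls <- c(h1[inWin, j], h2[inWin, j])
            expect_equal(ancestryProportion(wa, "NAM")[i, j],
                         mean(calls == 2))
            expect_equal(ancestryProportion(wa, "AFR")[i, j],
                         mean(calls == 3))
        }
    }
})

test_that("counts partition exactly and sites without markers are untested", {
    p <- simParams(nIndividuals = 10L, nSnps = 50L, nSites = 200L,
                   causalMechanism = "null")
    la <- simulateTracts(p, seed = 41)
    man <- simulateManifest(p, seed = 42)
    wa <- windowedProportions(la, man, omega = 100000)
    # exact integer identity: EUR + NAM + AFR counts = 2 * n_snps
    cEur <- 2L * nSnpsInWindow(wa) - wa@countNAM - wa@countAFR
    expect_true(all(cEur >= 0))
    sums <- ancestryProportion(wa, "EUR") + ancestryProportion(wa, "NAM") +
        ancestryProportion(wa, "AFR")
    expect_lt(max(abs(sums[isTested(wa), ] - 1)), 1e-12)
    expect_true(all(is.na(sums[!isTested(wa), ])))
    expect_equal(unname(isTested(wa)), unname(nSnpsInWindow(wa) >= 1))
    # a chromosome with no ancestry-called SNPs is excluded, not an error
    off <- makeSites(5000, chrom = "chr9")
    expect_false(any(isTested(windowedProportions(la, off))))
})

test_that("window nesting makes tested sites monotone in window size", {
    p <- simParams(nIndividuals = 8L, nSnps = 100L, nSites = 300L,
                   causalMechanism = "null")
    la <- simulateTracts(p, seed = 51)
    man <- simulateManifest(p, seed = 52)
    omegas <- c(50000, 200000, 1000000)
    sets <- lapply(omegas, function(om)
        windowSnps(man, rowRanges(la), om))
    for (i in seq_along(man)) {
        expect_true(all(sets[[1]][[i]] %in% sets[[2]][[i]]))
        expect_true(all(sets[[2]][[i]] %in% sets[[3]][[i]]))
    }
    nTested <- vapply(omegas, function(om)
        sum(isTested(windowedProportions(la, man, omega = om))), numeric(1))
    expect_true(all(diff(nTested) >= 0))
})

test_that("global proportions are consistent with per-SNP windows", {
    p <- simParams(nIndividuals = 15L, nSnps = 40L)
    la <- simulateTracts(p, seed = 61)
    gp <- globalProportions(la)
    expect_equal(unname(rowSums(gp)), rep(1, 15))
    # tiling the genome with 1-SNP windows and weighting by SNP count
    # reproduces the genome-wide average
    wa <- windowedProportions(la, rowRanges(la), omega = 1)
    expect_true(all(nSnpsInWindow(wa) == 1))
    expect_equal(colMeans(ancestryProportion(wa, "NAM")),
                 gp[, "NAM"], tolerance = 1e-12)
    # single-ancestry individual
    laE <- makeAncestry(matrix(1L, 4, 1), matrix(1L, 4, 1), pos = 1:4 * 10)
    expect_equal(unname(globalProportions(laE)[1, ]), c(1, 0, 0))
})

test_that("single-SNP windows equal per-SNP ancestry allele counts", {
    p <- simParams(nIndividuals = 12L, nSnps = 30L)
    la <- simulateTracts(p, seed = 71)
    wa <- windowedProportions(la, rowRanges(la), omega = 1)
    for (s in sample(rownames(la), 5)) {
        al <- snpAncestryAlleles(la, s)
        i <- match(s, rownames(la))
        expect_equal(ancestryProportion(wa, "NAM")[i, ],
                     al[, "a_NAM"] / 2)
        expect_equal(ancestryProportion(wa, "AFR")[i, ],
                     al[, "a_AFR"] / 2)
        expect_true(all(rowSums(al) <= 2))
    }
    # haplotypes (NAM, AFR) -> (1, 1); (EUR, EUR) -> (0, 0)
    la2 <- makeAncestry(matrix(c(2L, 1L)), matrix(c(3L, 1L)),
                        pos = c(10, 20))
    expect_equal(unname(snpAncestryAlleles(la2, "snp1")[1, ]), c(1L, 1L))
    expect_equal(unname(snpAncestryAlleles(la2, "snp2")[1, ]), c(0L, 0L))
    expect_error(snpAncestryAlleles(la2, "nope"), "unknown SNP")
})

test_that("effective sample size counts strictly-pure individuals", {
    la <- makeAncestry(
        hap1 = matrix(c(1L, 1L, 1L, 1L,   1L, 1L, 1L, 2L), 4),
        hap2 = matrix(c(1L, 1L, 1L, 1L,   1L, 1L, 2L, 3L), 4),
        pos = c(10, 20, 30, 40))
    wa <- windowedProportions(la, makeSites(25), omega = 100)
    # s1: pi = (1, 0, 0); s2: pi = (0.625, 0.25, 0.125)
    ess <- effectiveSampleSize(wa)
    expect_equal(ess$perSite$n_EUR, 1L)
    expect_equal(ess$perSite$n_NAM, 0L)
    # exactly 0.75 is NOT more than three quarters
    la75 <- makeAncestry(
        hap1 = matrix(c(1L, 1L), 2), hap2 = matrix(c(1L, 2L), 2),
        pos = c(10, 20))
    wa75 <- windowedProportions(la75, makeSites(15), omega = 100)
    expect_equal(ancestryProportion(wa75, "EUR")[1, 1], 0.75)
    ess75 <- effectiveSampleSize(wa75, threshold = 0.75)
    expect_equal(ess75$perSite$n_EUR, 0L)
    expect_error(effectiveSampleSize(wa, threshold = 0.2), "1/3")
    expect_error(effectiveSampleSize(wa, threshold = 1.5), "1/3")
})

test_that("effective-N matches brute force and is monotone in threshold", {
    p <- simParams(nIndividuals = 30L, nSnps = 200L, nSites = 50L,
                   causalMechanism = "null")
    la <- simulateTracts(p, seed = 81)
    man <- simulateManifest(p, seed = 82)
    wa <- windowedProportions(la, man)
    ess <- effectiveSampleSize(wa, threshold = 0.75)
    piE <- ancestryProportion(wa, "EUR")
    piN <- ancestryProportion(wa, "NAM")
    tested <- which(isTested(wa))
    for (k in seq_along(tested)) {
        expect_equal(ess$perSite$n_EUR[k],
                     sum(piE[tested[k], ] > 0.75))
        expect_equal(ess$perSite$n_NAM[k],
                     sum(piN[tested[k], ] > 0.75))
    }
    for (th in c(0.5, 0.6, 0.9)) {
        lo <- effectiveSampleSize(wa, threshold = th)$perSite
        hi <- effectiveSampleSize(wa, threshold = min(th + 0.1, 1))$perSite
        expect_true(all(hi$n_EUR <= lo$n_EUR))
        expect_true(all(hi$n_NAM <= lo$n_NAM))
        expect_true(all(hi$n_AFR <= lo$n_AFR))
    }
})
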