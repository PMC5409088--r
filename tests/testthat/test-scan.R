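test_that("the 2-df LRT follows its closed form", {
    expect_equal(lrt2df(-10, -10), list(stat = 0, p = 1))
    r <- lrt2df(-7.004268, -10)
    expect_equal(r$stat, 5.991464, tolerance = 1e-6)
    expect_equal(r$p, 0.05, tolerance = 1e-5)
    # chi-squared(2) upper tail equals exp(-stat/2)
    stats <- c(0.3, 1, 4.2, 12)
    expect_equal(lrt2df(stats / 2, 0)$p, exp(-stats / 2),
                 tolerance = 1e-12)
    expect_error(lrt2df(-1, 0), "not nested")
})

test_that("BH adjustment reproduces the step-up enumeration oracle", {
    p <- c(0.001, 0.02, 0.04, 0.9)
    got <- bhFdr(p, alpha = 0.05)
    expect_equal(got$reject, c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(got$reject, bhOracle(p, 0.05))
    expect_equal(bhFdr(rep(1, 5), 0.05)$reject, rep(FALSE, 5))
    expect_equal(bhFdr(rep(1, 5), 0.05)$q, rep(1, 5))
    # m = 1: reject iff p <= alpha
    expect_true(bhFdr(0.04, 0.05)$reject)
    expect_false(bhFdr(0.06, 0.05)$reject)
    expect_length(bhFdr(numeric(0), 0.05)$q, 0)
    set.seed(5)
    for (i in 1:50) {
        pv <- runif(sample(3:40, 1))^sample(1:3, 1)
        al <- runif(1, 0.01, 0.2)
        got <- bhFdr(pv, al)
        expect_equal(got$reject, bhOracle(pv, al))
        expect_true(all(got$q >= pv - 1e-15))
    }
})

test_that("per-site fits agree with an independent normal-equations solve", {
    set.seed(61)
    n <- 40
    covars <- plainCovars(n, seed = 62)
    for (i in 1:20) {
        piN <- runif(n, 0, 0.7)
        piA <- pmin(runif(n, 0, 0.3), 1 - piN)
        y <- rnorm(n) + 0.5 * piN
        fit <- fitSite(y, piN, piA, covars)
        X <- cbind(1, covars$age, covars$sex == "M", piN, piA)
        beta <- solve(crossprod(X), crossprod(X, y))
        expect_equal(fit$bNam, beta[4], tolerance = 1e-8)
        expect_equal(fit$bAfr, beta[5], tolerance = 1e-8)
        rss <- sum((y - X %*% beta)^2)
        expect_equal(fit$loglikFull,
                     -n / 2 * (log(2 * pi * rss / n) + 1),
                     tolerance = 1e-8)
    }
})

test_that("degenerate ancestry designs are skipped, not crashed", {
    n <- 30
    covars <- plainCovars(n)
    y <- rnorm(n)
    # pure-EUR cohort: both proportions identically zero
    fit <- fitSite(y, rep(0, n), rep(0, n), covars)
    expect_true(fit$skipped)
    expect_match(fit$reason, "rank-deficient")
    # collinear NAM and AFR proportions
    piN <- runif(n)
    fit2 <- fitSite(y, piN, piN * 2, covars)
    expect_true(fit2$skipped)
})

test_that("the scan recovers causal sites and destroys signal under permutation", {
    p <- simParams(nIndividuals = 100L, nSnps = 500L, nSites = 200L,
                   causalFraction = 0.1, effectScale = 2)
    co <- simulateCohort(p, seed = 71)
    scan <- scanPopDNAm(co$meth, co$ancestry, co$covariates,
                        covariateNames = colonCovars)
    sig <- significantSites(scan)
    expect_gt(length(intersect(sig, co$truth$causalSites)),
              0.5 * length(co$truth$causalSites))
    # breaking the sample alignment of the ancestry table kills the signal
    perm <- co$ancestry
    set.seed(72)
    colnames(perm) <- sample(colnames(perm))
    scanPerm <- suppressMessages(
        scanPopDNAm(co$meth, perm, co$covariates,
                    covariateNames = colonCovars))
    expect_lte(length(significantSites(scanPerm)), 1)
})

test_that("the reduced model is invariant to the window size", {
    p <- simParams(nIndividuals = 40L, nSnps = 300L, nSites = 80L,
                   causalMechanism = "null")
    co <- simulateCohort(p, seed = 81)
    s1 <- scanPopDNAm(co$meth, co$ancestry, co$covariates,
                      omega = 200000L, covariateNames = colonCovars)
    s2 <- scanPopDNAm(co$meth, co$ancestry, co$covariates,
                      omega = 1000000L, covariateNames = colonCovars)
    shared <- intersect(scanTable(s1)$site_id, scanTable(s2)$site_id)
    i1 <- match(shared, scanTable(s1)$site_id)
    i2 <- match(shared, scanTable(s2)$site_id)
    expect_equal(scanTable(s1)$loglik_reduced[i1],
                 scanTable(s2)$loglik_reduced[i2], tolerance = 1e-10)
    expect_true(all(scanTable(s1)$q >= scanTable(s1)$p - 1e-15))
    expect_true(all(scanTable(s1)$lrt >= -1e-8))
})

test_that("adjusting for global ancestry does not inflate the yield", {
    tot <- c(local = 0, global = 0)
    for (seed in 1:5) {
        p <- simParams(nIndividuals = 120L, nSnps = 400L, nSites = 150L,
                       causalFraction = 0.1)
        co <- simulateCohort(p, seed = 90 + seed)
        nl <- length(significantSites(
            scanPopDNAm(co$meth, co$ancestry, co$covariates,
                        covariateNames = colonCovars)))
        ng <- length(significantSites(
            scanPopDNAm(co$meth, co$ancestry, co$covariates,
                        covariateNames = colonCovars,
                        includeGlobalAncestry = TRUE)))
        tot <- tot + c(nl, ng)
    }
    expect_lte(tot["global"], tot["local"])
})

test_that("the window sweep reports nested yields and self-overlap 1", {
    p <- simParams(nIndividuals = 80L, nSnps = 400L, nSites = 150L,
                   causalFraction = 0.1)
    co <- simulateCohort(p, seed = 101)
    sw <- scanSweep(co$meth, co$ancestry, co$covariates,
                    omegaList = c(200000L, 500000L, 1000000L),
                    covariateNames = colonCovars)
    expect_true(all(diff(sw$summary$n_tested) >= 0))
    expect_equal(unname(diag(sw$jaccard)), rep(1, 3))
    expect_true(all(sw$summary$fraction_significant >= 0 &
                    sw$summary$fraction_significant <= 1))
})

test_that("a cohort with no windowed markers is an error", {
    p <- simParams(nIndividuals = 20L, nSnps = 30L, nSites = 10L,
                   causalMechanism = "null")
    co <- simulateCohort(p, seed = 111)
    offMan <- makeSites(seq_len(10) * 100, chrom = "chr7")
    M <- assay(co$meth, "M")[1:10, ]
    rownames(M) <- names(offMan)
    offMeth <- MethylationSet(M, offMan)
    expect_error(scanPopDNAm(offMeth, co$ancestry, co$covariates,
                             covariateNames = colonCovars),
                 "zero tested sites")
})
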