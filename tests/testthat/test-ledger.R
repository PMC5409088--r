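# a small cohort with a scan attached, reused across blocks
ledgerFixture <- function(seed = 201, mech = "popspecific_variant",
                          n = 150L) {
    p <- simParams(nIndividuals = n, nSnps = 150L, nSites = 30L,
                   causalFraction = 0.2, effectScale = 2,
                   causalMechanism = mech)
    co <- simulateCohort(p, seed = seed)
    scan <- suppressMessages(
        scanPopDNAm(co$meth, co$ancestry, co$covariates,
                    covariateNames = colonCovars))
    list(p = p, co = co, scan = scan)
}

test_that("pair enumeration matches the distance rule and counting identity", {
    fx <- ledgerFixture()
    pairs <- enumeratePairs(fx$scan, fx$co$genotypes, distance = 500000L)
    tab <- scanTable(fx$scan)
    sig <- tab[tab$significant, ]
    snpPos <- start(rowRanges(fx$co$genotypes))
    # brute-force filter per significant site
    expected <- 0L
    for (k in seq_len(nrow(sig))) {
        inWin <- which(abs(snpPos - sig$pos[k]) <= 500000)
        expected <- expected + length(inWin)
        got <- pairs$snp_id[pairs$site_id == sig$site_id[k]]
        expect_setequal(got, rownames(fx$co$genotypes)[inWin])
    }
    expect_equal(nrow(pairs), expected)
    # a scan with no significant sites contributes zero pairs
    empty <- fx$scan
    empty@table$significant <- FALSE
    expect_equal(nrow(enumeratePairs(empty, fx$co$genotypes)), 0)
})

test_that("pair fits respect nesting and AIC bookkeeping", {
    set.seed(211)
    n <- 60
    covars <- plainCovars(n, seed = 212)
    for (i in 1:10) {
        dosage <- sample(0:2, n, replace = TRUE)
        aNam <- sample(0:2, n, replace = TRUE)
        aAfr <- pmin(sample(0:2, n, replace = TRUE), 2 - aNam)
        y <- rnorm(n) + 0.2 * dosage
        r <- fitPair(y, dosage, aNam, aAfr, covars)
        expect_gte(r$loglik_joint, r$loglik_gen - 1e-8)
        expect_gte(r$loglik_joint, r$loglik_anc - 1e-8)
        expect_gte(r$loglik_gen, r$loglik_null - 1e-8)
        # AIC = 2k - 2 loglik with k = rank + 1 (error variance included)
        kNull <- ncol(stats::model.matrix(~ age + sex, covars)) + 1
        expect_equal(r$aic_null, 2 * kNull - 2 * r$loglik_null,
                     tolerance = 1e-10)
        expect_equal(r$aic_gen, 2 * (kNull + 1) - 2 * r$loglik_gen,
                     tolerance = 1e-10)
    }
})

test_that("AIC ranking is invariant to M-value location shifts", {
    fx <- ledgerFixture()
    co <- fx$co
    tab <- scanTable(fx$scan)
    site <- tab$site_id[tab$significant][1]
    snp <- rownames(co$genotypes)[which.min(abs(
        start(rowRanges(co$genotypes)) -
        tab$pos[match(site, tab$site_id)]))]
    y <- assay(co$meth, "M")[site, ]
    al <- snpAncestryAlleles(co$ancestry, snp)
    dose <- assay(co$genotypes, "dosage")[snp, ]
    r1 <- fitPair(y, dose, al[, 1], al[, 2], co$covariates,
                  covariateNames = colonCovars)
    r2 <- fitPair(y + 5, dose, al[, 1], al[, 2], co$covariates,
                  covariateNames = colonCovars)
    expect_equal(r1$best_model, r2$best_model)
    expect_equal(r1$aic_anc - r1$aic_gen, r2$aic_anc - r2$aic_gen,
                 tolerance = 1e-8)
})

test_that("unavailable models fall back gracefully and ties go to null", {
    n <- 40
    covars <- plainCovars(n, seed = 221)
    y <- rnorm(n)
    # constant dosage: genotype and joint models unavailable
    r <- fitPair(y, rep(2, n), sample(0:2, n, TRUE),
                 sample(0:1, n, TRUE), covars)
    expect_true(is.na(r$loglik_gen))
    expect_true(is.na(r$p_conditional))
    expect_true(r$best_model %in% c("null", "ancestry"))
    # predictors constructed to carry exactly zero partial signal: all
    # models fit the data equally well and the parameter penalty sends the
    # tie to the null model
    set.seed(222)
    X0 <- stats::model.matrix(~ age + sex, covars)
    dose <- sample(0:2, n, TRUE)
    aN <- sample(0:2, n, TRUE)
    aA <- pmin(sample(0:2, n, TRUE), 2 - aN)
    Z <- qr.resid(qr(X0), cbind(dose, aN, aA))  # residualized predictors
    z <- qr.resid(qr(cbind(X0, Z)), rnorm(n))   # noise orthogonal to them
    yTie <- as.vector(X0 %*% c(1, 0.1, 0.3)) + z
    rTie <- fitPair(yTie, dose, aN, aA, covars)
    expect_equal(rTie$best_model, "null")
    expect_equal(rTie$loglik_gen, rTie$loglik_null, tolerance = 1e-8)
    expect_equal(rTie$loglik_anc, rTie$loglik_null, tolerance = 1e-8)
})

test_that("mechanism discrimination separates the two causal regimes", {
    wins <- c(popspecific_variant = 0, common_variant = 0)
    seeds <- 1:5
    for (s in seeds) {
        for (mech in names(wins)) {
            p <- simParams(nIndividuals = 250L, nSnps = 60L, nSites = 20L,
                           causalFraction = 0.05, effectScale = 2,
                           causalMechanism = mech)
            co <- simulateCohort(p, seed = 300 + s)
            site <- co$truth$causalSites[1]
            snp <- co$truth$causalSnps[[site]]
            al <- snpAncestryAlleles(co$ancestry, snp)
            r <- fitPair(assay(co$meth, "M")[site, ],
                         assay(co$genotypes, "dosage")[snp, ],
                         al[, 1], al[, 2], co$covariates,
                         covariateNames = colonCovars)
            want <- if (mech == "popspecific_variant") "ancestry"
                    else "genotype"
            wins[mech] <- wins[mech] + (r$best_model == want)
        }
    }
    expect_gte(wins[["popspecific_variant"]], 4)
    expect_gte(wins[["common_variant"]], 4)
})

test_that("the ledger summary recounts its own table", {
    fx <- ledgerFixture()
    led <- suppressMessages(
        modelLedger(fx$scan, fx$co$meth, fx$co$ancestry, fx$co$genotypes,
                    fx$co$covariates, covariateNames = colonCovars))
    s <- ledgerSummary(led, fdrAlpha = 0.01, pThreshold = 0.05)
    tab <- pairTable(led)
    expect_equal(sum(s$bestModelFraction), 1)
    expect_equal(s$nPairs, nrow(tab))
    # brute-force recount
    ancSig <- !is.na(tab$q_anc) & tab$q_anc <= 0.01
    expect_equal(s$nSitesAncestrySignificant,
                 length(unique(tab$site_id[ancSig])))
    expect_equal(s$nPairsAncestrySignificant, sum(ancSig))
    if (any(ancSig))
        expect_equal(s$fractionConditionalSignificant,
                     mean(tab$p_conditional[ancSig] < 0.05, na.rm = TRUE))
    expect_true(all(tab$loglik_joint >=
                    pmax(tab$loglik_gen, tab$loglik_anc) - 1e-8,
                    na.rm = TRUE))
})
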