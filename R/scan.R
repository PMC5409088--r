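## The population-specific methylation scan: per-site OLS of M-values on
## windowed NAM/AFR ancestry proportions plus covariates (European ancestry
## is the omitted reference), 2-df likelihood ratio test, BH FDR.

# Gaussian log-likelihood of an OLS fit at the MLE variance
.gaussLoglik <- function(rss, n) {
    if (rss <= 0) return(Inf)
    -n / 2 * (log(2 * pi * rss / n) + 1)
}

# dummy-coded covariate design; character/factor columns are releveled to
# the most frequent category as reference, numeric columns enter linearly
.covariateDesign <- function(covars, covariateNames = NULL) {
    if (is.null(covariateNames)) covariateNames <- colnames(covars)
    miss <- setdiff(covariateNames, colnames(covars))
    if (length(miss))
        stop("covariates not found: ", paste(miss, collapse = ", "))
    d <- covars[, covariateNames, drop = FALSE]
    for (j in seq_along(d)) {
        if (is.character(d[[j]]) || is.factor(d[[j]])) {
            f <- factor(d[[j]])
            ref <- names(sort(table(f), decreasing = TRUE))[1]
            d[[j]] <- stats::relevel(f, ref = ref)
        }
    }
    keep <- complete.cases(d)
    X <- stats::model.matrix(~ ., data = d[keep, , drop = FALSE])
    list(X = X, keep = keep, nDropped = sum(!keep))
}

#' 2-df likelihood ratio test
#'
#' \code{stat = 2 * (loglikFull - loglikReduced)}, referred to the upper
#' tail of the chi-squared distribution with 2 degrees of freedom (for
#' which the tail probability has the closed form \code{exp(-stat/2)}).
#' A statistic more negative than \code{-1e-8} indicates the models were
#' not nested or the fit failed, and is an error.
#'
#' @param loglikFull,loglikReduced log-likelihoods of nested fits
#' @return list with \code{stat} and \code{p}
#' @export
#' @examples
#' lrt2df(-10, -10)          # stat 0, p 1
#' lrt2df(-7.004268, -10)    # stat ~5.99, p ~0.05
lrt2df <- function(loglikFull, loglikReduced) {
    stat <- 2 * (loglikFull - loglikReduced)
    if (any(stat < -1e-8))
        stop("negative LRT statistic: models not nested or fit failed")
    stat <- pmax(stat, 0)
    list(stat = stat, p = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH procedure: q-values are the cumulative-minimum adjusted
#' p-values (\code{p.adjust} with \code{method = "BH"}); the rejection set
#' at level \code{alpha} is every p with \code{q <= alpha}, equivalent to
#' rejecting the largest k with \code{p_(k) <= alpha * k / m} and all
#' smaller.
#'
#' @param p numeric vector of p-values in \code{[0, 1]}
#' @param alpha FDR level
#' @return list with \code{q} and logical \code{reject}
#' @export
bhFdr <- function(p, alpha = 0.01) {
    if (!length(p)) return(list(q = numeric(0), reject = logical(0)))
    if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    q <- p.adjust(p, method = "BH")
    list(q = q, reject = q <= alpha)
}

#' Fit the per-site ancestry model
#'
#' Ordinary least squares of one site's M-values on covariates plus the
#' Native American and African windowed ancestry proportions (full model)
#' and on covariates alone (reduced model), with Gaussian log-likelihoods
#' at the MLE variance. The two ancestry coefficients are interpretable as
#' the mean M-value difference between a pure European and a pure NAM /
#' AFR individual. A design that is not of full column rank (e.g. a cohort
#' without ancestry variation) yields \code{skipped = TRUE} with a reason,
#' not an error.
#'
#' @param y numeric vector of M-values (one site, aligned with rows of
#'   \code{covars})
#' @param piNam,piAfr per-sample windowed ancestry proportions
#' @param covars covariate data.frame (samples in rows, aligned with
#'   \code{y})
#' @param covariateNames columns of \code{covars} to adjust for (default
#'   all)
#' @param pMethod \code{"exact"} for the finite-sample p-value of the LRT
#'   (via its monotone equivalence with the F statistic), \code{"chisq"}
#'   for the asymptotic chi-squared(2) tail
#' @return list with \code{bNam}, \code{bAfr}, \code{loglikFull},
#'   \code{loglikReduced}, \code{stat}, \code{p}, \code{nUsed},
#'   \code{skipped}, \code{reason}
#' @export
fitSite <- function(y, piNam, piAfr, covars, covariateNames = NULL,
                    pMethod = c("exact", "chisq")) {
    pMethod <- match.arg(pMethod)
    dsg <- .covariateDesign(covars, covariateNames)
    keep <- dsg$keep & !is.na(y) & !is.na(piNam) & !is.na(piAfr)
    X0 <- .covariateDesign(covars[keep, , drop = FALSE], covariateNames)$X
    out <- .fitOne(y[keep], X0, qr(X0), piNam[keep], piAfr[keep], pMethod)
    out$nUsed <- sum(keep)
    out
}

# shared per-site worker: X0 and its qr are reused across sites
.fitOne <- function(y, X0, qr0, piNam, piAfr, pMethod) {
    n <- length(y)
    rank0 <- qr0$rank
    if (n < rank0 + 4L)
        return(list(skipped = TRUE, reason = "too few samples"))
    r0 <- qr.resid(qr0, y)
    rss0 <- sum(r0^2)
    X <- cbind(X0, pi_nam = piNam, pi_afr = piAfr)
    fit <- lm.fit(X, y)
    if (fit$rank < rank0 + 2L)
        return(list(skipped = TRUE,
                    reason = "rank-deficient design (collinear ancestry)"))
    rss1 <- sum(fit$residuals^2)
    ll0 <- .gaussLoglik(rss0, n)
    ll1 <- .gaussLoglik(rss1, n)
    stat <- if (is.finite(ll1)) max(0, 2 * (ll1 - ll0)) else Inf
    p <- if (pMethod == "chisq") {
        pchisq(stat, df = 2, lower.tail = FALSE)
    } else if (rss1 <= 0) {
        0
    } else {
        f <- max(0, (rss0 - rss1) / 2) / (rss1 / (n - fit$rank))
        pf(f, 2, n - fit$rank, lower.tail = FALSE)
    }
    list(skipped = FALSE, reason = NA_character_,
         bNam = unname(fit$coefficients["pi_nam"]),
         bAfr = unname(fit$coefficients["pi_afr"]),
         loglikFull = ll1, loglikReduced = ll0, stat = stat, p = p)
}

#' Scan for population-specific methylation sites
#'
#' For every CpG with at least \code{minSnps} ancestry-informative SNPs in
#' its window, regresses M-values on covariates plus the windowed NAM and
#' AFR ancestry proportions, tests the two ancestry terms jointly (2 df)
#' and applies a Benjamini-Hochberg adjustment at \code{fdrAlpha} across
#' all tested sites. Samples are intersected across the three inputs;
#' samples with incomplete covariates are dropped with a log message.
#'
#' \code{includeGlobalAncestry = TRUE} adds each individual's genome-wide
#' NAM and AFR proportions to both the full and the reduced model, the
#' standard guard against confounding of local with global ancestry (it
#' typically reduces the number of significant sites when the two are
#' positively correlated).
#'
#' By default p-values come from the exact finite-sample null distribution
#' of the LRT (through its monotone equivalence with the partial F
#' statistic); \code{pMethod = "chisq"} gives the asymptotic
#' chi-squared(2) tail instead. The reported \code{lrt} statistic is
#' \code{n * log(RSS_reduced / RSS_full)} in both cases.
#'
#' @param meth a \linkS4class{MethylationSet}
#' @param ancestry a \linkS4class{LocalAncestry}
#' @param covars covariate data.frame keyed by sample row names
#' @param omega window size in bp (default 500kb total)
#' @param minSnps minimum in-window SNPs for a site to be tested
#' @param fdrAlpha FDR level for the significance flag (default 0.01)
#' @param covariateNames covariate columns to adjust for (default: all
#'   columns of \code{covars})
#' @param includeGlobalAncestry add genome-wide NAM/AFR proportions to both
#'   models
#' @param pMethod \code{"exact"} (default) or \code{"chisq"}
#' @param windowIsTotalSize see \code{\link{windowSnps}}
#' @return a \linkS4class{ScanResult}
#' @export
scanPopDNAm <- function(meth, ancestry, covars, omega = 500000L,
                        minSnps = 1L, fdrAlpha = 0.01,
                        covariateNames = NULL,
                        includeGlobalAncestry = FALSE,
                        pMethod = c("exact", "chisq"),
                        windowIsTotalSize = TRUE) {
    pMethod <- match.arg(pMethod)
    stopifnot(is(meth, "MethylationSet"), is(ancestry, "LocalAncestry"),
              fdrAlpha > 0, fdrAlpha < 1)
    samples <- intersectSamples(meth, ancestry, covars)
    meth <- meth[, samples]
    ancestry <- ancestry[, samples]
    covars <- covars[samples, , drop = FALSE]

    dsg <- .covariateDesign(covars, covariateNames)
    if (dsg$nDropped > 0) {
        message(dsg$nDropped, " samples dropped for missing covariates")
        keep <- which(dsg$keep)
        meth <- meth[, keep]
        ancestry <- ancestry[, keep]
        covars <- covars[keep, , drop = FALSE]
        dsg <- .covariateDesign(covars, covariateNames)
    }
    X0 <- dsg$X
    if (includeGlobalAncestry) {
        gp <- globalProportions(ancestry)
        X0 <- cbind(X0, global_nam = gp[, "NAM"], global_afr = gp[, "AFR"])
    }
    qr0 <- qr(X0)
    n <- nrow(X0)

    wa <- windowedProportions(ancestry, rowRanges(meth), omega = omega,
                              minSnps = minSnps,
                              windowIsTotalSize = windowIsTotalSize)
    tested <- which(wa@tested)
    if (!length(tested)) stop("zero tested sites: no SNPs in any window")
    piN <- ancestryProportion(wa, "NAM")
    piA <- ancestryProportion(wa, "AFR")
    M <- assay(meth, "M")

    res <- vector("list", length(tested))
    for (k in seq_along(tested)) {
        i <- tested[k]
        res[[k]] <- .fitOne(M[i, ], X0, qr0, piN[i, ], piA[i, ], pMethod)
    }
    skipped <- vapply(res, `[[`, logical(1), "skipped")
    keep <- which(!skipped)
    if (!length(keep)) stop("zero tested sites: all designs rank-deficient")
    idx <- tested[keep]
    num <- function(f) vapply(res[keep], `[[`, numeric(1), f)
    p <- num("p")
    adj <- bhFdr(p, fdrAlpha)
    tab <- DataFrame(
        site_id = rownames(meth)[idx],
        chrom = as.character(seqnames(rowRanges(meth)))[idx],
        pos = start(rowRanges(meth))[idx],
        b_nam = num("bNam"), b_afr = num("bAfr"),
        loglik_full = num("loglikFull"),
        loglik_reduced = num("loglikReduced"),
        lrt = num("stat"), p = p, q = adj$q, significant = adj$reject,
        n_snps = wa@nSnps[idx], n_samples = n)
    new("ScanResult", table = tab, tissue = tissueLabel(meth),
        config = list(omega = as.integer(omega), minSnps = as.integer(minSnps),
                      fdrAlpha = fdrAlpha,
                      covariateNames = covariateNames %||% colnames(covars),
                      includeGlobalAncestry = includeGlobalAncestry,
                      pMethod = pMethod,
                      windowIsTotalSize = windowIsTotalSize),
        counts = list(nTested = length(idx),
                      nExcluded = sum(!wa@tested),
                      nSkipped = sum(skipped),
                      nSamplesUsed = n,
                      nSamplesDropped = dsg$nDropped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Window-size sweep of the scan
#'
#' Runs \code{\link{scanPopDNAm}} at each window size and summarises the
#' absolute and relative yield of significant sites plus the pairwise
#' Jaccard overlap of the significant sets — the number of tested sites is
#' non-decreasing in the window size because windows are nested.
#'
#' @inheritParams scanPopDNAm
#' @param omegaList integer vector of window sizes (at least two)
#' @param ... passed on to \code{scanPopDNAm}
#' @return list with \code{summary} (data.frame: omega, n_tested,
#'   n_significant, fraction_significant), \code{jaccard} (matrix of
#'   overlaps of significant sets) and \code{significant} (list of site-id
#'   vectors per omega)
#' @export
scanSweep <- function(meth, ancestry, covars, omegaList, ...) {
    stopifnot(length(omegaList) >= 2)
    scans <- lapply(omegaList, function(om)
        scanPopDNAm(meth, ancestry, covars, omega = om, ...))
    sig <- lapply(scans, significantSites)
    names(sig) <- as.character(omegaList)
    nt <- vapply(scans, function(s) s@counts$nTested, numeric(1))
    ns <- lengths(sig)
    jac <- outer(seq_along(sig), seq_along(sig), Vectorize(function(i, j) {
        u <- length(union(sig[[i]], sig[[j]]))
        if (u == 0) 1 else length(intersect(sig[[i]], sig[[j]])) / u
    }))
    dimnames(jac) <- list(names(sig), names(sig))
    list(summary = data.frame(omega = omegaList, n_tested = nt,
                              n_significant = ns,
                              fraction_significant = ns / nt),
         jaccard = jac, significant = sig)
}

#' @rdname scanPopDNAm
#' @param x a \linkS4class{ScanResult}
#' @param path output TSV
#' @export
writeScanResult <- function(x, path) {
    stopifnot(is(x, "ScanResult"))
    con <- file(path, "w")
    writeLines(sprintf("# ancestryMeth %s scan: tissue=%s omega=%d fdr=%g pMethod=%s",
                       as.character(packageVersion("ancestryMeth")),
                       x@tissue, x@config$omega, x@config$fdrAlpha,
                       x@config$pMethod), con)
    write.table(as.data.frame(x@table), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    invisible(path)
}
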