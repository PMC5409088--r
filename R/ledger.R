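## Genotype-versus-ancestry model comparison at popDNAm sites: for each
## significant CpG and every panel SNP within `distance` of it, fit
## null / genotype / local-ancestry / joint OLS models sharing the scan
## covariates, compare by AIC, and test ancestry conditional on genotype.

#' Enumerate CpG-SNP pairs for the model comparison
#'
#' All (site, SNP) pairs where the site is significant in the scan and the
#' SNP lies within \code{distance} bp of it (closed interval, same
#' chromosome): a SNP "within 500kb" spans a 1Mb total window.
#'
#' @param scan a \linkS4class{ScanResult}
#' @param genotypes a \linkS4class{PhasedGenotypes}
#' @param distance maximum site-SNP distance in bp (default 500kb)
#' @return \code{DataFrame} with columns \code{site_id}, \code{snp_id}
#' @export
enumeratePairs <- function(scan, genotypes, distance = 500000L) {
    stopifnot(is(scan, "ScanResult"))
    tab <- scanTable(scan)
    sig <- tab[tab$significant, , drop = FALSE]
    if (!nrow(sig)) return(DataFrame(site_id = character(0),
                                     snp_id = character(0)))
    sites <- GRanges(sig$chrom, IRanges(sig$pos, width = 1))
    names(sites) <- sig$site_id
    idx <- windowSnps(sites, rowRanges(genotypes), omega = 2L * distance,
                      windowIsTotalSize = TRUE)
    DataFrame(site_id = rep(sig$site_id, lengths(idx)),
              snp_id = rownames(genotypes)[unlist(idx)])
}

# one pair against a shared covariate design; NA p-values flag models that
# are unavailable (constant dosage, collinear ancestry alleles)
.fitPairOne <- function(y, X0, qr0, dosage, aNam, aAfr, pMethod) {
    n <- length(y)
    rank0 <- qr0$rank
    rss0 <- sum(qr.resid(qr0, y)^2)
    ll0 <- .gaussLoglik(rss0, n)
    aic <- function(ll, rank) 2 * (rank + 1) - 2 * ll  # +1: error variance

    fitAdd <- function(cols, dfAdd) {
        fit <- lm.fit(cbind(X0, cols), y)
        if (fit$rank < rank0 + dfAdd) return(NULL)
        rss <- sum(fit$residuals^2)
        list(ll = .gaussLoglik(rss, n), rss = rss, rank = fit$rank)
    }
    pOf <- function(rssRed, fitFull, df) {
        if (pMethod == "chisq")
            pchisq(max(0, n * log(rssRed / fitFull$rss)), df,
                   lower.tail = FALSE)
        else if (fitFull$rss <= 0) 0
        else pf(max(0, (rssRed - fitFull$rss) / df) /
                    (fitFull$rss / (n - fitFull$rank)),
                df, n - fitFull$rank, lower.tail = FALSE)
    }

    gen <- if (stats::var(dosage) > 0) fitAdd(cbind(dosage = dosage), 1L)
           else NULL
    anc <- fitAdd(cbind(a_nam = aNam, a_afr = aAfr), 2L)
    joint <- if (!is.null(gen) && !is.null(anc))
        fitAdd(cbind(dosage = dosage, a_nam = aNam, a_afr = aAfr), 3L)
    else NULL

    aics <- c(null = aic(ll0, rank0),
              genotype = if (!is.null(gen)) aic(gen$ll, gen$rank) else NA,
              ancestry = if (!is.null(anc)) aic(anc$ll, anc$rank) else NA)
    avail <- which(!is.na(aics))
    # best by AIC; ties broken toward fewer parameters ('avail' is ordered
    # null < genotype < ancestry by parameter count)
    aAvail <- round(aics[avail], 9)
    best <- avail[which(aAvail == min(aAvail))[1]]

    list(loglik_null = ll0,
         loglik_gen = if (is.null(gen)) NA_real_ else gen$ll,
         loglik_anc = if (is.null(anc)) NA_real_ else anc$ll,
         loglik_joint = if (is.null(joint)) NA_real_ else joint$ll,
         aic_null = aics[["null"]], aic_gen = aics[["genotype"]],
         aic_anc = aics[["ancestry"]],
         p_gen = if (is.null(gen)) NA_real_ else pOf(rss0, gen, 1L),
         p_anc = if (is.null(anc)) NA_real_ else pOf(rss0, anc, 2L),
         p_conditional = if (is.null(joint)) NA_real_
                         else pOf(gen$rss, joint, 2L),
         best_model = names(aics)[best])
}

#' Fit the three models for a single CpG-SNP pair
#'
#' Null (covariates only), genotype (+ reference-allele dosage), ancestry
#' (+ NAM and AFR allele counts at the SNP) and joint models by OLS;
#' marginal LRTs of genotype (1 df) and ancestry (2 df) against the null;
#' conditional LRT of the joint model against genotype-only (2 df); AIC
#' with the residual variance counted as a parameter, ties broken toward
#' fewer parameters. A constant dosage marks the genotype and joint models
#' unavailable rather than failing.
#'
#' @param y M-values for the site, aligned with \code{covars} rows
#' @param dosage reference-allele dosage at the SNP
#' @param aNam,aAfr ancestry allele counts at the SNP (see
#'   \code{\link{snpAncestryAlleles}})
#' @param covars covariate data.frame
#' @param covariateNames covariate columns (default all)
#' @param pMethod \code{"exact"} or \code{"chisq"} (see
#'   \code{\link{scanPopDNAm}})
#' @return named list of log-likelihoods, AICs, p-values and
#'   \code{best_model}
#' @export
fitPair <- function(y, dosage, aNam, aAfr, covars, covariateNames = NULL,
                    pMethod = c("exact", "chisq")) {
    pMethod <- match.arg(pMethod)
    dsg <- .covariateDesign(covars, covariateNames)
    keep <- dsg$keep & !is.na(y) & !is.na(dosage)
    X0 <- .covariateDesign(covars[keep, , drop = FALSE], covariateNames)$X
    .fitPairOne(y[keep], X0, qr(X0), dosage[keep], aNam[keep], aAfr[keep],
                pMethod)
}

#' Genotype-versus-ancestry model ledger
#'
#' Runs \code{\link{fitPair}} for every pair from
#' \code{\link{enumeratePairs}}, then BH-adjusts the genotype and the
#' ancestry marginal p-values separately (each analysis at its own FDR).
#'
#' @param scan a \linkS4class{ScanResult} with significant sites
#' @param meth the \linkS4class{MethylationSet} the scan was run on
#' @param ancestry a \linkS4class{LocalAncestry}
#' @param genotypes a \linkS4class{PhasedGenotypes}
#' @param covars covariate data.frame
#' @param distance site-SNP distance cutoff in bp
#' @param fdrAlpha FDR level for the per-analysis BH adjustment
#' @param covariateNames covariate columns (should match the scan's)
#' @param pMethod \code{"exact"} or \code{"chisq"}
#' @return a \linkS4class{ModelLedger}
#' @export
modelLedger <- function(scan, meth, ancestry, genotypes, covars,
                        distance = 500000L, fdrAlpha = 0.01,
                        covariateNames = NULL,
                        pMethod = c("exact", "chisq")) {
    pMethod <- match.arg(pMethod)
    samples <- intersectSamples(meth, ancestry, genotypes, covars)
    meth <- meth[, samples]
    ancestry <- ancestry[, samples]
    genotypes <- genotypes[, samples]
    covars <- covars[samples, , drop = FALSE]
    dsg <- .covariateDesign(covars, covariateNames)
    if (dsg$nDropped > 0) {
        keep <- which(dsg$keep)
        meth <- meth[, keep]; ancestry <- ancestry[, keep]
        genotypes <- genotypes[, keep]
        covars <- covars[keep, , drop = FALSE]
        dsg <- .covariateDesign(covars, covariateNames)
    }
    X0 <- dsg$X
    qr0 <- qr(X0)

    pairs <- enumeratePairs(scan, genotypes, distance)
    if (!nrow(pairs)) stop("no pairs: scan has no significant sites")
    M <- assay(meth, "M")
    dosage <- assay(genotypes, "dosage")
    h1 <- assay(ancestry, "hap1"); h2 <- assay(ancestry, "hap2")
    snpIdx <- match(pairs$snp_id, rownames(genotypes))
    ancIdx <- match(pairs$snp_id, rownames(ancestry))
    if (anyNA(ancIdx))
        stop("pair SNPs missing from the local-ancestry table")
    siteIdx <- match(pairs$site_id, rownames(meth))

    rows <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        i <- ancIdx[k]
        rows[[k]] <- .fitPairOne(M[siteIdx[k], ], X0, qr0,
                                 dosage[snpIdx[k], ],
                                 (h1[i, ] == 2L) + (h2[i, ] == 2L),
                                 (h1[i, ] == 3L) + (h2[i, ] == 3L),
                                 pMethod)
    }
    num <- function(f) vapply(rows, function(r)
        as.numeric(r[[f]]), numeric(1))
    tab <- DataFrame(pairs,
        loglik_null = num("loglik_null"), loglik_gen = num("loglik_gen"),
        loglik_anc = num("loglik_anc"), loglik_joint = num("loglik_joint"),
        aic_null = num("aic_null"), aic_gen = num("aic_gen"),
        aic_anc = num("aic_anc"),
        p_gen = num("p_gen"), p_anc = num("p_anc"),
        p_conditional = num("p_conditional"),
        best_model = vapply(rows, `[[`, character(1), "best_model"))
    tab$q_gen <- p.adjust(tab$p_gen, method = "BH")
    tab$q_anc <- p.adjust(tab$p_anc, method = "BH")
    new("ModelLedger", pairs = tab,
        config = list(distance = as.integer(distance), fdrAlpha = fdrAlpha,
                      pMethod = pMethod, nSamples = nrow(X0)))
}

#' Summarise a model ledger
#'
#' The quantities of the genetic-architecture analysis: the fraction of
#' pairs best explained by each model (AIC), the number of sites with at
#' least one SNP whose ancestry (resp. genotype) association is
#' significant after the per-analysis BH adjustment, and — among
#' ancestry-significant pairs — the fraction whose ancestry effect remains
#' significant (\code{p_conditional < pThreshold}) when adjusting for the
#' genotype.
#'
#' @param ledger a \linkS4class{ModelLedger}
#' @param fdrAlpha FDR level applied to the stored q-values
#' @param pThreshold threshold on the conditional p-value
#' @return list of summary quantities
#' @export
ledgerSummary <- function(ledger, fdrAlpha = 0.01, pThreshold = 0.05) {
    tab <- pairTable(ledger)
    best <- factor(tab$best_model, levels = c("null", "genotype", "ancestry"))
    frac <- as.numeric(table(best)) / nrow(tab)
    names(frac) <- levels(best)
    ancSig <- !is.na(tab$q_anc) & tab$q_anc <= fdrAlpha
    genSig <- !is.na(tab$q_gen) & tab$q_gen <= fdrAlpha
    condSig <- ancSig & !is.na(tab$p_conditional) &
        tab$p_conditional < pThreshold
    list(nPairs = nrow(tab),
         nSites = length(unique(tab$site_id)),
         bestModelFraction = frac,
         nSitesAncestrySignificant = length(unique(tab$site_id[ancSig])),
         nSitesGenotypeSignificant = length(unique(tab$site_id[genSig])),
         nPairsAncestrySignificant = sum(ancSig),
         fractionConditionalSignificant =
             if (any(ancSig)) mean(tab$p_conditional[ancSig] < pThreshold,
                                   na.rm = TRUE) else NA_real_,
         fdrAlpha = fdrAlpha, pThreshold = pThreshold)
}

#' @rdname modelLedger
#' @param x a \linkS4class{ModelLedger}
#' @param path output TSV
#' @export
writeModelLedger <- function(x, path) {
    stopifnot(is(x, "ModelLedger"))
    con <- file(path, "w")
    writeLines(sprintf("# ancestryMeth %s ledger: distance=%d fdr=%g",
                       as.character(packageVersion("ancestryMeth")),
                       x@config$distance, x@config$fdrAlpha), con)
    write.table(as.data.frame(x@pairs), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    invisible(path)
}
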