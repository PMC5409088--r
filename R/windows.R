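## Windowed local-ancestry proportions. The window around a CpG at position
## l is the closed interval [l - h, l + h] on the same chromosome, with
## h = floor(omega / 2) when omega is the total window size (the default) or
## h = omega when omega is a half-width. Windows never span chromosomes.

.halfWidth <- function(omega, windowIsTotalSize) {
    stopifnot(omega > 0)
    if (windowIsTotalSize) omega %/% 2L else as.integer(omega)
}

#' SNPs falling in the window around each site
#'
#' Returns, for each query site, the indices of SNPs with position in the
#' closed interval \code{[pos - h, pos + h]} on the same chromosome, where
#' \code{h = floor(omega/2)} if \code{omega} is the total window size. Ties
#' at the boundary are included; the empty set is allowed.
#'
#' @param sites \code{GRanges} of query sites (width 1)
#' @param snps \code{GRanges} of SNP positions (width 1)
#' @param omega window size in basepairs
#' @param windowIsTotalSize if \code{TRUE} (default) \code{omega} is the
#'   total window size, i.e. half-width \code{floor(omega/2)}; if
#'   \code{FALSE} it is the half-width itself
#' @return an \code{IntegerList}, one element per site, with indices into
#'   \code{snps}
#' @export
#' @examples
#' sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, width = 1))
#' snps <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(700, 750, 1250, 1251), width = 1))
#' windowSnps(sites, snps, omega = 500)  # 750 and 1250 are in [750, 1250]
windowSnps <- function(sites, snps, omega, windowIsTotalSize = TRUE) {
    h <- .halfWidth(omega, windowIsTotalSize)
    win <- GRanges(seqnames(sites),
                   IRanges(pmax(1L, start(sites) - h), start(sites) + h))
    hits <- findOverlaps(win, snps)
    S4Vectors::splitAsList(S4Vectors::subjectHits(hits),
                         factor(S4Vectors::queryHits(hits),
                                levels = seq_along(sites)))
}

#' Windowed ancestry proportions per site and individual
#'
#' For every site, counts ancestry-i calls across both haplotypes of each
#' individual over the SNPs in the window centred on the site, and divides
#' by twice the number of in-window SNPs. Counting is integer arithmetic,
#' so the three proportions sum to one exactly. Sites with fewer than
#' \code{minSnps} in-window SNPs (including sites on chromosomes without
#' any ancestry-called SNPs) are flagged untested, not errors.
#'
#' @param ancestry a \linkS4class{LocalAncestry}
#' @param sites \code{GRanges} of CpG sites (e.g. a manifest or
#'   \code{rowRanges} of a \linkS4class{MethylationSet})
#' @param omega window size in basepairs (default 500kb, total size)
#' @param minSnps minimum in-window SNP count for a site to be tested
#'   (default 1: only sites without any markers are excluded)
#' @param windowIsTotalSize see \code{\link{windowSnps}}
#' @return a \linkS4class{WindowedAncestry}
#' @export
windowedProportions <- function(ancestry, sites, omega = 500000L,
                                minSnps = 1L, windowIsTotalSize = TRUE) {
    stopifnot(is(ancestry, "LocalAncestry"), minSnps >= 1L)
    if (is(sites, "MethylationSet")) sites <- rowRanges(sites)
    h <- .halfWidth(omega, windowIsTotalSize)
    snps <- rowRanges(ancestry)
    nSamp <- ncol(ancestry)
    nSite <- length(sites)
    cNAM <- matrix(0L, nSite, nSamp)
    cAFR <- matrix(0L, nSite, nSamp)
    nIn <- integer(nSite)
    h1 <- assay(ancestry, "hap1"); h2 <- assay(ancestry, "hap2")
    siteChrom <- as.character(seqnames(sites))
    snpChrom <- as.character(seqnames(snps))
    for (chr in unique(siteChrom)) {
        si <- which(siteChrom == chr)
        pj <- which(snpChrom == chr)
        if (!length(pj)) next
        pos <- start(snps)[pj]  # sorted by class validity
        # cumulative per-sample call counts along the chromosome, so any
        # window reduces to a difference of two rows
        csNAM <- apply((h1[pj, , drop = FALSE] == 2L) +
                       (h2[pj, , drop = FALSE] == 2L), 2L, cumsum)
        csAFR <- apply((h1[pj, , drop = FALSE] == 3L) +
                       (h2[pj, , drop = FALSE] == 3L), 2L, cumsum)
        csNAM <- rbind(0L, matrix(csNAM, ncol = nSamp))
        csAFR <- rbind(0L, matrix(csAFR, ncol = nSamp))
        l <- start(sites)[si]
        a <- findInterval(l - h - 1L, pos) + 1L  # first SNP with pos >= l-h
        b <- findInterval(l + h, pos)            # last SNP with pos <= l+h
        nIn[si] <- pmax(0L, b - a + 1L)
        ok <- nIn[si] > 0L
        cNAM[si[ok], ] <- csNAM[b[ok] + 1L, , drop = FALSE] -
            csNAM[a[ok], , drop = FALSE]
        cAFR[si[ok], ] <- csAFR[b[ok] + 1L, , drop = FALSE] -
            csAFR[a[ok], , drop = FALSE]
    }
    new("WindowedAncestry", sites = sites, samples = colnames(ancestry),
        countNAM = cNAM, countAFR = cAFR, nSnps = nIn,
        tested = nIn >= minSnps,
        window = list(omega = as.integer(omega), minSnps = as.integer(minSnps),
                      windowIsTotalSize = windowIsTotalSize))
}

#' Genome-wide ancestry proportions per individual
#'
#' The same counting rule as \code{\link{windowedProportions}} applied to
#' all SNPs in the table: per individual, the fraction of ancestry-i calls
#' over both haplotypes at every SNP. Rows sum to one exactly.
#'
#' @param ancestry a \linkS4class{LocalAncestry}
#' @return numeric matrix, samples x 3, columns EUR/NAM/AFR
#' @export
globalProportions <- function(ancestry) {
    stopifnot(is(ancestry, "LocalAncestry"), nrow(ancestry) > 0L)
    h1 <- assay(ancestry, "hap1"); h2 <- assay(ancestry, "hap2")
    denom <- 2L * nrow(ancestry)
    cnt <- vapply(1:3, function(k)
        colSums(h1 == k) + colSums(h2 == k), numeric(ncol(ancestry)))
    p <- matrix(cnt / denom, ncol = 3,
                dimnames = list(colnames(ancestry), ancestryLabels()))
    p
}

#' Ancestry allele counts at a single SNP
#'
#' Counts, over the two haplotypes of each individual, the alleles of
#' Native American and of African ancestry at one SNP. These are the
#' regressors of the local-ancestry model in the genotype-versus-ancestry
#' comparison; \code{a_NAM + a_AFR <= 2} and the European count is the
#' remainder.
#'
#' @param ancestry a \linkS4class{LocalAncestry}
#' @param snpId a SNP id present in the table
#' @return integer matrix, samples x 2, columns \code{a_NAM}, \code{a_AFR}
#' @export
snpAncestryAlleles <- function(ancestry, snpId) {
    i <- match(snpId, rownames(ancestry))
    if (is.na(i)) stop("unknown SNP id: ", snpId)
    h1 <- assay(ancestry, "hap1")[i, ]
    h2 <- assay(ancestry, "hap2")[i, ]
    cbind(a_NAM = (h1 == 2L) + (h2 == 2L),
          a_AFR = (h1 == 3L) + (h2 == 3L))
}

#' Effective sample size at tested sites
#'
#' For each tested site, counts the individuals of largely pure local
#' ancestry — more than \code{threshold} (default three quarters, strict
#' inequality) of the windowed ancestry proportion for one population —
#' and averages the counts over tested sites. The three per-site counts
#' come from disjoint individual sets whenever \code{threshold > 1/3},
#' which is why smaller thresholds are rejected.
#'
#' @param wa a \linkS4class{WindowedAncestry}
#' @param threshold purity cutoff in \code{(1/3, 1]}; an individual is
#'   counted for population i at a site if \code{pi_i > threshold}
#' @return list with \code{perSite} (a \code{DataFrame}: site_id, n_EUR,
#'   n_NAM, n_AFR over tested sites), \code{average} (named numeric,
#'   genome-average count per population) and \code{threshold}
#' @export
effectiveSampleSize <- function(wa, threshold = 0.75) {
    stopifnot(is(wa, "WindowedAncestry"))
    if (threshold <= 1 / 3 || threshold > 1)
        stop("threshold must lie in (1/3, 1]")
    if (!any(wa@tested)) stop("no tested sites")
    idx <- which(wa@tested)
    counts <- lapply(ancestryLabels(), function(pop) {
        p <- ancestryProportion(wa, pop)[idx, , drop = FALSE]
        unname(as.integer(rowSums(p > threshold)))
    })
    names(counts) <- ancestryLabels()
    list(perSite = DataFrame(site_id = names(wa@sites)[idx],
                             n_EUR = counts$EUR,
                             n_NAM = counts$NAM,
                             n_AFR = counts$AFR),
         average = vapply(counts, mean, numeric(1)),
         threshold = threshold)
}

#' @rdname windowedProportions
#' @param x a \linkS4class{WindowedAncestry}
#' @param path output TSV (long format: site_id, sample, pi_eur, pi_nam,
#'   pi_afr, n_snps; untested sites omitted)
#' @export
writeWindowedAncestry <- function(x, path) {
    stopifnot(is(x, "WindowedAncestry"))
    idx <- which(x@tested)
    pe <- ancestryProportion(x, "EUR")[idx, , drop = FALSE]
    pn <- ancestryProportion(x, "NAM")[idx, , drop = FALSE]
    pa <- ancestryProportion(x, "AFR")[idx, , drop = FALSE]
    df <- data.frame(
        site_id = rep(names(x@sites)[idx], times = length(x@samples)),
        sample = rep(x@samples, each = length(idx)),
        pi_eur = as.vector(pe), pi_nam = as.vector(pn),
        pi_afr = as.vector(pa),
        n_snps = rep(x@nSnps[idx], times = length(x@samples)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
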