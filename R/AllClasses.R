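#' @include AllGenerics.R
NULL

# sort order by (chromosome, position) without relying on S4 order methods
.grOrder <- function(gr)
    order(as.integer(as.factor(as.character(seqnames(gr)))), start(gr))

## Central S4 containers. LocalAncestry, MethylationSet and PhasedGenotypes
## extend RangedSummarizedExperiment so the usual [i, j] subsetting, assay()
## and colnames() semantics apply; WindowedAncestry, ScanResult and
## ModelLedger are plain S4 with accessors.

#' Phased per-SNP local-ancestry calls
#'
#' A \linkS4class{RangedSummarizedExperiment} with two integer assays,
#' \code{hap1} and \code{hap2}, holding the ancestry code of each haplotype
#' at each SNP (1 = EUR, 2 = NAM, 3 = AFR; see \code{\link{ancestryLabels}}).
#' Rows are SNPs (a \link[GenomicRanges]{GRanges} of width-1 positions,
#' 1-based, named by SNP id, sorted by chromosome and position); columns are
#' samples. This is the in-memory form of an RFMix-Viterbi-style call set.
#'
#' @param hap1,hap2 integer matrices (SNPs x samples) of ancestry codes in
#'   \code{1:3}
#' @param snps \code{GRanges} of SNP positions, named by SNP id
#' @return a \code{LocalAncestry} object (rows sorted by position)
#' @aliases LocalAncestry ancestryCodes,LocalAncestry-method
#' @export LocalAncestry
#' @exportClass LocalAncestry
#' @examples
#' snps <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' names(snps) <- c("rs1", "rs2")
#' h <- matrix(1L, 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' la <- LocalAncestry(h, h, snps)
#' ancestryCodes(la, 2)
setClass("LocalAncestry", contains = "RangedSummarizedExperiment")

LocalAncestry <- function(hap1, hap2, snps) {
    stopifnot(is.matrix(hap1), is.matrix(hap2),
              all(dim(hap1) == dim(hap2)), length(snps) == nrow(hap1))
    if (is.null(names(snps)))
        stop("'snps' must be named by SNP id")
    storage.mode(hap1) <- "integer"
    storage.mode(hap2) <- "integer"
    o <- .grOrder(snps)
    se <- SummarizedExperiment(
        assays = list(hap1 = hap1[o, , drop = FALSE],
                      hap2 = hap2[o, , drop = FALSE]),
        rowRanges = snps[o])
    new("LocalAncestry", se)
}

setValidity("LocalAncestry", function(object) {
    msg <- character()
    if (!identical(assayNames(object), c("hap1", "hap2")))
        msg <- c(msg, "assays must be 'hap1' and 'hap2'")
    for (a in assayNames(object)) {
        v <- assay(object, a)
        if (anyNA(v) || !all(v %in% 1:3))
            msg <- c(msg, sprintf(
                "assay '%s' must contain only codes 1:3 (EUR/NAM/AFR), no NA", a))
    }
    rr <- rowRanges(object)
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
        msg <- c(msg, "SNP ids (rownames) must be present and unique")
    if (!identical(.grOrder(rr), seq_along(rr)))
        msg <- c(msg, "SNPs must be sorted by (chromosome, position)")
    if (is.null(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present")
    if (length(msg)) msg else TRUE
})

#' @rdname LocalAncestry-class
setMethod("ancestryCodes", "LocalAncestry", function(x, haplotype = 1L) {
    stopifnot(haplotype %in% 1:2)
    assay(x, paste0("hap", haplotype))
})

setMethod("show", "LocalAncestry", function(object) {
    cat("LocalAncestry:", nrow(object), "SNPs x", ncol(object),
        "samples (2 haplotypes each)\n")
    cat("  ancestries:", paste(ancestryLabels(), collapse = "/"), "\n")
    cat("  chromosomes:",
        paste(unique(as.character(seqnames(rowRanges(object)))), collapse = ", "),
        "\n")
})

#' Methylation M-values with CpG coordinates
#'
#' A \linkS4class{RangedSummarizedExperiment} with a single numeric assay
#' \code{M} of methylation M-values (logit2 of the methylated fraction).
#' Rows are CpG sites (width-1 \code{GRanges}, named by site id); columns
#' are samples. The tissue the matrix was assayed in is kept in
#' \code{metadata()$tissue} and returned by \code{tissueLabel()}.
#'
#' @param M numeric matrix (sites x samples) of finite M-values
#' @param sites \code{GRanges} of CpG positions, named by site id
#' @param tissue single string labelling the tissue
#' @return a \code{MethylationSet}
#' @aliases MethylationSet tissueLabel,MethylationSet-method
#' @export MethylationSet
#' @exportClass MethylationSet
setClass("MethylationSet", contains = "RangedSummarizedExperiment")

MethylationSet <- function(M, sites, tissue = "unknown") {
    stopifnot(is.matrix(M), length(sites) == nrow(M))
    if (is.null(names(sites)))
        stop("'sites' must be named by site id")
    se <- SummarizedExperiment(assays = list(M = M), rowRanges = sites)
    metadata(se)$tissue <- tissue
    new("MethylationSet", se)
}

setValidity("MethylationSet", function(object) {
    msg <- character()
    if (!identical(assayNames(object), "M"))
        msg <- c(msg, "single assay 'M' required")
    if (!all(is.finite(assay(object, "M"))))
        msg <- c(msg, "M-values must be finite")
    rr <- rowRanges(object)
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
        msg <- c(msg, "site ids must be present and unique")
    if (is.null(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present")
    if (length(msg)) msg else TRUE
})

#' @rdname MethylationSet-class
setMethod("tissueLabel", "MethylationSet", function(x) {
    t <- metadata(x)$tissue
    if (is.null(t)) "unknown" else t
})

setMethod("show", "MethylationSet", function(object) {
    cat("MethylationSet:", nrow(object), "sites x", ncol(object),
        "samples, tissue =", tissueLabel(object), "\n")
})

#' Phased genotypes with reference-allele dosage
#'
#' A \linkS4class{RangedSummarizedExperiment} with assay \code{dosage}
#' counting reference alleles (0/1/2) and, when phased input is available,
#' assays \code{hap1}/\code{hap2} with per-haplotype indicators (1 =
#' reference allele carried). Rows are SNPs named by id, columns samples.
#'
#' @param dosage integer matrix (SNPs x samples) in 0:2
#' @param snps \code{GRanges} of SNP positions, named by SNP id
#' @param hap1,hap2 optional 0/1 matrices; when given,
#'   \code{dosage == hap1 + hap2} is enforced
#' @return a \code{PhasedGenotypes}
#' @aliases PhasedGenotypes
#' @export PhasedGenotypes
#' @exportClass PhasedGenotypes
setClass("PhasedGenotypes", contains = "RangedSummarizedExperiment")

PhasedGenotypes <- function(dosage, snps, hap1 = NULL, hap2 = NULL) {
    stopifnot(is.matrix(dosage), length(snps) == nrow(dosage))
    if (is.null(names(snps)))
        stop("'snps' must be named by SNP id")
    storage.mode(dosage) <- "integer"
    assays <- list(dosage = dosage)
    if (!is.null(hap1) || !is.null(hap2)) {
        stopifnot(!is.null(hap1), !is.null(hap2))
        storage.mode(hap1) <- "integer"
        storage.mode(hap2) <- "integer"
        assays$hap1 <- hap1
        assays$hap2 <- hap2
    }
    o <- .grOrder(snps)
    assays <- lapply(assays, function(a) a[o, , drop = FALSE])
    se <- SummarizedExperiment(assays = assays, rowRanges = snps[o])
    new("PhasedGenotypes", se)
}

setValidity("PhasedGenotypes", function(object) {
    msg <- character()
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' required")
    else {
        d <- assay(object, "dosage")
        if (anyNA(d) || !all(d %in% 0:2))
            msg <- c(msg, "dosage must be 0, 1 or 2 (reference-allele count)")
        if (all(c("hap1", "hap2") %in% assayNames(object))) {
            h <- assay(object, "hap1") + assay(object, "hap2")
            if (!all(h == d))
                msg <- c(msg, "dosage must equal hap1 + hap2 when phased")
        }
    }
    rr <- rowRanges(object)
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
        msg <- c(msg, "SNP ids must be present and unique")
    if (length(msg)) msg else TRUE
})

setMethod("show", "PhasedGenotypes", function(object) {
    cat("PhasedGenotypes:", nrow(object), "SNPs x", ncol(object), "samples",
        if (all(c("hap1", "hap2") %in% assayNames(object))) "(phased)\n"
        else "(unphased)\n")
})

#' Per-site windowed local-ancestry proportions
#'
#' For each CpG site and individual, the proportion of ancestry-i alleles
#' among SNPs falling in a window centred on the site: the count of
#' ancestry-i calls over both haplotypes divided by twice the number of
#' in-window SNPs. Counts are stored as integers so the three proportions
#' sum to one exactly by construction. Sites with fewer than \code{minSnps}
#' in-window SNPs are flagged untested and carry \code{NA} proportions.
#'
#' @slot sites \code{GRanges} of the CpG sites (named by site id)
#' @slot samples character vector of sample ids
#' @slot countNAM,countAFR integer matrices (sites x samples) of ancestry
#'   call counts over both haplotypes; EUR counts are implied
#' @slot nSnps integer in-window SNP count per site
#' @slot tested logical per site
#' @slot window list with \code{omega}, \code{minSnps},
#'   \code{windowIsTotalSize}
#' @aliases WindowedAncestry
#'   ancestryProportion,WindowedAncestry-method
#'   nSnpsInWindow,WindowedAncestry-method isTested,WindowedAncestry-method
#' @exportClass WindowedAncestry
setClass("WindowedAncestry", representation(
    sites = "GRanges", samples = "character",
    countNAM = "matrix", countAFR = "matrix",
    nSnps = "integer", tested = "logical", window = "list"))

setValidity("WindowedAncestry", function(object) {
    msg <- character()
    n <- length(object@sites)
    if (nrow(object@countNAM) != n || nrow(object@countAFR) != n ||
        length(object@nSnps) != n || length(object@tested) != n)
        msg <- c(msg, "per-site slots must align with 'sites'")
    if (ncol(object@countNAM) != length(object@samples))
        msg <- c(msg, "count columns must align with 'samples'")
    tot <- object@countNAM + object@countAFR
    lim <- 2L * object@nSnps
    if (any(tot > lim))
        msg <- c(msg, "ancestry counts exceed 2 x n_snps")
    if (length(msg)) msg else TRUE
})

#' @rdname WindowedAncestry-class
setMethod("ancestryProportion", "WindowedAncestry", function(x, population) {
    population <- match.arg(population, ancestryLabels())
    denom <- 2 * x@nSnps
    cnt <- switch(population,
        NAM = x@countNAM,
        AFR = x@countAFR,
        EUR = denom - x@countNAM - x@countAFR)
    p <- cnt / denom
    p[!x@tested, ] <- NA_real_
    rownames(p) <- names(x@sites)
    colnames(p) <- x@samples
    p
})

#' @rdname WindowedAncestry-class
setMethod("nSnpsInWindow", "WindowedAncestry", function(x)
    setNames(x@nSnps, names(x@sites)))

#' @rdname WindowedAncestry-class
setMethod("isTested", "WindowedAncestry", function(x)
    setNames(x@tested, names(x@sites)))

setMethod("show", "WindowedAncestry", function(object) {
    cat("WindowedAncestry:", length(object@sites), "sites x",
        length(object@samples), "samples\n")
    cat(sprintf("  window: omega=%d bp (%s), minSnps=%d; %d sites tested\n",
        object@window$omega,
        if (isTRUE(object@window$windowIsTotalSize)) "total size"
        else "half-width",
        object@window$minSnps, sum(object@tested)))
})

#' Result of the population-specific methylation scan
#'
#' Per tested site: the estimated mean M-value difference between a pure
#' European and a pure Native American (\code{b_nam}) or African
#' (\code{b_afr}) individual, model log-likelihoods, the 2-df LRT statistic,
#' its p-value, the BH-adjusted q-value and the significance call at the
#' scan's FDR level. Accessors: \code{scanTable()} for the full per-site
#' \code{DataFrame}, \code{significantSites()} for the significant site ids.
#'
#' @slot table a \code{DataFrame}, one row per tested site
#' @slot tissue tissue label carried over from the input
#' @slot config list of scan settings (window, FDR level, covariates, ...)
#' @slot counts list of bookkeeping counts (tested / excluded / skipped
#'   sites, samples used and dropped)
#' @aliases ScanResult scanTable,ScanResult-method
#'   significantSites,ScanResult-method
#' @exportClass ScanResult
setClass("ScanResult", representation(
    table = "DataFrame", tissue = "character", config = "list",
    counts = "list"))

#' @rdname ScanResult-class
setMethod("scanTable", "ScanResult", function(x) x@table)

#' @rdname ScanResult-class
setMethod("significantSites", "ScanResult", function(x, alpha = NULL) {
    tab <- x@table
    if (is.null(alpha))
        tab$site_id[tab$significant]
    else
        tab$site_id[tab$q <= alpha]
})

setMethod("show", "ScanResult", function(object) {
    cat("ScanResult (", object@tissue, "): ", nrow(object@table),
        " sites tested, ", sum(object@table$significant),
        " significant at FDR ", object@config$fdrAlpha * 100, "%\n", sep = "")
    cat(sprintf("  window omega=%d bp, %d samples; excluded (no SNPs): %d, skipped (rank): %d\n",
        object@config$omega, object@counts$nSamplesUsed,
        object@counts$nExcluded, object@counts$nSkipped))
})

#' Genotype-versus-ancestry model comparison ledger
#'
#' One row per (CpG site, SNP) pair: log-likelihoods and AICs of the null
#' (covariates only), genotype (+ reference-allele dosage) and local-ancestry
#' (+ NAM/AFR allele counts) models, marginal LRT p/q-values for genotype
#' and ancestry, the conditional p-value of ancestry adjusted for genotype
#' (joint vs genotype-only, 2 df) and the AIC-best model label.
#'
#' @slot pairs a \code{DataFrame}, one row per pair
#' @slot config list of settings (distance, FDR level, ...)
#' @aliases ModelLedger pairTable,ModelLedger-method
#' @exportClass ModelLedger
setClass("ModelLedger", representation(pairs = "DataFrame", config = "list"))

#' @rdname ModelLedger-class
setMethod("pairTable", "ModelLedger", function(x) x@pairs)

setMethod("show", "ModelLedger", function(object) {
    tab <- table(factor(object@pairs$best_model,
                        levels = c("null", "genotype", "ancestry")))
    cat("ModelLedger:", nrow(object@pairs), "site-SNP pairs,",
        length(unique(object@pairs$site_id)), "sites\n")
    cat("  best model:",
        paste(sprintf("%s %d (%.0f%%)", names(tab), tab,
                      100 * tab / max(1, nrow(object@pairs))),
              collapse = ", "), "\n")
})
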