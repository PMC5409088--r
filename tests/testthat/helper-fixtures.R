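# small hand-built objects shared across test files

makeAncestry <- function(hap1, hap2, pos, chrom = "chr1",
                         samples = sprintf("s%d", seq_len(ncol(hap1)))) {
    snps <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    names(snps) <- sprintf("snp%d", seq_along(pos))
    colnames(hap1) <- colnames(hap2) <- samples
    LocalAncestry(hap1, hap2, snps)
}

makeSites <- function(pos, chrom = "chr1",
                      ids = sprintf("cg%d", seq_along(pos))) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
    names(gr) <- ids
    gr
}

# covariate table with no structure, for fits that only need an intercept
# plus something to adjust for
plainCovars <- function(n, samples = sprintf("s%d", seq_len(n)), seed = 1) {
    set.seed(seed)
    data.frame(age = sample(30:70, n, replace = TRUE),
               sex = sample(c("F", "M"), n, replace = TRUE),
               row.names = samples)
}

# independent step-up BH oracle by direct enumeration
bhOracle <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= alpha * seq_len(m) / m)
    reject <- rep(FALSE, m)
    if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
    reject
}

colonCovars <- c("age", "sex", "city", "colon_location")
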