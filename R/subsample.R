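## Two-population subsampling power analysis: how the number of sites with
## a significant population effect grows with per-population sample size,
## in a simple gender + population regression on the M-scale.

#' Two-population site scan
#'
#' Per site, OLS of M-values on gender plus a population indicator; the
#' population effect is tested with a 1-df LRT (equivalently the partial F
#' / coefficient test) and BH-adjusted across sites.
#'
#' @param M numeric matrix (sites x samples) of M-values, or a
#'   \linkS4class{MethylationSet}
#' @param population factor with exactly two levels, one per sample
#' @param gender factor, one per sample
#' @param fdrAlpha FDR level (default 0.01)
#' @param pMethod \code{"exact"} or \code{"chisq"} (see
#'   \code{\link{scanPopDNAm}})
#' @return list with \code{nSignificant}, \code{nTested}, \code{p},
#'   \code{q}
#' @export
twoGroupScan <- function(M, population, gender, fdrAlpha = 0.01,
                         pMethod = c("exact", "chisq")) {
    pMethod <- match.arg(pMethod)
    if (is(M, "MethylationSet")) M <- assay(M, "M")
    population <- droplevels(factor(population))
    if (nlevels(population) != 2L)
        stop("exactly two population labels required, got ",
             nlevels(population))
    gender <- droplevels(factor(gender))
    n <- ncol(M)
    stopifnot(length(population) == n, length(gender) == n)
    X1 <- stats::model.matrix(~ gender + population)
    X0 <- stats::model.matrix(~ gender)
    rank1 <- qr(X1)$rank
    Y <- t(M)
    rss1 <- colSums(qr.resid(qr(X1), Y)^2)
    rss0 <- colSums(qr.resid(qr(X0), Y)^2)
    p <- if (pMethod == "chisq") {
        pchisq(pmax(0, n * log(rss0 / rss1)), df = 1, lower.tail = FALSE)
    } else {
        f <- pmax(0, rss0 - rss1) / (rss1 / (n - rank1))
        pf(f, 1, n - rank1, lower.tail = FALSE)
    }
    adj <- bhFdr(p, fdrAlpha)
    list(nSignificant = sum(adj$reject), nTested = nrow(M),
         p = setNames(p, rownames(M)), q = setNames(adj$q, rownames(M)))
}

#' Subsampling power curve
#'
#' For each per-population size, draws \code{nReps} balanced random
#' subsets without replacement, runs \code{\link{twoGroupScan}} on each
#' and records the number of significant sites. All draws come from one
#' seeded stream and are logged for auditability.
#'
#' @inheritParams twoGroupScan
#' @param sizes per-population subset sizes (default 10, 20, 30, 40, 50)
#' @param nReps repetitions per size (default 10)
#' @param seed integer seed
#' @return list with \code{curve} (data.frame: size, mean_count, sd_count),
#'   \code{counts} (nReps x sizes matrix), \code{drawLog} (sample indices
#'   per draw), \code{seed}
#' @export
subsamplePower <- function(M, population, gender,
                           sizes = c(10L, 20L, 30L, 40L, 50L),
                           nReps = 10L, fdrAlpha = 0.01, seed = 1L,
                           pMethod = c("exact", "chisq")) {
    pMethod <- match.arg(pMethod)
    if (is(M, "MethylationSet")) M <- assay(M, "M")
    population <- droplevels(factor(population))
    if (nlevels(population) != 2L)
        stop("exactly two population labels required")
    avail <- table(population)
    if (max(sizes) > min(avail))
        stop("size ", max(sizes), " exceeds available samples in population '",
             names(avail)[which.min(avail)], "' (", min(avail), ")")
    set.seed(seed)
    counts <- matrix(NA_real_, nReps, length(sizes),
                     dimnames = list(NULL, as.character(sizes)))
    drawLog <- list()
    for (j in seq_along(sizes)) {
        s <- sizes[j]
        for (r in seq_len(nReps)) {
            idx <- unlist(lapply(levels(population), function(l)
                sample(which(population == l), s)))
            counts[r, j] <- twoGroupScan(M[, idx, drop = FALSE],
                                         population[idx], gender[idx],
                                         fdrAlpha, pMethod)$nSignificant
            drawLog[[paste0("size", s, "_rep", r)]] <- idx
        }
    }
    list(curve = data.frame(size = sizes,
                            mean_count = colMeans(counts),
                            sd_count = apply(counts, 2, sd)),
         counts = counts, drawLog = drawLog, seed = seed)
}
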