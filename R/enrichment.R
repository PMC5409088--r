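## Permutation enrichment of significant sites in genomic-context
## categories and near GWAS-catalog SNPs. The null model draws
## size-matched subsets of the tested sites uniformly without replacement;
## empirical p-values carry an add-one correction, so the smallest
## reportable p is 1/(nDraws + 1).

#' Assign manifest sites to genomic-context categories
#'
#' Gene context is multi-label: a site belongs to a category if it is in
#' that relation with at least one gene; sites with no gene relations form
#' the Intergenic category. CpG-island context is single-label over
#' Island / N_Shore / S_Shore / N_Shelf / S_Shelf / Sea (the island, its
#' 2kb flanks, the next 2kb, and everything else).
#'
#' @param manifest a manifest \code{GRanges} (see \code{\link{readManifest}})
#' @return list with \code{gene} (a \code{CharacterList} per site,
#'   including \code{"Intergenic"}), \code{island} (character per site)
#'   and \code{categories} (all category labels in display order)
#' @export
assignCategories <- function(manifest) {
    isl <- mcols(manifest)$island_relation
    bad <- setdiff(unique(isl), .ISLAND_LEVELS)
    if (length(bad)) stop("unknown island label: ", bad[1])
    gene <- mcols(manifest)$gene_relations
    gene <- CharacterList(lapply(gene, function(g)
        if (length(g)) g else "Intergenic"))
    list(gene = gene, island = isl,
         categories = c(.GENE_LEVELS, "Intergenic", .ISLAND_LEVELS))
}

# numeric membership matrix (sites x categories) for fast subset tallies
.categoryMembership <- function(manifest) {
    cats <- assignCategories(manifest)
    memb <- matrix(0, length(manifest), length(cats$categories),
                   dimnames = list(names(manifest), cats$categories))
    for (cat in c(.GENE_LEVELS, "Intergenic"))
        memb[, cat] <- as.numeric(any(cats$gene == cat))
    for (cat in .ISLAND_LEVELS)
        memb[, cat] <- as.numeric(cats$island == cat)
    memb
}

#' Permutation enrichment of significant sites by genomic context
#'
#' Per category, compares the fraction of significant sites in the
#' category against the fraction of all tested sites in it. Significance
#' comes from \code{nDraws} uniform same-size subsets of the tested sites:
#' the two-sided empirical p-value is the add-one-corrected fraction of
#' draws whose category fraction deviates from the expectation at least
#' as much as observed. Per-category p-values are not multiplicity
#' adjusted.
#'
#' @param sigSites character vector of significant site ids (must be a
#'   subset of \code{testedSites})
#' @param testedSites character vector of all tested site ids
#' @param manifest manifest \code{GRanges} covering the tested sites
#' @param nDraws number of null draws (default 10000)
#' @param seed integer seed
#' @return \code{DataFrame} with one row per category: observed and
#'   expected fractions, the empirical 95\% null interval, the two-sided
#'   empirical p, the direction, \code{n_draws} and \code{seed}
#' @export
permutationEnrichment <- function(sigSites, testedSites, manifest,
                                  nDraws = 10000L, seed = 1L) {
    if (!length(sigSites)) stop("at least one significant site required")
    if (!all(sigSites %in% testedSites))
        stop("sigSites must be a subset of testedSites")
    if (!all(testedSites %in% names(manifest)))
        stop("testedSites missing from the manifest")
    memb <- .categoryMembership(manifest[testedSites])
    m <- length(sigSites)
    nT <- length(testedSites)
    obs <- colMeans(memb[match(sigSites, testedSites), , drop = FALSE])
    expected <- colMeans(memb)
    set.seed(seed)
    nullFrac <- matrix(0, nDraws, ncol(memb))
    for (d in seq_len(nDraws)) {
        idx <- sample.int(nT, m)  # without replacement, size-matched
        stopifnot(length(idx) == m)
        nullFrac[d, ] <- colSums(memb[idx, , drop = FALSE]) / m
    }
    dev <- abs(sweep(nullFrac, 2, expected))
    obsDev <- abs(obs - expected)
    p <- (1 + colSums(dev >= rep(obsDev - 1e-12, each = nDraws))) /
        (nDraws + 1)
    ci <- apply(nullFrac, 2, quantile, probs = c(0.025, 0.975))
    DataFrame(category = colnames(memb),
              observed_fraction = unname(obs),
              expected_fraction = unname(expected),
              null_lo = unname(ci[1, ]), null_hi = unname(ci[2, ]),
              empirical_p = unname(p),
              direction = unname(ifelse(obs >= expected, "enriched",
                                        "depleted")),
              n_draws = nDraws, seed = seed)
}

#' GWAS-catalog proximity enrichment
#'
#' Statistic: the number of significant sites with at least one catalog
#' SNP within \code{distance} bp (closed interval, same chromosome; a
#' 50kb cutoff spans a 100kb window centred on the site). The one-sided
#' empirical p-value is the add-one-corrected fraction of size-matched
#' uniform draws from the tested sites with at least as many proximal
#' sites.
#'
#' @inheritParams permutationEnrichment
#' @param catalog \code{GRanges} of catalog SNP positions
#' @param distance proximity cutoff in bp (default 50kb)
#' @return list with \code{observed}, \code{observedFraction},
#'   \code{expectedFraction}, \code{nullInterval95}, \code{p},
#'   \code{nDraws}, \code{seed}, \code{distance}
#' @export
gwasProximityEnrichment <- function(sigSites, testedSites, manifest,
                                    catalog, distance = 50000L,
                                    nDraws = 10000L, seed = 1L) {
    if (!length(sigSites)) stop("at least one significant site required")
    if (!all(sigSites %in% testedSites))
        stop("sigSites must be a subset of testedSites")
    sites <- manifest[testedSites]
    if (!length(catalog)) {
        return(list(observed = 0L, observedFraction = 0,
                    expectedFraction = 0,
                    nullInterval95 = c(0, 0), p = 1,
                    nDraws = nDraws, seed = seed, distance = distance))
    }
    win <- GRanges(seqnames(sites),
                   IRanges(pmax(1L, start(sites) - distance),
                           start(sites) + distance))
    hasProx <- GenomicRanges::countOverlaps(win, catalog) > 0
    names(hasProx) <- testedSites
    m <- length(sigSites)
    obs <- sum(hasProx[sigSites])
    set.seed(seed)
    nullCount <- integer(nDraws)
    for (d in seq_len(nDraws)) {
        idx <- sample.int(length(testedSites), m)
        stopifnot(length(idx) == m)
        nullCount[d] <- sum(hasProx[idx])
    }
    list(observed = as.integer(obs), observedFraction = obs / m,
         expectedFraction = mean(hasProx),
         nullInterval95 = unname(quantile(nullCount / m, c(0.025, 0.975))),
         p = (1 + sum(nullCount >= obs)) / (nDraws + 1),
         nDraws = nDraws, seed = seed, distance = distance)
}
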