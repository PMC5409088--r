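## Cross-tissue comparison of scan results: relaxed-threshold replication
## and effect-size concordance on three site subsets. All comparisons are
## restricted to sites tested in both tissues; exclusions are counted.

#' Relaxed-threshold replication fraction
#'
#' Of the sites significant in the discovery tissue at a stringent FDR,
#' the fraction that is significant in the other tissue at a relaxed FDR
#' (q-values recomputed on the other tissue's full tested set). Discovery
#' sites untested in the other tissue are excluded from the denominator
#' and counted.
#'
#' @param discovery,other \linkS4class{ScanResult}s for the two tissues
#' @param fdrDiscovery stringent FDR in the discovery tissue (default 1\%)
#' @param fdrReplication relaxed FDR in the other tissue (default 50\%)
#' @return list with \code{fraction} (\code{NA} if no discovery sites),
#'   \code{nDiscovery}, \code{nDiscoveryTestedOther}, \code{nReplicated},
#'   \code{nUntestedOther}
#' @export
replicationFraction <- function(discovery, other, fdrDiscovery = 0.01,
                                fdrReplication = 0.5) {
    td <- scanTable(discovery)
    to <- scanTable(other)
    disc <- td$site_id[td$q <= fdrDiscovery]
    discTested <- intersect(disc, to$site_id)
    repl <- intersect(discTested,
                      to$site_id[to$q <= fdrReplication])
    list(fraction = if (length(discTested)) length(repl) / length(discTested)
                    else NA_real_,
         nDiscovery = length(disc),
         nDiscoveryTestedOther = length(discTested),
         nReplicated = length(repl),
         nUntestedOther = length(disc) - length(discTested))
}

#' Cross-tissue correlation of ancestry effects
#'
#' Correlation between the per-site NAM (and AFR) effect estimates of two
#' scans over a chosen site subset: all sites tested in both tissues,
#' sites significant in at least one, or sites significant in both.
#' Subsets smaller than \code{minSites} return \code{NA} coefficients with
#' the subset size.
#'
#' @param a,b \linkS4class{ScanResult}s
#' @param subset \code{"all"}, \code{"either_sig"} or \code{"both_sig"}
#' @param method \code{"pearson"} (default) or \code{"spearman"}
#' @param minSites minimum subset size for a coefficient
#' @return list with \code{rhoNam}, \code{rhoAfr}, \code{nSites},
#'   \code{subset}, \code{method}
#' @export
effectCorrelation <- function(a, b,
                              subset = c("all", "either_sig", "both_sig"),
                              method = c("pearson", "spearman"),
                              minSites = 3L) {
    subset <- match.arg(subset)
    method <- match.arg(method)
    ta <- scanTable(a); tb <- scanTable(b)
    shared <- intersect(ta$site_id, tb$site_id)
    ia <- match(shared, ta$site_id); ib <- match(shared, tb$site_id)
    keep <- switch(subset,
        all = rep(TRUE, length(shared)),
        either_sig = ta$significant[ia] | tb$significant[ib],
        both_sig = ta$significant[ia] & tb$significant[ib])
    n <- sum(keep)
    if (n < minSites)
        return(list(rhoNam = NA_real_, rhoAfr = NA_real_, nSites = n,
                    subset = subset, method = method))
    list(rhoNam = cor(ta$b_nam[ia][keep], tb$b_nam[ib][keep],
                      method = method),
         rhoAfr = cor(ta$b_afr[ia][keep], tb$b_afr[ib][keep],
                      method = method),
         nSites = n, subset = subset, method = method)
}

#' Full cross-tissue comparison
#'
#' Replication fractions in both directions, effect correlations on the
#' three site subsets, and the count of sites significant in both tissues.
#' The correlation type is a reporting choice surfaced in the output
#' metadata, not a modelling assumption.
#'
#' @inheritParams replicationFraction
#' @inheritParams effectCorrelation
#' @return list with \code{replicationAtoB}, \code{replicationBtoA},
#'   \code{correlations} (per subset), \code{overlapCount},
#'   \code{method}
#' @export
crossTissue <- function(a, b, fdrDiscovery = 0.01, fdrReplication = 0.5,
                        method = c("pearson", "spearman")) {
    method <- match.arg(method)
    subsets <- c("all", "either_sig", "both_sig")
    corrs <- lapply(subsets, function(s)
        effectCorrelation(a, b, subset = s, method = method))
    names(corrs) <- subsets
    list(replicationAtoB = replicationFraction(a, b, fdrDiscovery,
                                               fdrReplication),
         replicationBtoA = replicationFraction(b, a, fdrDiscovery,
                                               fdrReplication),
         correlations = corrs,
         overlapCount = corrs$both_sig$nSites,
         method = method,
         fdrDiscovery = fdrDiscovery, fdrReplication = fdrReplication)
}

#' Per-site paired effects across two tissues
#'
#' The data behind a cross-tissue effect scatter: one row per site tested
#' in both tissues with both tissues' effect estimates and significance
#' flags.
#'
#' @param a,b \linkS4class{ScanResult}s
#' @return \code{DataFrame} with effects and significance per tissue
#' @export
pairedEffects <- function(a, b) {
    ta <- scanTable(a); tb <- scanTable(b)
    shared <- intersect(ta$site_id, tb$site_id)
    ia <- match(shared, ta$site_id); ib <- match(shared, tb$site_id)
    DataFrame(site_id = shared,
              b_nam_a = ta$b_nam[ia], b_afr_a = ta$b_afr[ia],
              significant_a = ta$significant[ia],
              b_nam_b = tb$b_nam[ib], b_afr_b = tb$b_afr[ib],
              significant_b = tb$significant[ib])
}
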