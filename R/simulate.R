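## Synthetic admixed cohorts with known causal structure. The generator is
## deliberately simple and fully checkable: Balding-Nichols ancestral
## allele frequencies, Poisson-switch ancestry tracts with i.i.d. segment
## ancestries (a pulse-admixture approximation) on a uniform recombination
## map, genotypes drawn conditional on local ancestry, and M-scale
## methylomes whose cis signal is driven by local ancestry or by single
## variants. Every stage is seeded and deterministic.

#' Parameters of the synthetic admixed cohort
#'
#' Defaults emulate the scale and structure of a three-way admixed Latin
#' American cohort: 132 individuals, a single synthetic chromosome,
#' genome-wide ancestry around 55\% European / 35\% Native American /
#' 10\% African, admixture about 8 generations old, and moderate
#' Balding-Nichols differentiation of the three ancestral populations.
#' Site, SNP and sample counts are configurable throughout; multi-chromosome
#' cohorts are built by repetition with independent seeds.
#'
#' @param nIndividuals cohort size
#' @param nSnps ancestry-informative SNPs on the chromosome
#' @param nSites CpG sites on the chromosome
#' @param chromLengthBp physical chromosome length (bp)
#' @param chromLengthMorgans genetic length (Morgans); the recombination
#'   map is uniform
#' @param generations admixture age g: ancestry switch points per haplotype
#'   form a Poisson process of rate g per Morgan
#' @param globalAlpha probability triple (EUR, NAM, AFR) of segment
#'   ancestries; must sum to 1
#' @param fst per-population Balding-Nichols differentiation F, each in
#'   (0, 1)
#' @param causalFraction fraction of sites given a true cis effect
#' @param effectScale magnitude of true effects in units of
#'   \code{noiseSd} (signs are drawn at random)
#' @param noiseSd residual SD of M-values
#' @param causalMechanism \code{"ancestry_cis"} (M depends on windowed
#'   ancestry proportions), \code{"common_variant"} (on the dosage of a
#'   panel SNP segregating in all three populations),
#'   \code{"popspecific_variant"} (on the dosage of a variant private to
#'   one population, simulated from the true tracts but \emph{not} placed
#'   in the genotype panel) or \code{"null"}
#' @param contextEnrichment named multipliers over manifest categories
#'   (island and/or gene-context labels) biasing where causal sites are
#'   placed; \code{NULL} for uniform placement
#' @param windowOmega,minSnps window used to compute the true ancestry
#'   proportions that drive \code{ancestry_cis} effects
#' @param islandFreqs marginal frequencies of the CpG-island categories in
#'   the simulated manifest
#' @param popspecificFreq allele frequency of the private variant in its
#'   carrier population
#' @param popspecificCarrier carrier population of the private variant
#' @param mislabelRate optional symmetric ancestry-call error rate
#'   (default 0: tracts are returned as truth)
#' @param chrom chromosome name
#' @return a validated parameter list of class \code{simParams}
#' @export
simParams <- function(nIndividuals = 132L, nSnps = 2000L, nSites = 500L,
                      chromLengthBp = 1e8, chromLengthMorgans = 1,
                      generations = 8,
                      globalAlpha = c(EUR = 0.55, NAM = 0.35, AFR = 0.10),
                      fst = c(EUR = 0.15, NAM = 0.25, AFR = 0.15),
                      causalFraction = 0.05, effectScale = 2, noiseSd = 1,
                      causalMechanism = c("ancestry_cis", "common_variant",
                                          "popspecific_variant", "null"),
                      contextEnrichment = NULL,
                      windowOmega = 500000L, minSnps = 1L,
                      islandFreqs = c(Island = 0.31, N_Shore = 0.12,
                                      S_Shore = 0.10, N_Shelf = 0.05,
                                      S_Shelf = 0.04, Sea = 0.38),
                      popspecificFreq = 0.5, popspecificCarrier = "NAM",
                      mislabelRate = 0, chrom = "chr1") {
    causalMechanism <- match.arg(causalMechanism)
    stopifnot(nIndividuals >= 2, nSnps >= 1, nSites >= 1,
              chromLengthBp > 0, chromLengthMorgans > 0, generations >= 0,
              length(globalAlpha) == 3, abs(sum(globalAlpha) - 1) < 1e-8,
              all(globalAlpha >= 0),
              causalFraction >= 0, causalFraction <= 1,
              noiseSd >= 0, popspecificFreq > 0, popspecificFreq <= 1,
              popspecificCarrier %in% .ANCESTRIES,
              mislabelRate >= 0, mislabelRate < 1)
    if (any(fst <= 0 | fst >= 1))
        stop("each fst must lie in (0, 1)")
    names(globalAlpha) <- .ANCESTRIES
    names(fst) <- .ANCESTRIES
    p <- list(nIndividuals = as.integer(nIndividuals),
              nSnps = as.integer(nSnps), nSites = as.integer(nSites),
              chromLengthBp = chromLengthBp,
              chromLengthMorgans = chromLengthMorgans,
              generations = generations, globalAlpha = globalAlpha,
              fst = fst, causalFraction = causalFraction,
              effectScale = effectScale, noiseSd = noiseSd,
              causalMechanism = causalMechanism,
              contextEnrichment = contextEnrichment,
              windowOmega = as.integer(windowOmega),
              minSnps = as.integer(minSnps),
              islandFreqs = islandFreqs / sum(islandFreqs),
              popspecificFreq = popspecificFreq,
              popspecificCarrier = popspecificCarrier,
              mislabelRate = mislabelRate, chrom = chrom)
    class(p) <- "simParams"
    p
}

# independent per-stage seeds derived from one master seed
.childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) + 1000003 * k) %% 2147483647)
}

#' Simulated SNP map
#'
#' Uniformly placed, distinct, sorted SNP positions on the synthetic
#' chromosome; genetic positions follow the uniform map.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed
#' @return \code{GRanges} named by SNP id with metadata column
#'   \code{genetic_pos} (Morgans)
#' @export
simulateSnpMap <- function(params, seed = 1L) {
    set.seed(seed)
    pos <- sort(sample.int(params$chromLengthBp, params$nSnps))
    gr <- GRanges(params$chrom, IRanges(pos, width = 1))
    names(gr) <- sprintf("snp%06d", seq_len(params$nSnps))
    mcols(gr)$genetic_pos <-
        pos / params$chromLengthBp * params$chromLengthMorgans
    gr
}

#' Balding-Nichols population allele frequencies
#'
#' For each SNP an ancestral frequency p ~ Uniform(0.05, 0.95) is drawn,
#' then each population's frequency independently from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so that across SNPs
#' E[freq] = p and Var[freq] = F p (1 - p).
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed
#' @return numeric matrix (nSnps x 3, columns EUR/NAM/AFR) of
#'   reference-allele frequencies in (0, 1), with the ancestral frequencies
#'   as attribute \code{"ancestral"}
#' @export
simulateFrequencies <- function(params, seed = 1L) {
    set.seed(seed)
    n <- params$nSnps
    p <- runif(n, 0.05, 0.95)
    freq <- vapply(.ANCESTRIES, function(pop) {
        F <- params$fst[[pop]]
        pmin(pmax(rbeta(n, p * (1 - F) / F, (1 - p) * (1 - F) / F),
                  1e-6), 1 - 1e-6)
    }, numeric(n))
    attr(freq, "ancestral") <- p
    freq
}

# one haplotype: exponential gaps of rate g along the genetic map until the
# chromosome end is crossed; the crossing gap is kept in the gap record so
# the pooled gap distribution is exactly Exponential(g) (Wald's identity)
.haplotypeTracts <- function(g, Lm, alpha) {
    if (g <= 0)
        return(list(switches = numeric(0), gaps = numeric(0),
                    ancestries = sample.int(3L, 1L, prob = alpha)))
    gaps <- numeric(0)
    s <- 0
    repeat {
        gap <- rexp(1, rate = g)
        gaps <- c(gaps, gap)
        s <- s + gap
        if (s > Lm) break
    }
    switches <- cumsum(gaps)
    switches <- switches[switches < Lm]
    list(switches = switches, gaps = gaps,
         ancestries = sample.int(3L, length(switches) + 1L, replace = TRUE,
                                 prob = alpha))
}

#' Simulated mosaic local-ancestry tracts
#'
#' Per haplotype, ancestry switch points form a Poisson process of rate
#' \code{generations} per Morgan along the (uniform) genetic map; segment
#' ancestries are i.i.d. draws from \code{globalAlpha}. Calls are emitted
#' at every SNP of the map. With \code{generations = 0} each haplotype is
#' single-ancestry. An optional symmetric mislabeling rate flips each
#' emitted call to one of the other two codes.
#'
#' @param params a \code{\link{simParams}} list
#' @param snps SNP map from \code{\link{simulateSnpMap}}; generated
#'   internally (seed-derived) when \code{NULL}
#' @param seed integer seed
#' @param keepSegments keep the per-haplotype switch points, gap draws and
#'   segment ancestries in \code{metadata()$segments} (used by diagnostic
#'   checks)
#' @return a \linkS4class{LocalAncestry} of true (or mislabeled) calls
#' @export
simulateTracts <- function(params, snps = NULL, seed = 1L,
                           keepSegments = FALSE) {
    if (is.null(snps)) snps <- simulateSnpMap(params, .childSeed(seed, 101))
    set.seed(seed)
    g <- params$generations
    Lm <- params$chromLengthMorgans
    gpos <- mcols(snps)$genetic_pos
    if (is.null(gpos))
        gpos <- start(snps) / params$chromLengthBp * Lm
    nInd <- params$nIndividuals
    hap1 <- matrix(NA_integer_, length(snps), nInd)
    hap2 <- hap1
    segs <- if (keepSegments) vector("list", 2L * nInd) else NULL
    for (i in seq_len(nInd)) {
        for (h in 1:2) {
            t <- .haplotypeTracts(g, Lm, params$globalAlpha)
            calls <- t$ancestries[findInterval(gpos, t$switches) + 1L]
            if (h == 1L) hap1[, i] <- calls else hap2[, i] <- calls
            if (keepSegments) segs[[2L * (i - 1L) + h]] <- t
        }
    }
    if (params$mislabelRate > 0) {
        flip <- function(m) {
            doFlip <- matrix(runif(length(m)) < params$mislabelRate, nrow(m))
            shift <- matrix(sample.int(2L, length(m), replace = TRUE), nrow(m))
            m[doFlip] <- (m[doFlip] - 1L + shift[doFlip]) %% 3L + 1L
            m
        }
        hap1 <- flip(hap1); hap2 <- flip(hap2)
    }
    colnames(hap1) <- colnames(hap2) <- sprintf("ind%04d", seq_len(nInd))
    la <- LocalAncestry(hap1, hap2, snps)
    if (keepSegments) metadata(la)$segments <- segs
    la
}

#' Genotypes conditional on local ancestry
#'
#' Each haplotype's allele at each SNP is Bernoulli with the
#' reference-allele frequency of that haplotype's local ancestral
#' population at the SNP.
#'
#' @param tracts a \linkS4class{LocalAncestry}
#' @param freqs frequency matrix from \code{\link{simulateFrequencies}}
#'   (rows aligned with the SNPs of \code{tracts})
#' @param seed integer seed
#' @return a phased \linkS4class{PhasedGenotypes}
#' @export
simulateGenotypes <- function(tracts, freqs, seed = 1L) {
    stopifnot(is(tracts, "LocalAncestry"))
    if (nrow(freqs) != nrow(tracts))
        stop("SNP mismatch: ", nrow(freqs), " frequency rows vs ",
             nrow(tracts), " SNPs in tracts")
    set.seed(seed)
    draw <- function(H) {
        p <- freqs[cbind(rep(seq_len(nrow(H)), ncol(H)), as.vector(H))]
        matrix(rbinom(length(H), 1L, p), nrow(H),
               dimnames = dimnames(H))
    }
    h1 <- draw(assay(tracts, "hap1"))
    h2 <- draw(assay(tracts, "hap2"))
    PhasedGenotypes(h1 + h2, rowRanges(tracts), hap1 = h1, hap2 = h2)
}

#' Simulated sample covariates
#'
#' Age (years), sex, recruitment city, colon biopsy location and blood
#' cell-type proportions (CD4T, CD8T, NK, Mono, Gran, B; a normalized
#' gamma draw around typical whole-blood composition). No missing values.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed
#' @return data.frame keyed by sample id
#' @export
simulateCovariates <- function(params, seed = 1L) {
    set.seed(seed)
    n <- params$nIndividuals
    cellShape <- c(CD4T = 15, CD8T = 8, NK = 4, Mono = 7, Gran = 60, B = 5)
    cells <- vapply(cellShape, function(s) rgamma(n, shape = s), numeric(n))
    cells <- cells / rowSums(cells)
    d <- data.frame(
        age = sample(30:79, n, replace = TRUE),
        sex = sample(c("F", "M"), n, replace = TRUE),
        city = sample(paste0("city", 1:3), n, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)),
        colon_location = sample(c("left", "right", "nonspecific"), n,
                                replace = TRUE, prob = c(0.45, 0.45, 0.10)),
        cells, row.names = sprintf("ind%04d", seq_len(n)))
    stopifnot(!anyNA(d))
    d
}

#' Simulated CpG-site manifest
#'
#' Uniformly placed CpG sites with gene-context relations (multi-label,
#' empty for intergenic sites) and a single CpG-island relation drawn from
#' the configured marginal frequencies, loosely following 450K array
#' proportions.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed
#' @return a manifest \code{GRanges} (see \code{\link{readManifest}})
#' @export
simulateManifest <- function(params, seed = 1L) {
    set.seed(seed)
    n <- params$nSites
    pos <- sort(sample.int(params$chromLengthBp, n))
    gr <- GRanges(params$chrom, IRanges(pos, width = 1))
    names(gr) <- sprintf("cg%06d", seq_len(n))
    geneW <- c(TSS1500 = 0.20, TSS200 = 0.12, "5'UTR" = 0.12,
               "1stExon" = 0.08, Body = 0.43, "3'UTR" = 0.05)
    rel <- lapply(seq_len(n), function(i) {
        if (runif(1) < 0.25) return(character(0))  # intergenic
        k <- sample(1:2, 1, prob = c(0.85, 0.15))  # relations to 1-2 genes
        unique(sample(names(geneW), k, replace = TRUE, prob = geneW))
    })
    mcols(gr)$gene_relations <- CharacterList(rel)
    mcols(gr)$island_relation <- sample(names(params$islandFreqs), n,
                                        replace = TRUE,
                                        prob = params$islandFreqs)
    gr
}

# causal placement weight per site from named category multipliers
.contextWeights <- function(manifest, contextEnrichment) {
    w <- rep(1, length(manifest))
    if (is.null(contextEnrichment)) return(w)
    isl <- mcols(manifest)$island_relation
    hit <- match(isl, names(contextEnrichment))
    w <- ifelse(is.na(hit), w, w * contextEnrichment[hit])
    gene <- mcols(manifest)$gene_relations
    for (cat in intersect(names(contextEnrichment), .GENE_LEVELS)) {
        has <- any(gene == cat)
        w[as.logical(has)] <- w[as.logical(has)] * contextEnrichment[[cat]]
    }
    w
}

#' Simulated methylome with known causal structure
#'
#' Builds M-values as baseline + covariate effects + cis signal + Gaussian
#' noise. The cis signal follows \code{params$causalMechanism}:
#' \describe{
#'   \item{ancestry_cis}{\code{M = b0 + b_NAM pi_NAM + b_AFR pi_AFR + ...},
#'     with the proportions computed from the true tracts in the configured
#'     window.}
#'   \item{common_variant}{\code{M = b0 + b dosage + ...} for an in-window
#'     panel SNP segregating in all three populations.}
#'   \item{popspecific_variant}{as above, but the causal variant is private
#'     to one population and is simulated from the true tracts at the site
#'     \emph{without} entering the genotype panel; the nearest panel SNP is
#'     recorded as its tag.}
#'   \item{null}{covariates + noise only.}
#' }
#' Causal sites are drawn among tested sites with weights from
#' \code{params$contextEnrichment}; effect magnitudes are
#' \code{effectScale * noiseSd} with random signs. Passing the
#' \code{truth} of a previous call simulates a second tissue: causal sites
#' and (a configurable fraction of) effects are reused, baselines and
#' noise are redrawn.
#'
#' @param tracts a \linkS4class{LocalAncestry} of true tracts
#' @param genotypes a \linkS4class{PhasedGenotypes} (panel genotypes)
#' @param covars covariate data.frame from \code{\link{simulateCovariates}}
#' @param manifest manifest \code{GRanges}
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed
#' @param truth truth list of a previous call, to share causal structure
#'   across tissues
#' @param sharedFraction fraction of causal effects kept identical when
#'   \code{truth} is supplied (default 1)
#' @param tissue tissue label for the output
#' @return list with \code{meth} (a \linkS4class{MethylationSet}) and
#'   \code{truth} (causal sites, effects, causal/tag SNPs, mechanism)
#' @export
simulateMethylation <- function(tracts, genotypes, covars, manifest, params,
                                seed = 1L, truth = NULL, sharedFraction = 1,
                                tissue = "tissue1") {
    stopifnot(is(tracts, "LocalAncestry"), is(genotypes, "PhasedGenotypes"))
    set.seed(seed)
    samples <- colnames(tracts)
    stopifnot(identical(samples, rownames(covars)),
              identical(samples, colnames(genotypes)))
    n <- length(samples)
    nSites <- length(manifest)
    wa <- windowedProportions(tracts, manifest, omega = params$windowOmega,
                              minSnps = params$minSnps)
    piN <- ancestryProportion(wa, "NAM")
    piA <- ancestryProportion(wa, "AFR")

    # fixed covariate effect surface, identical across sites and tissues
    cityEff <- c(city1 = 0, city2 = 0.15, city3 = -0.1)
    locEff <- c(left = 0, right = 0.15, nonspecific = 0.05)
    covSignal <- 0.01 * (covars$age - 50) +
        0.2 * (covars$sex == "M") +
        cityEff[covars$city] + locEff[covars$colon_location]

    mech <- params$causalMechanism
    if (is.null(truth)) {
        mCausal <- round(params$causalFraction * nSites)
        if (mech == "null") mCausal <- 0L
        if (params$causalFraction > 0 && mCausal < 1 && mech != "null") {
            warning("causalFraction * nSites < 1: zero causal sites")
            mCausal <- 0L
        }
        eligible <- which(wa@tested)
        w <- .contextWeights(manifest, params$contextEnrichment)[eligible]
        causal <- if (mCausal > 0)
            sort(eligible[sample.int(length(eligible),
                                     min(mCausal, length(eligible)),
                                     prob = w)])
        else integer(0)
        # effects in residual-SD units; unit scale for noiseless simulations
        b <- params$effectScale * (if (params$noiseSd > 0) params$noiseSd else 1)
        effects <- DataFrame(
            site_id = names(manifest)[causal],
            b_nam = b * sample(c(-1, 1), length(causal), replace = TRUE),
            b_afr = b * sample(c(-1, 1), length(causal), replace = TRUE),
            b_snp = b * sample(c(-1, 1), length(causal), replace = TRUE))
        causalSnps <- character(0)
    } else {
        stopifnot(identical(truth$mechanism, mech))
        causal <- match(truth$causalSites, names(manifest))
        effects <- truth$effects
        if (sharedFraction < 1 && nrow(effects)) {
            redraw <- runif(nrow(effects)) >= sharedFraction
            b <- params$effectScale *
                (if (params$noiseSd > 0) params$noiseSd else 1)
            effects$b_nam[redraw] <- b * sample(c(-1, 1), sum(redraw), TRUE)
            effects$b_afr[redraw] <- b * sample(c(-1, 1), sum(redraw), TRUE)
            effects$b_snp[redraw] <- b * sample(c(-1, 1), sum(redraw), TRUE)
        }
        causalSnps <- truth$causalSnps
    }

    M <- matrix(rnorm(nSites * n, sd = params$noiseSd), nSites, n,
                dimnames = list(names(manifest), samples))
    M <- M + rep(rnorm(nSites, sd = 1.5), n) +   # per-site baseline
        rep(covSignal, each = nSites)

    if (length(causal)) {
        snpPos <- start(rowRanges(genotypes))
        dosage <- assay(genotypes, "dosage")
        freqs <- metadata(genotypes)$freqs
        newTags <- is.null(truth)
        if (newTags) causalSnps <- setNames(character(length(causal)),
                                            names(manifest)[causal])
        for (k in seq_along(causal)) {
            i <- causal[k]
            if (mech == "ancestry_cis") {
                M[i, ] <- M[i, ] + effects$b_nam[k] * piN[i, ] +
                    effects$b_afr[k] * piA[i, ]
            } else if (mech == "common_variant") {
                if (newTags) {
                    win <- which(abs(snpPos - start(manifest)[i]) <=
                                 params$windowOmega %/% 2)
                    cand <- win
                    if (!is.null(freqs)) {
                        common <- win[rowSums(freqs[win, , drop = FALSE] > 0.2 &
                                              freqs[win, , drop = FALSE] < 0.8) == 3]
                        if (length(common)) cand <- common
                    }
                    if (!length(cand))
                        cand <- which.min(abs(snpPos - start(manifest)[i]))
                    j <- cand[which.min(abs(snpPos[cand] - start(manifest)[i]))]
                    causalSnps[k] <- rownames(genotypes)[j]
                } else j <- match(causalSnps[[names(manifest)[i]]],
                                  rownames(genotypes))
                M[i, ] <- M[i, ] + effects$b_snp[k] * dosage[j, ]
            } else if (mech == "popspecific_variant") {
                # private variant at the site, drawn from the true tracts at
                # the nearest panel SNP's local ancestry; hidden from the panel
                j <- which.min(abs(snpPos - start(manifest)[i]))
                if (newTags) causalSnps[k] <- rownames(genotypes)[j]
                carrier <- match(params$popspecificCarrier, .ANCESTRIES)
                ji <- match(rownames(genotypes)[j], rownames(tracts))
                hid <- rbinom(n, 1, params$popspecificFreq *
                                  (assay(tracts, "hap1")[ji, ] == carrier)) +
                       rbinom(n, 1, params$popspecificFreq *
                                  (assay(tracts, "hap2")[ji, ] == carrier))
                M[i, ] <- M[i, ] + effects$b_snp[k] * hid
            }
        }
    }
    meth <- MethylationSet(M, manifest, tissue = tissue)
    list(meth = meth,
         truth = list(causalSites = names(manifest)[causal],
                      effects = effects, causalSnps = causalSnps,
                      mechanism = mech, tissue = tissue))
}

#' Simulated GWAS-catalog SNP positions
#'
#' Either uniform positions along the chromosome or positions placed
#' within \code{maxDist} of supplied sites (to give proximity enrichment a
#' known positive case).
#'
#' @param params a \code{\link{simParams}} list
#' @param seed integer seed
#' @param n number of catalog SNPs
#' @param nearSites optional \code{GRanges}; when given, catalog SNPs are
#'   placed near these sites
#' @param maxDist placement half-width around \code{nearSites} (bp)
#' @return \code{GRanges} named by catalog SNP id
#' @export
simulateGwasCatalog <- function(params, seed = 1L, n = 200L,
                                nearSites = NULL, maxDist = 25000L) {
    set.seed(seed)
    if (is.null(nearSites)) {
        pos <- sort(sample.int(params$chromLengthBp, n))
    } else {
        anchor <- sample(start(nearSites), n, replace = TRUE)
        pos <- sort(pmax(1L, pmin(params$chromLengthBp,
            anchor + sample(seq(-maxDist, maxDist), n, replace = TRUE))))
    }
    gr <- GRanges(params$chrom, IRanges(pos, width = 1))
    names(gr) <- sprintf("gwas%05d", seq_len(n))
    gr
}

#' Simulate a complete admixed cohort
#'
#' Orchestrates map, frequencies, tracts, genotypes, covariates, manifest,
#' methylome(s) and a GWAS catalog from a single master seed (per-stage
#' child seeds are derived deterministically, so stages are individually
#' reproducible). With \code{tissues = 2} a second methylome is simulated
#' with shared causal structure (see \code{\link{simulateMethylation}}),
#' optionally on a subset of the samples.
#'
#' @param params a \code{\link{simParams}} list
#' @param seed master seed
#' @param tissues 1 or 2
#' @param tissue2Samples number of samples assayed in the second tissue
#'   (default: all)
#' @param sharedFraction fraction of causal effects shared between the two
#'   tissues
#' @return list with \code{snps}, \code{freqs}, \code{ancestry},
#'   \code{genotypes}, \code{covariates}, \code{manifest}, \code{meth}
#'   (and \code{meth2}), \code{truth} (and \code{truth2}), \code{gwas}
#' @export
simulateCohort <- function(params, seed = 1L, tissues = 1L,
                           tissue2Samples = NULL, sharedFraction = 1) {
    stopifnot(tissues %in% 1:2)
    snps <- simulateSnpMap(params, .childSeed(seed, 1))
    freqs <- simulateFrequencies(params, .childSeed(seed, 2))
    ancestry <- simulateTracts(params, snps, .childSeed(seed, 3))
    genotypes <- simulateGenotypes(ancestry, freqs, .childSeed(seed, 4))
    metadata(genotypes)$freqs <- freqs
    covariates <- simulateCovariates(params, .childSeed(seed, 5))
    manifest <- simulateManifest(params, .childSeed(seed, 6))
    t1 <- simulateMethylation(ancestry, genotypes, covariates, manifest,
                              params, .childSeed(seed, 7),
                              tissue = "tissue1")
    out <- list(snps = snps, freqs = freqs, ancestry = ancestry,
                genotypes = genotypes, covariates = covariates,
                manifest = manifest, meth = t1$meth, truth = t1$truth,
                gwas = simulateGwasCatalog(params, .childSeed(seed, 9)))
    if (tissues == 2L) {
        t2 <- simulateMethylation(ancestry, genotypes, covariates, manifest,
                                  params, .childSeed(seed, 8),
                                  truth = t1$truth,
                                  sharedFraction = sharedFraction,
                                  tissue = "tissue2")
        m2 <- t2$meth
        if (!is.null(tissue2Samples))
            m2 <- m2[, seq_len(tissue2Samples)]
        out$meth2 <- m2
        out$truth2 <- t2$truth
    }
    out
}

#' Simulated two-population methylation dataset
#'
#' A simple two-group cohort for the subsampling power analysis: M-values
#' with a mean shift of \code{effect * noiseSd} at a fraction of sites
#' between two pure populations, plus a gender covariate effect and
#' Gaussian noise.
#'
#' @param nPerGroup individuals per population
#' @param nSites CpG sites
#' @param causalFraction fraction of sites with a true population effect
#' @param effect mean shift in units of \code{noiseSd}
#' @param noiseSd residual SD
#' @param seed integer seed
#' @return list with \code{M} (sites x samples matrix), \code{population}
#'   and \code{gender} factors, and \code{causalSites}
#' @export
simulateTwoGroupCohort <- function(nPerGroup = 60L, nSites = 1000L,
                                   causalFraction = 0.05, effect = 2,
                                   noiseSd = 1, seed = 1L) {
    set.seed(seed)
    n <- 2L * nPerGroup
    population <- factor(rep(c("pop1", "pop2"), each = nPerGroup))
    gender <- factor(sample(c("F", "M"), n, replace = TRUE))
    m <- round(causalFraction * nSites)
    causal <- sort(sample.int(nSites, m))
    M <- matrix(rnorm(nSites * n, sd = noiseSd), nSites, n)
    M <- M + rep(rnorm(nSites, sd = 1.5), n) +
        rep(0.2 * (gender == "M"), each = nSites)
    M[causal, population == "pop2"] <- M[causal, population == "pop2"] +
        effect * noiseSd
    rownames(M) <- sprintf("cg%06d", seq_len(nSites))
    colnames(M) <- sprintf("s%04d", seq_len(n))
    list(M = M, population = population, gender = gender,
         causalSites = rownames(M)[causal])
}
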