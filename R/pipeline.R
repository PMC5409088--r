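## End-to-end demo orchestration on a simulated two-tissue cohort. Every
## stage writes plain TSV/JSON artifacts with a provenance header (package
## version and seed); a rerun with the same parameters and seed produces
## byte-identical files.

.artifactHeader <- function(stage, seed)
    sprintf("# ancestryMeth %s %s seed=%d",
            as.character(packageVersion("ancestryMeth")), stage, seed)

.writeTsv <- function(df, path, stage, seed) {
    con <- file(path, "w")
    writeLines(.artifactHeader(stage, seed), con)
    write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
    path
}

.writeJson <- function(x, path, stage, seed) {
    x <- c(list(tool = paste("ancestryMeth",
                             as.character(packageVersion("ancestryMeth"))),
                stage = stage, seed = seed), x)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
}

# covariate sets of the two simulated tissues: biopsy location for the
# colon-like tissue; cell proportions for the blood-like tissue, dropping
# granulocytes to avoid the sum-to-one collinearity
.demoCovariates <- function(tissue = c("tissue1", "tissue2")) {
    tissue <- match.arg(tissue)
    if (tissue == "tissue1")
        c("age", "sex", "city", "colon_location")
    else
        c("age", "sex", "city", "CD4T", "CD8T", "NK", "Mono", "B")
}

#' Run the full pipeline on a simulated two-tissue cohort
#'
#' Simulates an admixed cohort with known causal structure, writes its
#' input files, and runs every analysis stage: the popDNAm scan in both
#' tissues, a window-size sweep, the genotype-versus-ancestry model
#' ledger, the cross-tissue comparison, context and GWAS-proximity
#' enrichment, the effective-sample-size summary and a two-population
#' subsampling power curve. All artifacts are plain TSV/JSON with a
#' version + seed header; reruns with identical arguments are
#' byte-identical.
#'
#' @param outDir output directory (created if needed)
#' @param seed master seed for every source of randomness
#' @param params a \code{\link{simParams}} list; the default is a small
#'   two-tissue cohort with population-specific-variant causal structure
#' @param omegaSweep window sizes for the sweep
#' @param enrichmentDraws permutation draws for the enrichment stages
#' @param subsampleSizes,subsampleReps subsampling design
#' @return invisibly, a list with \code{artifacts} (file paths) and
#'   \code{results} (the in-memory stage results)
#' @export
runDemo <- function(outDir, seed = 1L,
                    params = simParams(nIndividuals = 96L, nSnps = 800L,
                                       nSites = 400L,
                                       causalMechanism = "popspecific_variant"),
                    omegaSweep = c(200000L, 500000L, 1000000L),
                    enrichmentDraws = 2000L,
                    subsampleSizes = c(10L, 20L, 30L),
                    subsampleReps = 3L) {
    dir.create(file.path(outDir, "inputs"), recursive = TRUE,
               showWarnings = FALSE)
    inp <- function(f) file.path(outDir, "inputs", f)
    out <- function(f) file.path(outDir, f)
    artifacts <- character(0)

    cohort <- simulateCohort(params, seed, tissues = 2L,
                             tissue2Samples =
                                 max(2L, round(0.7 * params$nIndividuals)))
    writeLocalAncestry(cohort$ancestry, inp("local_ancestry.tsv"))
    writeGenotypes(cohort$genotypes, inp("genotypes.tsv"))
    writeManifest(cohort$manifest, inp("manifest.tsv"))
    writeCovariates(cohort$covariates, inp("covariates.tsv"))
    writeMethylation(cohort$meth, inp("methylation_tissue1.tsv"))
    writeMethylation(cohort$meth2, inp("methylation_tissue2.tsv"))
    writeGwasCatalog(cohort$gwas, inp("gwas_catalog.tsv"))

    scan1 <- scanPopDNAm(cohort$meth, cohort$ancestry, cohort$covariates,
                         omega = params$windowOmega,
                         covariateNames = .demoCovariates("tissue1"))
    scan2 <- scanPopDNAm(cohort$meth2, cohort$ancestry, cohort$covariates,
                         omega = params$windowOmega,
                         covariateNames = .demoCovariates("tissue2"))
    artifacts <- c(artifacts,
        writeScanResult(scan1, out("scan_tissue1.tsv")),
        writeScanResult(scan2, out("scan_tissue2.tsv")))

    sweep <- scanSweep(cohort$meth, cohort$ancestry, cohort$covariates,
                       omegaList = omegaSweep,
                       covariateNames = .demoCovariates("tissue1"))
    artifacts <- c(artifacts,
        .writeTsv(sweep$summary, out("sweep.tsv"), "sweep", seed))

    ledger <- modelLedger(scan1, cohort$meth, cohort$ancestry,
                          cohort$genotypes, cohort$covariates,
                          covariateNames = .demoCovariates("tissue1"))
    artifacts <- c(artifacts,
        writeModelLedger(ledger, out("ledger_pairs.tsv")),
        .writeJson(ledgerSummary(ledger), out("ledger_summary.json"),
                   "ledger", seed))

    ct <- crossTissue(scan1, scan2)
    artifacts <- c(artifacts,
        .writeJson(ct, out("crosstissue.json"), "crosstissue", seed),
        .writeTsv(pairedEffects(scan1, scan2), out("paired_effects.tsv"),
                  "crosstissue", seed))

    wa <- windowedProportions(cohort$ancestry, cohort$manifest,
                              omega = params$windowOmega,
                              minSnps = params$minSnps)
    ess <- effectiveSampleSize(wa)
    artifacts <- c(artifacts,
        .writeTsv(ess$perSite, out("effective_n_sites.tsv"),
                  "effective_n", seed),
        .writeJson(list(average = as.list(ess$average),
                        threshold = ess$threshold),
                   out("effective_n.json"), "effective_n", seed))

    tested1 <- scanTable(scan1)$site_id
    sig1 <- significantSites(scan1)
    if (length(sig1)) {
        enr <- permutationEnrichment(sig1, tested1, cohort$manifest,
                                     nDraws = enrichmentDraws,
                                     seed = seed)
        gwas <- gwasProximityEnrichment(sig1, tested1, cohort$manifest,
                                        cohort$gwas,
                                        nDraws = enrichmentDraws,
                                        seed = seed)
        artifacts <- c(artifacts,
            .writeTsv(enr, out("enrichment.tsv"), "enrichment", seed),
            .writeJson(gwas, out("gwas_enrichment.json"), "enrichment",
                       seed))
    } else {
        enr <- NULL; gwas <- NULL
    }

    tg <- simulateTwoGroupCohort(nPerGroup = max(subsampleSizes) + 10L,
                                 nSites = 400L, seed = seed)
    power <- subsamplePower(tg$M, tg$population, tg$gender,
                            sizes = subsampleSizes, nReps = subsampleReps,
                            seed = seed)
    artifacts <- c(artifacts,
        .writeTsv(power$curve, out("subsample_curve.tsv"), "subsample",
                  seed))

    summary <- list(
        nSitesTested = scan1@counts$nTested,
        nSignificantTissue1 = length(sig1),
        nSignificantTissue2 = length(significantSites(scan2)),
        overlapCount = ct$overlapCount,
        replicationFraction = ct$replicationAtoB$fraction,
        bestModelFraction = as.list(ledgerSummary(ledger)$bestModelFraction),
        effectiveN = as.list(ess$average))
    artifacts <- c(artifacts,
        .writeJson(summary, out("summary.json"), "summary", seed))

    invisible(list(artifacts = artifacts,
                   results = list(cohort = cohort, scan1 = scan1,
                                  scan2 = scan2, sweep = sweep,
                                  ledger = ledger, crosstissue = ct,
                                  effectiveN = ess, enrichment = enr,
                                  gwasEnrichment = gwas, power = power)))
}
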