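## Readers and writers for the plain-text file contracts. Coordinates are
## 1-based inclusive throughout (Illumina manifest / VCF convention). All
## ancestry-bearing files carry integer codes together with an explicit
## code-to-label mapping, never bare integers.

.DEFAULT_CODES <- c(EUR = 1L, NAM = 2L, AFR = 3L)
.ISLAND_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "Sea")
.GENE_LEVELS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR")

.codesHeader <- function(codes)
    paste0("# ancestry_codes: ",
           paste(sprintf("%d=%s", codes, names(codes)), collapse = " "))

.parseCodesHeader <- function(lines) {
    h <- grep("^# ancestry_codes:", lines, value = TRUE)
    if (!length(h)) return(NULL)
    toks <- strsplit(sub("^# ancestry_codes:\\s*", "", h[1]), "\\s+")[[1]]
    parts <- strsplit(toks, "=")
    codes <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    names(codes) <- vapply(parts, function(p) p[2], character(1))
    codes
}

.readMarkerMap <- function(mapPath) {
    map <- read.table(mapPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(map)))
        stop("marker map must have columns snp_id, chrom, pos")
    gr <- GRanges(map$chrom, IRanges(map$pos, width = 1))
    names(gr) <- map$snp_id
    if (!is.null(map$genetic_pos)) mcols(gr)$genetic_pos <- map$genetic_pos
    gr
}

.writeMarkerMap <- function(snps, mapPath) {
    df <- data.frame(snp_id = names(snps),
                     chrom = as.character(seqnames(snps)),
                     pos = start(snps))
    gp <- mcols(snps)$genetic_pos
    if (!is.null(gp)) df$genetic_pos <- gp
    write.table(df, mapPath, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read and write phased local-ancestry calls
#'
#' Two dialects are supported. \code{"rfmix_viterbi"} is the RFMix v1
#' Viterbi layout: whitespace-delimited integer ancestry codes, one row per
#' SNP and one column per haplotype (two consecutive columns per sample),
#' with sample ids in a \code{<path>.samples} sidecar (one id per line) and
#' SNP coordinates in a \code{<path>.map} sidecar (TSV: snp_id, chrom, pos,
#' optional genetic_pos). \code{"internal_tsv"} is the canonical long
#' interchange format: a \code{# ancestry_codes: 1=EUR 2=NAM 3=AFR} mapping
#' header followed by TSV columns snp_id, sample, hap, code, with the same
#' \code{.map} sidecar. Undeclared codes are an error naming the offending
#' token and line; a SNP-count mismatch between calls and map is an error.
#'
#' @param path file to read or write; sidecars live at \code{<path>.map}
#'   (and \code{<path>.samples} for the RFMix dialect)
#' @param format \code{"internal_tsv"} or \code{"rfmix_viterbi"}
#' @param codes named integer vector mapping labels EUR/NAM/AFR to the
#'   integer codes used in the file; for \code{internal_tsv} a mapping
#'   header inside the file takes precedence
#' @param sampleIds sample ids for the RFMix dialect, overriding the
#'   \code{.samples} sidecar
#' @param mapPath marker-map path, default \code{<path>.map}
#' @return \code{readLocalAncestry} returns a \linkS4class{LocalAncestry};
#'   \code{writeLocalAncestry} invisibly returns \code{path}.
#' @export
readLocalAncestry <- function(path,
                              format = c("internal_tsv", "rfmix_viterbi"),
                              codes = c(EUR = 1L, NAM = 2L, AFR = 3L),
                              sampleIds = NULL,
                              mapPath = paste0(path, ".map")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    snps <- .readMarkerMap(mapPath)
    if (format == "internal_tsv") {
        lines <- readLines(path)
        hdr <- .parseCodesHeader(lines)
        if (!is.null(hdr)) codes <- hdr
        body <- lines[!startsWith(lines, "#")]
        dat <- read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
        need <- c("snp_id", "sample", "hap", "code")
        if (!all(need %in% names(dat)))
            stop("internal_tsv needs columns snp_id, sample, hap, code")
        bad <- which(!(dat$code %in% codes))
        if (length(bad))
            stop(sprintf(
                "unknown ancestry code '%s' at line %d (declared: %s)",
                dat$code[bad[1]],
                sum(startsWith(lines, "#")) + 1L + bad[1],
                paste(sprintf("%d=%s", codes, names(codes)), collapse = " ")))
        samples <- unique(dat$sample)
        ids <- unique(dat$snp_id)
        if (length(ids) != length(snps) || !setequal(ids, names(snps)))
            stop("SNP set in calls does not match the marker map (",
                 length(ids), " vs ", length(snps), " SNPs)")
        lut <- rep(NA_integer_, max(codes))
        lut[codes] <- match(names(codes), .ANCESTRIES)
        code <- lut[dat$code]
        si <- match(dat$snp_id, names(snps))
        sj <- match(dat$sample, samples)
        hap1 <- matrix(NA_integer_, length(snps), length(samples))
        hap2 <- hap1
        h1 <- dat$hap == 1
        hap1[cbind(si[h1], sj[h1])] <- code[h1]
        hap2[cbind(si[!h1], sj[!h1])] <- code[!h1]
        if (anyNA(hap1) || anyNA(hap2))
            stop("incomplete calls: two haplotypes per sample per SNP required")
        colnames(hap1) <- colnames(hap2) <- samples
        LocalAncestry(hap1, hap2, snps)
    } else {
        if (is.null(sampleIds)) {
            sf <- paste0(path, ".samples")
            if (!file.exists(sf))
                stop("RFMix dialect needs 'sampleIds' or a ", sf, " sidecar")
            sampleIds <- readLines(sf)
        }
        calls <- as.matrix(read.table(path, header = FALSE))
        if (nrow(calls) != length(snps))
            stop("SNP count mismatch: ", nrow(calls), " call rows vs ",
                 length(snps), " map entries")
        if (ncol(calls) != 2L * length(sampleIds))
            stop("expected ", 2L * length(sampleIds),
                 " haplotype columns, found ", ncol(calls))
        bad <- which(!(calls %in% codes))
        if (length(bad))
            stop(sprintf(
                "unknown ancestry code '%s' at line %d (declared: %s)",
                calls[bad[1]], (bad[1] - 1L) %% nrow(calls) + 1L,
                paste(sprintf("%d=%s", codes, names(codes)), collapse = " ")))
        lut <- rep(NA_integer_, max(codes))
        lut[codes] <- match(names(codes), .ANCESTRIES)
        rec <- matrix(lut[calls], nrow(calls), ncol(calls))
        hap1 <- rec[, seq(1L, ncol(rec), by = 2L), drop = FALSE]
        hap2 <- rec[, seq(2L, ncol(rec), by = 2L), drop = FALSE]
        colnames(hap1) <- colnames(hap2) <- sampleIds
        LocalAncestry(hap1, hap2, snps)
    }
}

#' @rdname readLocalAncestry
#' @param x a \linkS4class{LocalAncestry}
#' @export
writeLocalAncestry <- function(x, path,
                               format = c("internal_tsv", "rfmix_viterbi"),
                               codes = c(EUR = 1L, NAM = 2L, AFR = 3L),
                               mapPath = paste0(path, ".map")) {
    format <- match.arg(format)
    stopifnot(is(x, "LocalAncestry"))
    .writeMarkerMap(rowRanges(x), mapPath)
    backmap <- codes[match(.ANCESTRIES, names(codes))]
    h1 <- assay(x, "hap1"); h2 <- assay(x, "hap2")
    if (format == "internal_tsv") {
        samples <- colnames(x)
        long <- data.frame(
            snp_id = rep(names(rowRanges(x)), times = 2L * ncol(x)),
            sample = rep(rep(samples, each = nrow(x)), times = 2L),
            hap = rep(1:2, each = nrow(x) * ncol(x)),
            code = c(backmap[h1], backmap[h2]))
        con <- file(path, "w")
        writeLines(.codesHeader(codes), con)
        write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
    } else {
        wide <- matrix(0L, nrow(x), 2L * ncol(x))
        wide[, seq(1L, ncol(wide), by = 2L)] <- backmap[h1]
        wide[, seq(2L, ncol(wide), by = 2L)] <- backmap[h2]
        write.table(wide, path, sep = " ", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        writeLines(colnames(x), paste0(path, ".samples"))
    }
    invisible(path)
}

#' Read and write the CpG site manifest
#'
#' TSV with columns site_id, chrom, pos (1-based), gene_relations
#' (semicolon-joined subset of TSS1500/TSS200/5'UTR/1stExon/Body/3'UTR,
#' empty for intergenic sites) and island_relation (exactly one of Island,
#' N_Shore, S_Shore, N_Shelf, S_Shelf, Sea).
#'
#' @param path manifest TSV
#' @return a \code{GRanges} named by site id with metadata columns
#'   \code{gene_relations} (a \code{CharacterList}) and
#'   \code{island_relation}
#' @export
readManifest <- function(path) {
    dat <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#",
                      quote = "")
    need <- c("site_id", "chrom", "pos", "gene_relations", "island_relation")
    if (!all(need %in% names(dat)))
        stop("manifest needs columns ", paste(need, collapse = ", "))
    if (anyDuplicated(dat$site_id))
        stop("duplicated site_id in manifest: ",
             dat$site_id[duplicated(dat$site_id)][1])
    bad <- setdiff(unique(dat$island_relation), .ISLAND_LEVELS)
    if (length(bad))
        stop("unknown island_relation label: ", bad[1])
    rel <- strsplit(ifelse(is.na(dat$gene_relations), "", dat$gene_relations),
                    ";", fixed = TRUE)
    badg <- setdiff(unique(unlist(rel)), .GENE_LEVELS)
    if (length(badg))
        stop("unknown gene relation label: ", badg[1])
    gr <- GRanges(dat$chrom, IRanges(dat$pos, width = 1))
    names(gr) <- dat$site_id
    mcols(gr)$gene_relations <- CharacterList(rel)
    mcols(gr)$island_relation <- dat$island_relation
    gr
}

#' @rdname readManifest
#' @param manifest a manifest \code{GRanges} as returned by
#'   \code{readManifest}
#' @export
writeManifest <- function(manifest, path) {
    df <- data.frame(
        site_id = names(manifest),
        chrom = as.character(seqnames(manifest)),
        pos = start(manifest),
        gene_relations = vapply(mcols(manifest)$gene_relations,
                                paste, character(1), collapse = ";"),
        island_relation = mcols(manifest)$island_relation)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write methylation M-value matrices
#'
#' TSV with first column \code{site_id} and one column per sample; values
#' are M-scale methylation. Coordinates are attached from the manifest;
#' sites absent from the manifest or duplicated are an error.
#'
#' @param path matrix TSV
#' @param manifest manifest \code{GRanges} (see \code{\link{readManifest}})
#' @param tissue tissue label to attach
#' @return a \linkS4class{MethylationSet}
#' @export
readMethylation <- function(path, manifest, tissue = "unknown") {
    dat <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (names(dat)[1] != "site_id")
        stop("first column must be site_id")
    if (anyDuplicated(dat$site_id))
        stop("duplicated site_id: ", dat$site_id[duplicated(dat$site_id)][1])
    miss <- setdiff(dat$site_id, names(manifest))
    if (length(miss))
        stop(length(miss), " sites not present in the manifest (first: ",
             miss[1], ")")
    M <- as.matrix(dat[, -1, drop = FALSE])
    rownames(M) <- dat$site_id
    MethylationSet(M, manifest[dat$site_id], tissue = tissue)
}

#' @rdname readMethylation
#' @param x a \linkS4class{MethylationSet}
#' @export
writeMethylation <- function(x, path) {
    df <- data.frame(site_id = rownames(x), assay(x, "M"),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write sample covariate tables
#'
#' TSV keyed by a \code{sample} column; remaining columns are covariates
#' (age in years, sex, recruitment city, biopsy location, blood cell
#' proportions, ...). Missing values in covariates used by a model are a
#' hard error at fit time, not imputed.
#'
#' @param path covariate TSV
#' @return data.frame with sample ids as row names
#' @export
readCovariates <- function(path) {
    dat <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    if (names(dat)[1] != "sample") stop("first column must be 'sample'")
    if (anyDuplicated(dat$sample)) stop("duplicated sample ids")
    rownames(dat) <- dat$sample
    dat[, -1, drop = FALSE]
}

#' @rdname readCovariates
#' @param covars covariate data.frame with sample row names
#' @export
writeCovariates <- function(covars, path) {
    df <- data.frame(sample = rownames(covars), covars, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write genotype matrices
#'
#' \code{format = "tsv"}: columns snp_id, chrom, pos, then one column per
#' sample with reference-allele dosage 0/1/2. \code{format = "vcf"}: a VCF
#' whose GT field is parsed; phased genotypes (\code{|} separator) populate
#' per-haplotype assays, and dosage counts \emph{reference} alleles, i.e. a
#' GT of \code{0|1} gives dosage 1.
#'
#' @param path input file
#' @param format \code{"tsv"} or \code{"vcf"}
#' @return a \linkS4class{PhasedGenotypes}
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    if (format == "tsv") {
        dat <- read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
        need <- c("snp_id", "chrom", "pos")
        if (!all(need %in% names(dat)))
            stop("genotype TSV needs columns snp_id, chrom, pos, <samples>")
        if (anyDuplicated(dat$snp_id)) stop("duplicated snp_id")
        gr <- GRanges(dat$chrom, IRanges(dat$pos, width = 1))
        names(gr) <- dat$snp_id
        dosage <- as.matrix(dat[, setdiff(names(dat), need), drop = FALSE])
        rownames(dosage) <- dat$snp_id
        PhasedGenotypes(dosage, gr)
    } else {
        vcf <- VariantAnnotation::readVcf(path)
        gt <- VariantAnnotation::geno(vcf)$GT
        if (is.null(gt)) stop("VCF has no GT field")
        gr <- granges(SummarizedExperiment::rowRanges(vcf))
        mcols(gr) <- NULL
        phased <- all(grepl("|", gt, fixed = TRUE))
        al <- strsplit(gt, "[|/]")
        a1 <- matrix(vapply(al, `[`, character(1), 1L), nrow(gt))
        a2 <- matrix(vapply(al, `[`, character(1), 2L), nrow(gt))
        if (anyNA(suppressWarnings(as.integer(a1))))
            stop("missing or malformed GT calls in VCF")
        # reference-allele indicators per haplotype
        h1 <- (a1 == "0") + 0L; h2 <- (a2 == "0") + 0L
        dimnames(h1) <- dimnames(h2) <- dimnames(gt)
        if (phased)
            PhasedGenotypes(h1 + h2, gr, hap1 = h1, hap2 = h2)
        else
            PhasedGenotypes(h1 + h2, gr)
    }
}

#' @rdname readGenotypes
#' @param x a \linkS4class{PhasedGenotypes}
#' @export
writeGenotypes <- function(x, path) {
    df <- data.frame(snp_id = rownames(x),
                     chrom = as.character(seqnames(rowRanges(x))),
                     pos = start(rowRanges(x)),
                     assay(x, "dosage"), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read and write a GWAS-catalog-like SNP position list
#'
#' TSV with columns snp_id, chrom, pos (1-based).
#'
#' @param path catalog TSV
#' @return \code{GRanges} named by snp_id
#' @export
readGwasCatalog <- function(path) {
    dat <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    need <- c("snp_id", "chrom", "pos")
    if (!all(need %in% names(dat)))
        stop("catalog needs columns snp_id, chrom, pos")
    gr <- GRanges(dat$chrom, IRanges(dat$pos, width = 1))
    names(gr) <- dat$snp_id
    gr
}

#' @rdname readGwasCatalog
#' @param catalog catalog \code{GRanges}
#' @export
writeGwasCatalog <- function(catalog, path) {
    df <- data.frame(snp_id = names(catalog),
                     chrom = as.character(seqnames(catalog)),
                     pos = start(catalog))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Intersect sample sets across input objects
#'
#' All pipeline stages operate on the intersection of the sample ids
#' carried by their inputs. Reports, via \code{message()}, how many samples
#' each input loses; order of the inputs does not affect the result (the
#' intersection is returned in the order of the first input).
#'
#' @param ... character vectors of sample ids, or objects with
#'   \code{colnames()} / row names (covariate tables)
#' @return character vector of common sample ids
#' @export
intersectSamples <- function(...) {
    inputs <- list(...)
    ids <- lapply(inputs, function(x) {
        if (is.character(x)) x
        else if (is.data.frame(x)) rownames(x)
        else colnames(x)
    })
    common <- Reduce(intersect, ids)
    if (!length(common))
        stop("no overlapping samples across inputs")
    dropped <- vapply(ids, function(s) length(setdiff(s, common)), integer(1))
    if (any(dropped > 0))
        message("sample intersection: ", length(common), " kept; dropped ",
                paste(dropped, collapse = "+"), " across ", length(ids),
                " inputs")
    common
}
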