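#' @rdname LocalAncestry-class
#' @param x an object
#' @param haplotype integer, 1 or 2
#' @export
setGeneric("ancestryCodes", function(x, haplotype = 1L)
    standardGeneric("ancestryCodes"))

#' @rdname MethylationSet-class
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))

#' @rdname WindowedAncestry-class
#' @param population one of \code{ancestryLabels()}
#' @export
setGeneric("ancestryProportion", function(x, population)
    standardGeneric("ancestryProportion"))

#' @rdname WindowedAncestry-class
#' @export
setGeneric("nSnpsInWindow", function(x) standardGeneric("nSnpsInWindow"))

#' @rdname WindowedAncestry-class
#' @export
setGeneric("isTested", function(x) standardGeneric("isTested"))

#' @rdname ScanResult-class
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname ScanResult-class
#' @param alpha FDR level; defaults to the level the scan was run at
#' @export
setGeneric("significantSites", function(x, alpha = NULL)
    standardGeneric("significantSites"))

#' @rdname ModelLedger-class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))
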