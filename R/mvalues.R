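#' Convert between methylation beta- and M-values
#'
#' The M-value is the logit2 of the methylated fraction beta:
#' \code{M = log2(beta / (1 - beta))}. Array betas of exactly 0 or 1 (which
#' map to infinite M) are clipped to \code{[eps, 1 - eps]} with a warning
#' before conversion; values outside \code{[0, 1]} are an error.
#'
#' @param beta numeric vector of methylated fractions in \code{[0, 1]}
#' @param m numeric vector of M-values
#' @param eps clipping bound for betas of exactly 0 or 1 (default
#'   \code{1e-6})
#' @return \code{betaToM} returns M-values; \code{mToBeta} returns betas.
#'   The two round-trip to within 1e-12 away from the clipping bounds.
#' @export
#' @examples
#' betaToM(c(0.5, 0.8))   # 0, 2
#' mToBeta(betaToM(0.3))  # 0.3
betaToM <- function(beta, eps = 1e-6) {
    if (anyNA(beta) || any(beta < 0 | beta > 1))
        stop("beta values must lie in [0, 1]")
    if (any(beta == 0 | beta == 1)) {
        warning("beta values of exactly 0 or 1 clipped to [",
                format(eps), ", 1 - ", format(eps), "] before M conversion")
        beta <- pmin(pmax(beta, eps), 1 - eps)
    }
    log2(beta / (1 - beta))
}

#' @rdname betaToM
#' @export
mToBeta <- function(m) {
    1 / (1 + 2^(-m))
}
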