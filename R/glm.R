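#' NB GLM likelihood-ratio tests and DA calls
#'
#' \code{glmLRTest} fits, per ASV, the NB log-linear model
#' \eqn{\log \mu = \mathrm{offset} + X\beta} (offset = log effective library
#' size) by iteratively reweighted least squares, and tests a single
#' coefficient with the likelihood-ratio statistic
#' \eqn{2(\ell_{full} - \ell_{reduced})} against \eqn{\chi^2_1}. The
#' reported log2 fold change is \emph{shrunken}: it is re-estimated on counts
#' augmented with a small prior count (\code{priorCount}, apportioned across
#' samples in proportion to effective library size) so that ASVs with zero
#' counts in one group get a finite fold change; p-values always come from
#' the unaugmented fit. ASVs whose IRLS fails to converge get \code{PValue =
#' NA} (treated as non-significant downstream).
#'
#' \code{bhFdr} applies the Benjamini-Hochberg step-up adjustment
#' (\code{NA}s propagate); \code{callDA} labels each ASV \code{up} /
#' \code{down} / \code{ns} using strict thresholds (\code{FDR < fdrMax} and
#' \code{|logFC| > minAbsLogFC}).
#'
#' @param counts ASV x sample count matrix
#' @param design model matrix; \code{coef} indexes the tested column
#' @param coef column of \code{design} tested (default: last)
#' @param dispersion per-ASV (or scalar) NB dispersion
#' @param offset per-sample log effective library sizes
#' @param priorCount prior count for fold-change shrinkage (default 0.125)
#' @return \code{glmLRTest}: data.frame with \code{asv_id}, \code{logFC},
#'   \code{logCPM}, \code{LRT}, \code{PValue}, \code{converged}.
#' @name diffabund-glm
NULL

#' @rdname diffabund-glm
#' @export
glmLRTest <- function(counts, design, coef = ncol(design), dispersion,
                      offset = NULL, priorCount = 0.125) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("row", seq_len(nrow(counts)))
    design <- as.matrix(design)
    n <- ncol(counts)
    if (is.null(offset)) offset <- log(colSums(counts))
    effLib <- exp(offset)
    phi <- rep_len(dispersion, nrow(counts))
    full <- .nbglm_fit_cpp(counts, design, offset, phi)
    reduced <- .nbglm_fit_cpp(counts, design[, -coef, drop = FALSE],
                              offset, phi)
    lrt <- 2 * (full$loglik - reduced$loglik)
    lrt <- pmax(lrt, 0)
    conv <- full$converged & reduced$converged
    p <- pchisq(lrt, df = 1, lower.tail = FALSE)
    p[!conv] <- NA_real_
    # shrunken logFC: refit with library-size-proportional prior counts
    prior <- priorCount * effLib / mean(effLib)
    aug <- sweep(counts, 2, prior, "+")
    offAug <- log(effLib + 2 * prior)
    fitAug <- .nbglm_fit_cpp(aug, design, offAug, phi)
    logFC <- fitAug$beta[, coef] / log(2)
    cpm <- sweep(counts + 0.5, 2, effLib + 1, "/") * 1e6
    data.frame(asv_id = rownames(counts), logFC = logFC,
               logCPM = log2(rowMeans(cpm)), LRT = lrt, PValue = p,
               converged = conv, stringsAsFactors = FALSE)
}

#' @rdname diffabund-glm
#' @param p vector of p-values in [0, 1] (NA allowed)
#' @export
bhFdr <- function(p) {
    ok <- is.na(p) | (p >= 0 & p <= 1)
    if (!all(ok)) stop("p-values outside [0, 1]")
    p.adjust(p, method = "BH")
}

#' @rdname diffabund-glm
#' @param results data.frame with \code{logFC} and \code{FDR} columns
#' @param fdrMax FDR threshold (strict \code{<}; default 0.1)
#' @param minAbsLogFC absolute log2-fold-change threshold (strict \code{>};
#'   default 2)
#' @return \code{callDA}: the input with a \code{call} factor column
#'   (\code{up}/\code{down}/\code{ns}).
#' @export
callDA <- function(results, fdrMax = 0.1, minAbsLogFC = 2) {
    stopifnot(all(c("logFC", "FDR") %in% colnames(results)))
    sig <- !is.na(results$FDR) & results$FDR < fdrMax
    call <- rep("ns", nrow(results))
    call[sig & results$logFC > minAbsLogFC] <- "up"
    call[sig & results$logFC < -minAbsLogFC] <- "down"
    results$call <- factor(call, levels = c("up", "down", "ns"))
    results
}
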