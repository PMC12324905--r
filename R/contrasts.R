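#' Contrast specifications for lysis and habitat indices
#'
#' The three named two-group comparisons of the pipeline:
#' \describe{
#'   \item{\code{CLI_EPI}}{cell-free vs cell-associated rRNA within
#'     epipelagic samples; logFC > 0 = cf-enriched (lysed).}
#'   \item{\code{CLI_MES}}{cell-free vs cell-associated rRNA within
#'     mesopelagic samples; same sign convention.}
#'   \item{\code{EEI}}{epipelagic vs mesopelagic samples of
#'     cell-associated rRNA; logFC > 0 = epipelagic-enriched.}
#' }
#'
#' @param name one of \code{"CLI_EPI"}, \code{"CLI_MES"}, \code{"EEI"}
#' @return a \code{ContrastSpec} list: \code{name}, \code{select} (predicate
#'   on the sample table), \code{group_var}, \code{groupA} (numerator),
#'   \code{groupB} (reference).
#' @examples
#' contrastSpec("CLI_MES")
#' @export
contrastSpec <- function(name = c("CLI_EPI", "CLI_MES", "EEI")) {
    name <- match.arg(name)
    spec <- switch(name,
        CLI_EPI = list(select = function(s) s$layer == "epipelagic",
                       group_var = "fraction",
                       groupA = "cell_free", groupB = "cell_associated"),
        CLI_MES = list(select = function(s) s$layer == "mesopelagic",
                       group_var = "fraction",
                       groupA = "cell_free", groupB = "cell_associated"),
        EEI = list(select = function(s) s$fraction == "cell_associated",
                   group_var = "layer",
                   groupA = "epipelagic", groupB = "mesopelagic"))
    spec$name <- name
    class(spec) <- "ContrastSpec"
    spec
}

#' Run a differential-abundance contrast
#'
#' The full per-contrast pipeline: select the samples the contrast compares,
#' drop ASVs present (nonzero) in fewer than \code{minPrevalence} of the
#' selected samples, compute TMM normalisation factors, estimate NB
#' dispersions (common + tagwise), fit the two-group NB GLM and
#' likelihood-ratio test per ASV, adjust p-values by Benjamini-Hochberg
#' (per contrast) and call differential abundance. For \code{CLI} contrasts
#' the logFC column is the cell-lysis index; for \code{EEI} the epipelagic
#' enrichment index.
#'
#' @param x \linkS4class{MorsExperiment} (normally rarefied)
#' @param spec a \code{ContrastSpec} or its name
#' @param minPrevalence minimum number of selected samples with a nonzero
#'   count (default 4)
#' @param priorCount prior count for fold-change shrinkage (default 0.125)
#' @param priorDf prior df for tagwise dispersion shrinkage (default 10)
#' @param dispersionType \code{"tagwise"} (default) or \code{"common"}
#' @param fdrMax,minAbsLogFC DA thresholds (defaults 0.1, 2)
#' @return a \linkS4class{ContrastResults}
#' @examples
#' sim <- simulateMorsExperiment(simConfig(n_asvs = 150, seed = 7))
#' res <- runContrast(sim$mors, "CLI_MES")
#' table(res$call)
#' @export
runContrast <- function(x, spec, minPrevalence = 4, priorCount = 0.125,
                        priorDf = 10,
                        dispersionType = c("tagwise", "common"),
                        fdrMax = 0.1, minAbsLogFC = 2) {
    stopifnot(is(x, "MorsExperiment"))
    if (is.character(spec)) spec <- contrastSpec(spec)
    dispersionType <- match.arg(dispersionType)
    si <- sampleInfo(x)
    sel <- spec$select(si)
    si <- si[sel, , drop = FALSE]
    grp <- si[[spec$group_var]]
    if (sum(grp == spec$groupA) < 2 || sum(grp == spec$groupB) < 2)
        stop("contrast ", spec$name, ": each group needs >= 2 samples")
    m <- counts(x)[, si$sample_id, drop = FALSE]
    keep <- rowSums(m > 0) >= minPrevalence
    m <- m[keep, , drop = FALSE]
    if (!nrow(m)) stop("no ASVs pass the prevalence filter")
    nf <- tmmFactors(m)
    offset <- log(nf$eff_lib_sizes)
    design <- cbind(Intercept = 1, group = as.numeric(grp == spec$groupA))
    disp <- estimateDispersionNB(m, design, offset = offset,
                                 priorDf = priorDf)
    phi <- if (dispersionType == "tagwise") disp$tagwise else disp$common
    res <- glmLRTest(m, design, coef = 2, dispersion = phi, offset = offset,
                     priorCount = priorCount)
    res$FDR <- bhFdr(res$PValue)
    res <- callDA(res, fdrMax = fdrMax, minAbsLogFC = minAbsLogFC)
    res$allZeroGroup <- rowSums(m[, grp == spec$groupA, drop = FALSE]) == 0 |
        rowSums(m[, grp == spec$groupB, drop = FALSE]) == 0
    out <- S4Vectors::DataFrame(res[, c("asv_id", "logFC", "logCPM", "LRT",
                                        "PValue", "FDR", "call",
                                        "allZeroGroup", "converged")])
    rownames(out) <- res$asv_id
    S4Vectors::metadata(out) <- list(
        contrast = spec$name, groupA = spec$groupA, groupB = spec$groupB,
        n_A = sum(grp == spec$groupA), n_B = sum(grp == spec$groupB),
        n_tested = nrow(m), common_dispersion = disp$common,
        dispersion_type = dispersionType)
    new("ContrastResults", out)
}

setMethod("show", "ContrastResults", function(object) {
    md <- S4Vectors::metadata(object)
    cat("ContrastResults:", md$contrast, "(", md$groupA, "vs", md$groupB,
        ")\n")
    cat("  ", nrow(object), "ASVs tested;",
        sum(object$call == "up"), "up,", sum(object$call == "down"),
        "down at FDR < 0.1, |logFC| > 2\n")
    cat("   common dispersion:", signif(md$common_dispersion, 3), "\n")
    invisible(NULL)
})
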