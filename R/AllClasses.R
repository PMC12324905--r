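#' @useDynLib morsR, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats density optimize pchisq pnorm pt p.adjust quantile rlnorm
#'   rnbinom sd setNames complete.cases cor var lm coef
#' @importFrom utils read.delim write.table combn head
NULL

#' MorsExperiment: paired-fraction rRNA metabarcoding container
#'
#' An ASV x sample count container for Mortality-by-Ribosomal-Sequencing
#' (MoRS) analyses. It extends
#' \linkS4class{SummarizedExperiment}: the single \code{"counts"}
#' assay holds nonnegative integer read counts, \code{colData} holds the
#' per-sample metadata (station, depth, sublayer, layer, rRNA fraction) and
#' \code{rowData} holds the per-ASV taxonomy (PR2-style ranks \code{Lv1..Lv8}
#' plus a \code{protist} flag).
#'
#' Validity rules: counts are integer-valued and nonnegative; ASV and sample
#' ids are unique; \code{colData} carries \code{station}, \code{depth_m},
#' \code{sublayer} (\code{surface}/\code{SCM}/\code{mesopelagic}),
#' \code{layer} (\code{epipelagic}/\code{mesopelagic}) and \code{fraction}
#' (\code{cell_associated}/\code{cell_free}); \code{layer} is
#' \code{epipelagic} exactly when \code{sublayer} is \code{surface} or
#' \code{SCM}.
#'
#' @seealso \code{\link{MorsExperiment}} (constructor),
#'   \code{\link{readMorsExperiment}}, \code{\link{simulateMorsExperiment}}
#' @name MorsExperiment-class
#' @aliases MorsExperiment-class
#' @exportClass MorsExperiment
setClass("MorsExperiment", contains = "SummarizedExperiment")

.SUBLAYERS <- c("surface", "SCM", "mesopelagic")
.LAYERS <- c("epipelagic", "mesopelagic")
.FRACTIONS <- c("cell_associated", "cell_free")

.validMorsExperiment <- function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
        if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "ASV ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    need <- c("station", "depth_m", "sublayer", "layer", "fraction")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(miss) && nrow(cd)) {
        if (!all(cd$sublayer %in% .SUBLAYERS))
            msg <- c(msg, "sublayer must be surface, SCM or mesopelagic")
        if (!all(cd$layer %in% .LAYERS))
            msg <- c(msg, "layer must be epipelagic or mesopelagic")
        if (!all(cd$fraction %in% .FRACTIONS))
            msg <- c(msg, "fraction must be cell_associated or cell_free")
        epi <- cd$sublayer %in% c("surface", "SCM")
        if (!all((cd$layer == "epipelagic") == epi))
            msg <- c(msg,
                "layer must be 'epipelagic' iff sublayer is surface or SCM")
    }
    if (length(msg)) msg else TRUE
}
setValidity("MorsExperiment", .validMorsExperiment)

#' ContrastResults: per-ASV differential-abundance results
#'
#' A \linkS4class{DFrame} subclass holding one row per tested ASV with columns
#' \code{asv_id}, \code{logFC} (shrunken log2 fold change; houses the CLI or
#' EEI index depending on the contrast), \code{logCPM}, \code{LRT}
#' (likelihood-ratio statistic), \code{PValue}, \code{FDR}
#' (Benjamini-Hochberg) and \code{call} (\code{up}/\code{down}/\code{ns}),
#' plus bookkeeping flags \code{allZeroGroup} (all counts zero in one of the
#' compared groups) and \code{converged}. The contrast name, group labels and
#' group sizes are stored in \code{metadata()}.
#'
#' @name ContrastResults-class
#' @aliases ContrastResults-class
#' @exportClass ContrastResults
setClass("ContrastResults", contains = "DFrame")
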