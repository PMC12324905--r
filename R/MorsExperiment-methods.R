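#' Construct a MorsExperiment
#'
#' Bundle an ASV x sample count matrix with sample metadata and taxonomy into
#' a validated \linkS4class{MorsExperiment}.
#'
#' @param counts integer matrix, ASVs in rows (rownames = ASV ids), samples in
#'   columns (colnames = sample ids).
#' @param sampleInfo \code{data.frame} with one row per sample and columns
#'   \code{sample_id}, \code{station}, \code{depth_m}, \code{sublayer},
#'   \code{layer}, \code{fraction}. Rows are matched to \code{colnames(counts)}
#'   by \code{sample_id}; every sample in \code{counts} must be present.
#' @param taxonomy \code{data.frame} with one row per ASV and columns
#'   \code{asv_id}, rank columns (at least \code{Lv4} and \code{Lv5}) and a
#'   logical \code{protist} flag. Every ASV in \code{counts} must be present.
#' @return a \linkS4class{MorsExperiment}
#' @examples
#' cnt <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'               dimnames = list(c("asv1", "asv2"), c("s1", "s2")))
#' si <- data.frame(sample_id = c("s1", "s2"), station = "st1",
#'                  depth_m = c(10, 300),
#'                  sublayer = c("surface", "mesopelagic"),
#'                  layer = c("epipelagic", "mesopelagic"),
#'                  fraction = "cell_associated")
#' tx <- data.frame(asv_id = c("asv1", "asv2"), Lv4 = "Ciliophora",
#'                  Lv5 = "Spirotrichea", protist = TRUE)
#' MorsExperiment(cnt, si, tx)
#' @export
MorsExperiment <- function(counts, sampleInfo, taxonomy) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have ASV rownames and sample colnames")
    if (!"sample_id" %in% colnames(sampleInfo))
        stop("'sampleInfo' must have a 'sample_id' column")
    if (!"asv_id" %in% colnames(taxonomy))
        stop("'taxonomy' must have an 'asv_id' column")
    missSamp <- setdiff(colnames(counts), sampleInfo$sample_id)
    if (length(missSamp))
        stop("sample(s) in counts missing from sampleInfo: ",
             paste(missSamp, collapse = ", "))
    missAsv <- setdiff(rownames(counts), taxonomy$asv_id)
    if (length(missAsv))
        stop("ASV(s) in counts missing from taxonomy: ",
             paste(head(missAsv, 5), collapse = ", "),
             if (length(missAsv) > 5) ", ..." else "")
    storage.mode(counts) <- "integer"
    cd <- sampleInfo[match(colnames(counts), sampleInfo$sample_id), , drop = FALSE]
    rownames(cd) <- cd$sample_id
    rd <- taxonomy[match(rownames(counts), taxonomy$asv_id), , drop = FALSE]
    rownames(rd) <- rd$asv_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(cd),
        rowData = S4Vectors::DataFrame(rd))
    new("MorsExperiment", se)
}

#' @rdname morsR-generics
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "MorsExperiment", function(object) {
    SummarizedExperiment::assay(object, "counts")
})

#' @rdname morsR-generics
#' @export
setMethod("sampleInfo", "MorsExperiment", function(object) {
    as.data.frame(SummarizedExperiment::colData(object))
})

#' @rdname morsR-generics
#' @export
setMethod("taxonomy", "MorsExperiment", function(object) {
    as.data.frame(SummarizedExperiment::rowData(object))
})

setMethod("show", "MorsExperiment", function(object) {
    cat("MorsExperiment:", nrow(object), "ASVs x", ncol(object), "samples\n")
    cd <- SummarizedExperiment::colData(object)
    if (nrow(cd)) {
        cat("  layers:   ",
            paste(sprintf("%s (%d)", names(table(cd$layer)), table(cd$layer)),
                  collapse = ", "), "\n")
        cat("  fractions:",
            paste(sprintf("%s (%d)", names(table(cd$fraction)),
                          table(cd$fraction)), collapse = ", "), "\n")
    }
    tot <- colSums(SummarizedExperiment::assay(object, "counts"))
    if (length(tot))
        cat("  reads/sample: min", min(tot), "median", stats::median(tot),
            "max", max(tot), "\n")
    invisible(NULL)
})

# internal: replace the counts assay, keeping metadata aligned
.replaceCounts <- function(x, m, keepRows = NULL, keepCols = NULL) {
    if (!is.null(keepRows)) x <- x[keepRows, ]
    if (!is.null(keepCols)) x <- x[, keepCols]
    storage.mode(m) <- "integer"
    SummarizedExperiment::assay(x, "counts") <- m
    methods::validObject(x)
    x
}
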