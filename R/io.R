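#' Read and write the tabular interchange formats
#'
#' All files are UTF-8, tab-separated with a header row. The count table has
#' ASV ids in the first column (\code{asv_id}) and one column per sample;
#' cells are nonnegative integer read counts. The sample-metadata table has
#' columns \code{sample_id}, \code{station}, \code{depth_m}, \code{sublayer},
#' \code{layer}, \code{fraction}. The taxonomy table has \code{asv_id}, rank
#' columns \code{Lv1}..\code{Lv8} (any subset containing \code{Lv4} and
#' \code{Lv5}) and a logical \code{protist} column.
#'
#' Validation is strict: a non-integer or negative count aborts with the
#' offending ASV/sample coordinates, and \code{readMorsExperiment} refuses
#' count tables whose samples or ASVs lack metadata/taxonomy rows.
#'
#' @param path file path
#' @param counts,x matrix / object to write
#' @param sampleInfo,taxonomy data.frames as above
#' @param countsFile,sampleFile,taxonomyFile paths of the three tables
#' @return \code{readCountTable}: named integer matrix. \code{readSampleInfo},
#'   \code{readTaxonomy}: data.frame. \code{readMorsExperiment}:
#'   \linkS4class{MorsExperiment}. Writers return the path, invisibly.
#' @name mors-io
NULL

#' @rdname mors-io
#' @export
readCountTable <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("count table needs an asv_id column plus >=1 sample column")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) stop("duplicated ASV ids in ", path)
    m <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "invalid count %s at ASV '%s', sample '%s' in %s",
            format(m[bad[1L, , drop = FALSE]]), ids[bad[1L, 1L]],
            colnames(m)[bad[1L, 2L]], path))
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    m
}

#' @rdname mors-io
#' @export
writeCountTable <- function(counts, path) {
    df <- data.frame(asv_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname mors-io
#' @export
readSampleInfo <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "station", "depth_m", "sublayer", "layer",
              "fraction")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("sample info lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in ", path)
    df
}

#' @rdname mors-io
#' @export
writeSampleInfo <- function(sampleInfo, path) {
    write.table(sampleInfo, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname mors-io
#' @export
readTaxonomy <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("asv_id", "protist") %in% colnames(df)))
        stop("taxonomy needs 'asv_id' and 'protist' columns")
    if (anyDuplicated(df$asv_id)) stop("duplicated ASV ids in ", path)
    df$protist <- as.logical(df$protist)
    if (anyNA(df$protist)) stop("'protist' column must be TRUE/FALSE")
    df
}

#' @rdname mors-io
#' @export
writeTaxonomy <- function(taxonomy, path) {
    write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname mors-io
#' @export
readMorsExperiment <- function(countsFile, sampleFile, taxonomyFile) {
    MorsExperiment(readCountTable(countsFile), readSampleInfo(sampleFile),
                   readTaxonomy(taxonomyFile))
}

#' @rdname mors-io
#' @param dir output directory (created if absent); files
#'   \code{counts.tsv}, \code{samples.tsv}, \code{taxonomy.tsv}
#' @export
writeMorsExperiment <- function(x, dir) {
    stopifnot(is(x, "MorsExperiment"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCountTable(counts(x), file.path(dir, "counts.tsv"))
    writeSampleInfo(sampleInfo(x), file.path(dir, "samples.tsv"))
    writeTaxonomy(taxonomy(x), file.path(dir, "taxonomy.tsv"))
    invisible(dir)
}
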