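#' ASV-table preprocessing: prevalence filters, rarefaction, aggregation
#'
#' The standard preprocessing tail applied to a denoised ASV table before
#' lysis profiling: removal of non-protist lineages, removal of rare ASVs,
#' rarefaction to a fixed depth, and taxonomic aggregation. All functions
#' accept either a \linkS4class{MorsExperiment} (returned with metadata kept
#' in sync) or a bare count matrix (ASVs x samples; a matrix is returned).
#'
#' \code{filterRare} keeps ASVs with at least \code{minTotal} reads summed
#' over all samples \emph{and} nonzero counts in at least \code{minSamples}
#' samples (defaults: 10 reads, 2 samples). \code{filterNonProtist} keeps
#' ASVs whose taxonomy \code{protist} flag is \code{TRUE} (metazoans,
#' prokaryotes and unclassified reads are dropped). \code{rarefy} subsamples
#' each sample to exactly \code{depth} reads without replacement
#' (multivariate hypergeometric); samples with fewer than \code{depth} reads
#' are dropped with a warning. \code{aggregateByRank} sums counts over a
#' taxonomy rank; \code{relativeAbundance} converts counts to within-sample
#' proportions.
#'
#' @param x \linkS4class{MorsExperiment} or integer count matrix
#' @param minTotal minimum total reads across samples
#' @param minSamples minimum number of samples with a nonzero count
#' @param taxonomy taxonomy data.frame (only needed for matrix input)
#' @param depth rarefaction depth (reads per sample; default 25878)
#' @param seed integer seed for the subsampling RNG (required for
#'   reproducibility; logged via message)
#' @param rank taxonomy rank column name (e.g. \code{"Lv5"})
#' @return same container class as \code{x} (\code{aggregateByRank} returns a
#'   taxa x sample matrix; \code{relativeAbundance} a numeric matrix).
#' @examples
#' m <- matrix(c(12L, 0L, 3L, 9L), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' filterRare(m, minTotal = 10, minSamples = 2)
#' relativeAbundance(m)
#' @name preprocess
NULL

.getCounts <- function(x) {
    if (is(x, "MorsExperiment")) counts(x) else {
        m <- as.matrix(x)
        if (any(m < 0) || any(m != round(m)))
            stop("counts must be nonnegative integers")
        m
    }
}

.subsetRows <- function(x, keep) {
    if (is(x, "MorsExperiment")) x[keep, ] else x[keep, , drop = FALSE]
}

#' @rdname preprocess
#' @export
filterRare <- function(x, minTotal = 10, minSamples = 2) {
    m <- .getCounts(x)
    keep <- rowSums(m) >= minTotal & rowSums(m > 0) >= minSamples
    .subsetRows(x, keep)
}

#' @rdname preprocess
#' @export
filterNonProtist <- function(x, taxonomy = NULL) {
    if (is(x, "MorsExperiment")) taxonomy <- taxonomy(x)
    if (is.null(taxonomy)) stop("taxonomy required for matrix input")
    m <- .getCounts(x)
    miss <- setdiff(rownames(m), taxonomy$asv_id)
    if (length(miss))
        stop("ASV(s) without taxonomy: ", paste(head(miss, 5), collapse = ", "))
    keep <- taxonomy$protist[match(rownames(m), taxonomy$asv_id)]
    if (!any(keep)) warning("no protist ASVs retained")
    .subsetRows(x, keep)
}

#' @rdname preprocess
#' @export
rarefy <- function(x, depth = 25878, seed) {
    if (depth <= 0) stop("'depth' must be positive")
    if (!missing(seed) && !is.null(seed)) {
        set.seed(seed)
        message("rarefy: depth = ", depth, ", seed = ", seed)
    }
    m <- .getCounts(x)
    tot <- colSums(m)
    keep <- tot >= depth
    if (!all(keep))
        warning("dropping ", sum(!keep), " sample(s) below depth ", depth,
                ": ", paste(colnames(m)[!keep], collapse = ", "))
    out <- vapply(which(keep), function(j) {
        cj <- m[, j]
        if (tot[j] == depth) return(cj)
        reads <- rep.int(seq_along(cj), cj)
        drawn <- sample(reads, depth, replace = FALSE)
        tabulate(drawn, nbins = length(cj))
    }, integer(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), colnames(m)[keep]))
    if (is(x, "MorsExperiment")) .replaceCounts(x, out, keepCols = keep)
    else out
}

#' @rdname preprocess
#' @export
aggregateByRank <- function(x, rank, taxonomy = NULL) {
    if (is(x, "MorsExperiment")) taxonomy <- taxonomy(x)
    if (is.null(taxonomy)) stop("taxonomy required for matrix input")
    if (!rank %in% colnames(taxonomy)) stop("unknown rank: ", rank)
    m <- .getCounts(x)
    grp <- taxonomy[[rank]][match(rownames(m), taxonomy$asv_id)]
    if (anyNA(grp)) stop("ASV(s) lacking a '", rank, "' label")
    agg <- rowsum(m, group = grp)
    agg[order(rownames(agg)), , drop = FALSE]
}

#' @rdname preprocess
#' @export
relativeAbundance <- function(x) {
    m <- if (is(x, "MorsExperiment")) counts(x) else as.matrix(x)
    tot <- colSums(m)
    if (any(tot == 0))
        stop("all-zero sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    sweep(m, 2, tot, "/")
}
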