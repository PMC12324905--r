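#' Trimmed-mean-of-M-values (TMM) normalisation factors
#'
#' Compositional normalisation of sequencing libraries. For each sample, M
#' (log2 ratio of library-size-normalised abundance against a reference
#' sample) and A (average log2 abundance) values are computed over ASVs
#' positive in both samples; the upper and lower \code{logratioTrim} fraction
#' of M values and \code{sumTrim} fraction of A values are discarded; the
#' normalisation factor is 2 to the weighted mean of the surviving M values,
#' weighted by the inverse asymptotic (binomial) variance of M. The reference
#' sample is the one whose upper-quartile relative abundance is closest to
#' the across-sample mean upper quartile. Factors are rescaled to have
#' geometric mean 1.
#'
#' @param x \linkS4class{MorsExperiment} or count matrix (ASVs x samples)
#' @param logratioTrim two-sided trim fraction on M values (default 0.30)
#' @param sumTrim two-sided trim fraction on A values (default 0.05)
#' @param refColumn optional reference sample (index or name); default picks
#'   the upper-quartile rule above
#' @return object of class \code{NormFactors}: list with \code{factors}
#'   (named, geometric mean 1), \code{lib_sizes}, \code{eff_lib_sizes}
#'   (product) and \code{ref_sample}.
#' @examples
#' m <- matrix(rpois(60, 50), 10, 6,
#'             dimnames = list(paste0("a", 1:10), paste0("s", 1:6)))
#' tmmFactors(m)
#' @export
tmmFactors <- function(x, logratioTrim = 0.30, sumTrim = 0.05,
                       refColumn = NULL) {
    m <- .getCounts(x)
    if (ncol(m) < 2) stop("need >= 2 samples")
    libs <- colSums(m)
    if (any(libs == 0)) stop("all-zero sample(s)")
    if (is.null(refColumn)) {
        f75 <- apply(m, 2, function(cj) quantile(cj, 0.75)) / libs
        refColumn <- which.min(abs(f75 - mean(f75)))
    } else if (is.character(refColumn)) {
        refColumn <- match(refColumn, colnames(m))
    }
    refCnt <- m[, refColumn]
    refLib <- libs[refColumn]
    f <- vapply(seq_len(ncol(m)), function(j) {
        .tmmPair(m[, j], refCnt, libs[j], refLib, logratioTrim, sumTrim,
                 colnames(m)[j])
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(m)
    structure(list(factors = f, lib_sizes = libs,
                   eff_lib_sizes = libs * f,
                   ref_sample = colnames(m)[refColumn]),
              class = "NormFactors")
}

# single-sample TMM factor against a reference (doubly trimmed weighted mean)
.tmmPair <- function(obs, ref, libObs, libRef, logratioTrim, sumTrim,
                     label = "") {
    keep <- obs > 0 & ref > 0
    if (!any(keep)) {
        warning("sample ", label,
                " shares no positive ASVs with the reference; factor 1")
        return(1)
    }
    obs <- obs[keep]; ref <- ref[keep]
    M <- log2((obs / libObs) / (ref / libRef))
    A <- 0.5 * log2((obs / libObs) * (ref / libRef))
    # inverse asymptotic (binomial) variance of M
    v <- (libObs - obs) / (libObs * obs) + (libRef - ref) / (libRef * ref)
    w <- 1 / v
    fin <- is.finite(M) & is.finite(A) & is.finite(w)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (!length(M) || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep) || sum(w[keep]) == 0) return(1)
    f <- sum(w[keep] * M[keep]) / sum(w[keep])
    if (!is.finite(f)) 1 else 2^f
}
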