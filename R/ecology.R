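#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{ij} = 1 - 2\sum_k \min(x_{ik}, x_{jk}) / (\sum_k x_{ik} +
#' \sum_k x_{jk})}, computed between the columns (samples) of a count
#' table. Values lie in [0, 1]; identical samples give 0, samples with
#' disjoint support give 1.
#'
#' @param x \linkS4class{MorsExperiment} or count matrix (ASVs x samples)
#' @return a \code{\link[stats]{dist}} object over samples
#' @examples
#' brayCurtis(cbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1)))   # 0.5
#' @export
brayCurtis <- function(x) {
    m <- if (is(x, "MorsExperiment")) counts(x) else as.matrix(x)
    tot <- colSums(m)
    if (any(tot == 0))
        stop("all-zero sample(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    ns <- ncol(m)
    d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(ns - 1)) {
        for (j in (i + 1):ns) {
            d[j, i] <- d[i, j] <-
                1 - 2 * sum(pmin(m[, i], m[, j])) / (tot[i] + tot[j])
        }
    }
    stats::as.dist(d)
}

#' Agglomerative clustering with the Ward.D2 criterion
#'
#' Native agglomerative clustering using the Lance-Williams update for
#' Ward's D2 method (squared-dissimilarity criterion): merging clusters
#' \eqn{i, j} updates \eqn{d(ij, k)^2 = [(n_i + n_k) d(i,k)^2 + (n_j + n_k)
#' d(j,k)^2 - n_k d(i,j)^2] / (n_i + n_j + n_k)}. Merge heights are
#' non-decreasing. The return value is a standard \code{hclust} object
#' (merge matrix, heights, leaf order, labels), directly plottable.
#'
#' @param d a \code{\link[stats]{dist}} object or symmetric dissimilarity
#'   matrix
#' @return an object of class \code{hclust}, method \code{"ward.D2"}
#' @examples
#' hc <- wardCluster(brayCurtis(matrix(rpois(40, 10), 8, 5)))
#' hc$height
#' @export
wardCluster <- function(d) {
    dm <- as.matrix(d)
    n <- nrow(dm)
    if (n < 2) stop("need >= 2 samples")
    labels <- rownames(dm)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    d2 <- dm^2
    active <- seq_len(n)
    sizes <- rep(1L, n)
    ids <- -seq_len(n)       # hclust convention: negatives are singletons
    merge <- matrix(0L, n - 1, 2)
    height <- numeric(n - 1)
    for (step in seq_len(n - 1)) {
        sub <- d2[active, active, drop = FALSE]
        diag(sub) <- Inf
        ij <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        i <- active[min(ij)]; j <- active[max(ij)]
        height[step] <- sqrt(d2[i, j])
        # hclust row convention: singletons (by index) before clusters
        v <- c(ids[i], ids[j])
        merge[step, ] <- v[order(v >= 0, abs(v))]
        ni <- sizes[i]; nj <- sizes[j]
        for (k in setdiff(active, c(i, j))) {
            nk <- sizes[k]
            d2[i, k] <- d2[k, i] <-
                ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                 nk * d2[i, j]) / (ni + nj + nk)
        }
        sizes[i] <- ni + nj
        ids[i] <- step
        active <- setdiff(active, j)
    }
    structure(list(merge = merge, height = height,
                   order = .leafOrder(merge, n), labels = labels,
                   method = "ward.D2", call = match.call(),
                   dist.method = "user"),
              class = "hclust")
}

.leafOrder <- function(merge, n) {
    expand <- function(node) {
        if (node < 0) return(-node)
        c(expand(merge[node, 1]), expand(merge[node, 2]))
    }
    expand(n - 1)
}

#' Analysis of similarities (ANOSIM) by permutation
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities. With mid-ranks \eqn{r} of the \eqn{M =
#' n(n-1)/2} pairwise dissimilarities, \eqn{R = (\bar r_{between} - \bar
#' r_{within}) / (M/2)}; \eqn{R} near 1 indicates strong separation, 0 no
#' structure. The p-value is \eqn{(1 + \#\{R^* \ge R\}) / (1 + n_{perm})}
#' over uniformly resampled group labellings.
#'
#' @param d \code{\link[stats]{dist}} object or symmetric matrix
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   samples)
#' @param nPerm number of permutations (default 9999)
#' @param seed optional RNG seed
#' @return object of class \code{AnosimResult}: list with \code{R},
#'   \code{p}, \code{n_perm}, \code{grouping}
#' @examples
#' m <- cbind(a1 = c(10, 0), a2 = c(12, 1), b1 = c(0, 10), b2 = c(1, 12))
#' anosim(brayCurtis(m), c("a", "a", "b", "b"), nPerm = 199, seed = 1)
#' @export
anosim <- function(d, groups, nPerm = 9999, seed = NULL) {
    dm <- as.matrix(d)
    n <- nrow(dm)
    groups <- as.character(groups)
    if (length(groups) != n) stop("one group label per sample required")
    tab <- table(groups)
    if (length(tab) < 2) stop("need >= 2 groups")
    if (any(tab < 2)) stop("every group needs >= 2 samples")
    if (!is.null(seed)) set.seed(seed)
    lt <- lower.tri(dm)
    r <- rank(dm[lt])
    M <- length(r)
    pairIdx <- which(lt, arr.ind = TRUE)
    statR <- function(g) {
        within <- g[pairIdx[, 1]] == g[pairIdx[, 2]]
        (mean(r[!within]) - mean(r[within])) / (M / 2)
    }
    Robs <- statR(groups)
    Rperm <- vapply(seq_len(nPerm), function(i) statR(sample(groups)),
                    numeric(1))
    p <- (1 + sum(Rperm >= Robs)) / (1 + nPerm)
    structure(list(R = Robs, p = p, n_perm = nPerm,
                   grouping = paste(names(tab), collapse = "/")),
              class = "AnosimResult")
}

#' @export
print.AnosimResult <- function(x, ...) {
    cat(sprintf("ANOSIM (%s): R = %.3f, p = %.4g (%d permutations)\n",
                x$grouping, x$R, x$p, x$n_perm))
    invisible(x)
}

#' Log-transformed relative abundance for heatmap display
#'
#' Report-level convenience: log10 of relative abundance, with zeros
#' replaced by half the smallest nonzero proportion in the table before
#' taking logs.
#'
#' @param x \linkS4class{MorsExperiment} or count matrix
#' @return numeric matrix of log10 proportions
#' @export
logRelativeAbundance <- function(x) {
    p <- relativeAbundance(x)
    nz <- min(p[p > 0])
    log10(pmax(p, nz / 2))
}
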