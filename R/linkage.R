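#' Join lysis and habitat results, excluding ASVs without both measures
#'
#' ASVs lacking a computable result in either contrast (removed by the
#' prevalence filter, or with all-zero counts in one of the compared groups)
#' are excluded from all linkage statistics; the remaining ASVs are joined
#' on \code{asv_id}.
#'
#' @param cli,eei \linkS4class{ContrastResults} for a CLI contrast and the
#'   EEI contrast
#' @return data.frame with per-ASV \code{cli_logFC}, \code{cli_fdr},
#'   \code{cli_call}, \code{eei_logFC}, \code{eei_fdr}, \code{eei_call}
#' @export
zeroValueFilter <- function(cli, eei) {
    cliOk <- as.data.frame(cli[!cli$allZeroGroup, ])
    eeiOk <- as.data.frame(eei[!eei$allZeroGroup, ])
    shared <- intersect(cliOk$asv_id, eeiOk$asv_id)
    if (!length(shared)) warning("no ASVs shared between the two contrasts")
    ci <- cliOk[match(shared, cliOk$asv_id), ]
    ei <- eeiOk[match(shared, eeiOk$asv_id), ]
    data.frame(asv_id = shared,
               cli_logFC = ci$logFC, cli_fdr = ci$FDR,
               cli_call = ci$call,
               eei_logFC = ei$logFC, eei_fdr = ei$FDR,
               eei_call = ei$call, stringsAsFactors = FALSE)
}

# round half-up to 1 decimal (report parity)
.round1 <- function(x) floor(x * 10 + 0.5) / 10

#' Intersection of mesopelagic-lysis and epipelagic-enrichment DA sets
#'
#' Counts ASVs called significantly cf-enriched (lysed) in the mesopelagic
#' CLI contrast \emph{and} significantly epipelagic-enriched in the EEI
#' contrast, and expresses the overlap as a percentage of each DA set
#' (rounded half-up to one decimal).
#'
#' @param cliMes,eei \linkS4class{ContrastResults} (or data.frames with
#'   \code{asv_id} and \code{call})
#' @return list: \code{n_shared}, \code{n_cli_mes_up}, \code{n_eei_up},
#'   \code{pct_of_cli_mes}, \code{pct_of_eei} (NA when a DA set is empty)
#' @examples
#' a <- data.frame(asv_id = paste0("x", 1:171), call = "up")
#' b <- data.frame(asv_id = paste0("x", c(1:147, 300:589)), call = "up")
#' intersectDA(a, b)   # 147 shared: 86.0% of a, 33.6% of b
#' @export
intersectDA <- function(cliMes, eei) {
    upCli <- cliMes$asv_id[cliMes$call == "up"]
    upEei <- eei$asv_id[eei$call == "up"]
    shared <- intersect(upCli, upEei)
    list(n_shared = length(shared),
         n_cli_mes_up = length(upCli),
         n_eei_up = length(upEei),
         pct_of_cli_mes = if (length(upCli))
             .round1(100 * length(shared) / length(upCli)) else NA_real_,
         pct_of_eei = if (length(upEei))
             .round1(100 * length(shared) / length(upEei)) else NA_real_)
}

#' Habitat x lysis-depth cross-classification (Sankey counts)
#'
#' Assigns each joined ASV one habitat class (\code{EPI}/\code{MES}/
#' \code{BOTH}) and one lysis class - significantly cf-enriched in the
#' epipelagic contrast only (\code{lysed_EPI}), in the mesopelagic contrast
#' only (\code{lysed_MES}), in both (\code{lysed_both}) or in neither
#' (\code{not_lysed}) - and returns the full contingency table with
#' marginals.
#'
#' @param habitat data.frame from \code{\link{assignAsvHabitat}}
#' @param cliEpi,cliMes \linkS4class{ContrastResults} for the two CLI
#'   contrasts (or data.frames with \code{asv_id}, \code{call})
#' @param asvIds optional ASV id set to restrict to (e.g. the joined set
#'   from \code{\link{zeroValueFilter}}); default: ASVs present in
#'   \code{habitat}
#' @return a table (habitat x lysis class) with \code{sum} marginals
#' @export
sankeyCounts <- function(habitat, cliEpi, cliMes, asvIds = NULL) {
    ids <- if (is.null(asvIds)) habitat$asv_id
           else intersect(asvIds, habitat$asv_id)
    hab <- habitat$habitat[match(ids, habitat$asv_id)]
    upE <- ids %in% cliEpi$asv_id[cliEpi$call == "up"]
    upM <- ids %in% cliMes$asv_id[cliMes$call == "up"]
    lysis <- ifelse(upE & upM, "lysed_both",
             ifelse(upE, "lysed_EPI",
             ifelse(upM, "lysed_MES", "not_lysed")))
    lysis <- factor(lysis, levels = c("lysed_EPI", "lysed_MES",
                                      "lysed_both", "not_lysed"))
    hab <- factor(hab, levels = c("EPI", "MES", "BOTH"))
    stats::addmargins(table(habitat = hab, lysis = lysis))
}

#' Spearman rank correlation (mid-ranks, t approximation)
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the two-sided
#' p-value uses the t approximation with \eqn{n - 2} degrees of freedom.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped)
#' @return list: \code{rho}, \code{p}, \code{n} (\code{rho = NA} for a
#'   constant vector)
#' @export
spearmanCorr <- function(x, y) {
    stopifnot(length(x) == length(y))
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3) stop("need >= 3 complete pairs")
    if (sd(x) == 0 || sd(y) == 0)
        return(list(rho = NA_real_, p = NA_real_, n = n))
    rho <- cor(rank(x), rank(y))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
    list(rho = rho, p = p, n = n)
}

#' Wilcoxon rank-sum test (mid-ranks; exact for small groups)
#'
#' Rank-sum test for a difference in location between two groups, using
#' mid-ranks for ties. For groups both smaller than 8 the two-sided p-value
#' is computed by exhaustive enumeration of all group assignments; for
#' larger groups a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b numeric vectors (each nonempty)
#' @param exactMax exact enumeration when both groups are below this size
#'   (default 8)
#' @return list: \code{W} (rank sum of \code{a}), \code{U}, \code{p},
#'   \code{method}
#' @export
wilcoxonRankSum <- function(a, b, exactMax = 8) {
    if (!length(a) || !length(b)) stop("both groups must be nonempty")
    na <- length(a); nb <- length(b); N <- na + nb
    r <- rank(c(a, b))
    W <- sum(r[seq_len(na)])
    U <- W - na * (na + 1) / 2
    if (na < exactMax && nb < exactMax) {
        combs <- combn(N, na)
        Wall <- colSums(matrix(r[combs], nrow = na))
        pLe <- mean(Wall <= W + 1e-9)
        pGe <- mean(Wall >= W - 1e-9)
        p <- min(1, 2 * min(pLe, pGe))
        method <- "exact"
    } else {
        mW <- na * (N + 1) / 2
        ties <- table(r)
        tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
        vW <- na * nb / 12 * ((N + 1) - tieAdj)
        z <- W - mW
        z <- (z - sign(z) * 0.5) / sqrt(vW)
        p <- 2 * pnorm(-abs(z))
        method <- "normal"
    }
    list(W = W, U = U, p = p, method = method)
}

#' Read fractions of habitat classes per sample category
#'
#' For each (layer, fraction) sample category, the proportion of reads (of
#' the ASVs with habitat calls) belonging to each habitat class.
#'
#' @param x \linkS4class{MorsExperiment} (rarefied counts)
#' @param habitat data.frame from \code{\link{assignAsvHabitat}}
#' @return data.frame: \code{layer}, \code{fraction}, \code{habitat},
#'   \code{read_fraction} (sums to 1 within each category)
#' @export
habitatReadFractions <- function(x, habitat) {
    stopifnot(is(x, "MorsExperiment"))
    m <- counts(x)
    ids <- intersect(rownames(m), habitat$asv_id)
    if (!length(ids)) stop("no ASVs with habitat calls present in counts")
    m <- m[ids, , drop = FALSE]
    hab <- habitat$habitat[match(ids, habitat$asv_id)]
    si <- sampleInfo(x)
    cats <- unique(si[, c("layer", "fraction")])
    out <- do.call(rbind, lapply(seq_len(nrow(cats)), function(i) {
        samp <- si$sample_id[si$layer == cats$layer[i] &
                             si$fraction == cats$fraction[i]]
        reads <- rowSums(m[, samp, drop = FALSE])
        byClass <- tapply(reads, factor(hab, c("EPI", "MES", "BOTH")), sum,
                          default = 0)
        data.frame(layer = cats$layer[i], fraction = cats$fraction[i],
                   habitat = names(byClass),
                   read_fraction = as.numeric(byClass) / sum(reads),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}
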