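#' First-order decay kinetics of extracellular rRNA
#'
#' Spike-in decay experiments are summarised with the first-order model
#' \deqn{C_t = C_0 e^{-kt}}{Ct = C0 exp(-k t)} where \eqn{C_0} and \eqn{C_t}
#' are rRNA concentrations (molecules mL\eqn{^{-1}}) at time zero and
#' \eqn{t} hours, and \eqn{k} (h\eqn{^{-1}}) is the decay rate constant. The
#' half-life is \eqn{t_{1/2} = \ln 2 / k}.
#'
#' \code{fitK} is the two-point estimator \eqn{k = \ln(C_0/C_t)/t}, the
#' primary fit for day-0/day-1 designs; \code{fitKRegression} is the
#' multi-timepoint alternative (OLS of \eqn{\ln C} on \eqn{t}).
#' \code{summariseReplicates} reports the arithmetic mean (and SD) of
#' per-replicate \eqn{k} and the \emph{harmonic} mean of per-replicate
#' half-lives, which equals \eqn{\ln 2 /} (arithmetic mean \eqn{k}) exactly.
#'
#' @param c0,ct concentrations at time zero and time \code{t} (> 0)
#' @param t elapsed time, hours (> 0)
#' @param k decay rate constant(s), h^-1
#' @param times,concentrations paired vectors for the regression fit
#' @return \code{fitK}, \code{halfLife}: numeric. \code{summariseReplicates}:
#'   one-row \code{data.frame} with \code{n}, \code{mean_k}, \code{sd_k},
#'   \code{t_half} (harmonic mean, h), \code{mean_d1_d0}, \code{sd_d1_d0}.
#' @examples
#' k <- fitK(c0 = 1, ct = 0.055, t = 24)   # 0.121 h^-1
#' halfLife(k)                             # 5.72 h
#' summariseReplicates(c(0.118, 0.121, 0.124))
#' @name decay-kinetics
NULL

#' @rdname decay-kinetics
#' @export
fitK <- function(c0, ct, t) {
    stopifnot(length(c0) == length(ct))
    if (any(c0 <= 0) || any(ct <= 0)) stop("concentrations must be > 0")
    if (any(t <= 0)) stop("'t' must be > 0")
    k <- log(c0 / ct) / t
    if (any(k < 0))
        warning("ct > c0: negative decay constant(s) returned")
    k
}

#' @rdname decay-kinetics
#' @export
fitKRegression <- function(times, concentrations) {
    stopifnot(length(times) == length(concentrations))
    if (any(concentrations <= 0)) stop("concentrations must be > 0")
    if (length(times) < 2) stop("need >= 2 timepoints")
    -unname(coef(lm(log(concentrations) ~ times))[2L])
}

#' @rdname decay-kinetics
#' @export
halfLife <- function(k) {
    out <- rep(NA_real_, length(k))
    bad <- k <= 0
    if (any(bad)) warning("non-positive k: half-life undefined, NA returned")
    out[!bad] <- log(2) / k[!bad]
    out
}

#' @rdname decay-kinetics
#' @param ks vector of per-replicate decay constants
#' @param d1_d0 optional vector of per-replicate day-1/day-0 concentration
#'   ratios (reported alongside if given)
#' @export
summariseReplicates <- function(ks, d1_d0 = NULL) {
    if (!length(ks)) stop("need >= 1 replicate")
    pos <- ks > 0
    if (!all(pos))
        warning(sum(!pos), " non-positive k excluded from the half-life ",
                "harmonic mean")
    # harmonic mean of ln2/k_i == ln2 / mean(k_i)
    tHalf <- if (any(pos)) log(2) / mean(ks[pos]) else NA_real_
    data.frame(
        n = length(ks),
        mean_k = mean(ks),
        sd_k = if (length(ks) > 1) sd(ks) else NA_real_,
        t_half = tHalf,
        mean_d1_d0 = if (is.null(d1_d0)) NA_real_ else mean(d1_d0),
        sd_d1_d0 = if (is.null(d1_d0) || length(d1_d0) < 2) NA_real_
                   else sd(d1_d0))
}

#' Decay-experiment table: per-treatment kinetics from raw observations
#'
#' Consumes a long-format observation table (columns \code{setting},
#' \code{treatment}, \code{replicate}, \code{t}, \code{concentration}) and
#' returns one row per setting x treatment with the mean day-1/day-0 ratio,
#' mean decay constant and harmonic-mean half-life, computed per replicate
#' with the two-point estimator between \code{t = 0} and the last timepoint.
#'
#' @param obs data.frame of decay observations (see above); a path to a TSV
#'   file is also accepted.
#' @return data.frame, one row per (setting, treatment)
#' @export
decayTable <- function(obs) {
    if (is.character(obs)) obs <- read.delim(obs, stringsAsFactors = FALSE)
    need <- c("setting", "treatment", "replicate", "t", "concentration")
    miss <- setdiff(need, colnames(obs))
    if (length(miss))
        stop("decay table lacks column(s): ", paste(miss, collapse = ", "))
    groups <- unique(obs[, c("setting", "treatment")])
    out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
        g <- obs[obs$setting == groups$setting[i] &
                 obs$treatment == groups$treatment[i], ]
        fits <- vapply(split(g, g$replicate), function(r) {
            r <- r[order(r$t), ]
            if (r$t[1L] != 0) stop("replicate lacks a t = 0 observation")
            tEnd <- r$t[nrow(r)]
            c(k = fitK(r$concentration[1L], r$concentration[nrow(r)], tEnd),
              ratio = r$concentration[nrow(r)] / r$concentration[1L])
        }, numeric(2))
        s <- summariseReplicates(fits["k", ], d1_d0 = fits["ratio", ])
        cbind(groups[i, , drop = FALSE], s, row.names = NULL)
    }))
    rownames(out) <- NULL
    out
}

#' Small quantitative helpers for spike-in and abundance bookkeeping
#'
#' \code{recoveryEfficiency}: percent of expected spike-in copies recovered.
#' \code{linearityCheck}: slope, intercept and \eqn{r^2} of the ordinary
#' least-squares regression of \eqn{\log_{10}} observed on \eqn{\log_{10}}
#' expected concentration, used to verify quantitative linearity of an
#' extraction protocol over its dynamic range. \code{cfCaRatio}: ratio of
#' cell-free to cell-associated absolute rRNA abundance. \code{ddpcrCopies}:
#' Poisson-corrected copies mL\eqn{^{-1}} from droplet-digital PCR counts,
#' \eqn{\lambda = -\ln(1 - p/n)} copies per droplet.
#'
#' @param measured,expected copy numbers (same units); \code{expected > 0}
#' @param observed observed concentrations for the linearity fit
#' @param cf,ca cell-free and cell-associated abundances (copies mL^-1)
#' @param positive,total positive and total droplet counts
#' @param dropletVolume droplet volume in mL
#' @param dilution dilution factor applied to the template
#' @return \code{recoveryEfficiency}: percent. \code{linearityCheck}: list
#'   with \code{slope}, \code{intercept}, \code{r_squared}, \code{p}, \code{n}.
#'   \code{cfCaRatio}, \code{ddpcrCopies}: numeric.
#' @examples
#' recoveryEfficiency(831, 1000)           # 83.1 %
#' cfCaRatio(2.20e5, 3.83e7)               # ~0.006
#' ddpcrCopies(5000, 20000, 0.85e-6, 100)
#' @name decay-helpers
NULL

#' @rdname decay-helpers
#' @export
recoveryEfficiency <- function(measured, expected) {
    if (any(expected <= 0)) stop("'expected' must be > 0")
    100 * measured / expected
}

#' @rdname decay-helpers
#' @export
linearityCheck <- function(expected, observed) {
    stopifnot(length(expected) == length(observed))
    if (length(expected) < 3) stop("need >= 3 points")
    if (any(expected <= 0) || any(observed <= 0))
        stop("values must be > 0 for log-log regression")
    fit <- lm(log10(observed) ~ log10(expected))
    sm <- summary(fit)
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r_squared = sm$r.squared, p = unname(sm$coefficients[2L, 4L]),
         n = length(expected))
}

#' @rdname decay-helpers
#' @export
cfCaRatio <- function(cf, ca) {
    if (any(ca <= 0)) stop("'ca' must be > 0")
    cf / ca
}

#' @rdname decay-helpers
#' @export
ddpcrCopies <- function(positive, total, dropletVolume, dilution = 1) {
    stopifnot(positive >= 0, total > 0, dropletVolume > 0)
    if (positive >= total) stop("saturated reaction: positive >= total")
    lambda <- -log(1 - positive / total)
    lambda / dropletVolume * dilution
}
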