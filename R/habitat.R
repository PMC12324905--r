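#' Kernel-density mode detection with an area threshold
#'
#' Finds the modes of a set of values (typically per-ASV EEI indices within
#' a lineage) from a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth, evaluated on a uniform grid spanning the data
#' range extended by three bandwidths. Local maxima on the grid define
#' candidate modes; each mode's mass is the integrated density over its
#' basin (the grid segment delimited by the flanking local minima). Modes
#' holding less than \code{minMass} of the total area are suppressed and
#' their mass merged into the adjacent basin with the larger mass, so the
#' reported masses always sum to 1.
#'
#' @param values numeric vector (>= 5 finite values required)
#' @param minMass minimum fraction of the distribution area per reported
#'   mode (default 0.10)
#' @param gridPoints number of grid points (default 512)
#' @param bw bandwidth: a number, or \code{"nrd0"} (Silverman's rule,
#'   default)
#' @return object of class \code{ModeSet}: list with \code{modes} (data.frame
#'   \code{location}, \code{mass}, sorted by location), \code{bandwidth},
#'   \code{n_values}.
#' @examples
#' set.seed(1)
#' kdeModes(c(rnorm(100, -4), rnorm(100, 4)))  # two modes, ~0.5 mass each
#' @export
kdeModes <- function(values, minMass = 0.10, gridPoints = 512, bw = "nrd0") {
    values <- values[is.finite(values)]
    if (length(values) < 5) stop("need >= 5 finite values")
    if (var(values) == 0) {
        return(structure(list(
            modes = data.frame(location = values[1], mass = 1),
            bandwidth = 0, n_values = length(values)), class = "ModeSet"))
    }
    d <- density(values, bw = bw, n = gridPoints, cut = 3)
    y <- d$y
    n <- length(y)
    w <- y / sum(y)
    isMax <- c(y[1] > y[2],
               y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               y[n] > y[n - 1])
    peaks <- which(isMax)
    if (!length(peaks)) peaks <- which.max(y)
    # basin boundaries: the minimum of the valley between adjacent peaks
    bounds <- integer(0)
    if (length(peaks) > 1) {
        bounds <- vapply(seq_len(length(peaks) - 1), function(i) {
            seg <- peaks[i]:peaks[i + 1]
            seg[which.min(y[seg])]
        }, integer(1))
    }
    lo <- c(1L, bounds)
    hi <- c(bounds, n)
    basins <- data.frame(
        peak = peaks,
        location = d$x[peaks],
        mass = vapply(seq_along(peaks),
                      function(i) sum(w[lo[i]:hi[i]]), numeric(1)))
    # boundary grid points are shared between basins; renormalise
    basins$mass <- basins$mass / sum(basins$mass)
    while (nrow(basins) > 1 && min(basins$mass) < minMass) {
        i <- which.min(basins$mass)
        nb <- c(i - 1, i + 1)
        nb <- nb[nb >= 1 & nb <= nrow(basins)]
        j <- nb[which.max(basins$mass[nb])]
        basins$mass[j] <- basins$mass[j] + basins$mass[i]
        basins <- basins[-i, , drop = FALSE]
    }
    basins <- basins[order(basins$location), ]
    structure(list(
        modes = data.frame(location = basins$location, mass = basins$mass,
                           row.names = NULL),
        bandwidth = d$bw, n_values = length(values)), class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
    cat("ModeSet:", nrow(x$modes), "mode(s) from", x$n_values,
        "values (bw =", signif(x$bandwidth, 3), ")\n")
    print(x$modes)
    invisible(x)
}

#' Lineage-level multi-habitat classification from EEI modes
#'
#' For each lineage (taxonomy rank \code{rank}, default the subdivision
#' level \code{Lv4}), the density modes of its per-ASV epipelagic-enrichment
#' indices are computed with \code{\link{kdeModes}}. A mode located above 0
#' counts as an epipelagic mode, below 0 as a mesopelagic mode (a mode at
#' exactly 0 counts as neither); a lineage with at least one mode in each
#' depth category is a multi-habitat lineage. Lineages with fewer than
#' \code{minAsvs} ASVs are reported as \code{insufficient_data}.
#'
#' @param eeiByAsv named numeric vector of EEI values (names = ASV ids),
#'   already restricted to ASVs with computable indices
#' @param taxonomy taxonomy data.frame (\code{asv_id} + rank columns)
#' @param rank lineage rank column (default \code{"Lv4"})
#' @param minAsvs minimum ASVs per lineage (default 5)
#' @param minMass area threshold passed to \code{\link{kdeModes}}
#' @return data.frame: \code{lineage}, \code{n_asvs}, \code{n_modes},
#'   \code{mode_locations} (comma-separated), \code{multi_habitat}
#'   (logical, NA when insufficient), \code{status}
#' @export
classifyLineage <- function(eeiByAsv, taxonomy, rank = "Lv4", minAsvs = 5,
                            minMass = 0.10) {
    if (!rank %in% colnames(taxonomy)) stop("unknown rank: ", rank)
    lin <- taxonomy[[rank]][match(names(eeiByAsv), taxonomy$asv_id)]
    if (anyNA(lin)) stop("ASV(s) missing from taxonomy")
    out <- lapply(split(eeiByAsv, lin), function(v) {
        if (length(v) < minAsvs)
            return(data.frame(n_asvs = length(v), n_modes = NA_integer_,
                              mode_locations = NA_character_,
                              multi_habitat = NA,
                              status = "insufficient_data"))
        ms <- kdeModes(v, minMass = minMass)
        loc <- ms$modes$location
        data.frame(n_asvs = length(v), n_modes = nrow(ms$modes),
                   mode_locations = paste(signif(loc, 4), collapse = ","),
                   multi_habitat = any(loc > 0) && any(loc < 0),
                   status = "ok")
    })
    res <- do.call(rbind, out)
    data.frame(lineage = names(out), res, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Per-ASV habitat class from EEI differential-abundance calls
#'
#' Maps each ASV's EEI call to a habitat class: significantly
#' epipelagic-enriched (\code{up}) ASVs are \code{EPI}, significantly
#' mesopelagic-enriched (\code{down}) are \code{MES}, and non-significant
#' ASVs are \code{BOTH} (ubiquitous across depths).
#'
#' @param eeiResults \linkS4class{ContrastResults} from the EEI contrast
#' @return data.frame with \code{asv_id} and \code{habitat}
#'   (\code{EPI}/\code{MES}/\code{BOTH})
#' @export
assignAsvHabitat <- function(eeiResults) {
    stopifnot(all(c("asv_id", "call") %in% colnames(eeiResults)))
    habitat <- c(up = "EPI", down = "MES", ns = "BOTH")[
        as.character(eeiResults$call)]
    data.frame(asv_id = eeiResults$asv_id,
               habitat = factor(habitat, levels = c("EPI", "MES", "BOTH")),
               stringsAsFactors = FALSE)
}
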