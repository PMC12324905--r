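#' Synthetic paired-fraction community generator
#'
#' Generates paired cell-associated (ca) / cell-free (cf) ASV count tables
#' with known lysis and habitat ground truth, emulating a station x depth
#' survey design: \code{n_stations} stations, each sampled at the sublayers
#' of \code{depth_layout} (surface, subsurface chlorophyll maximum, and a
#' mesopelagic depth), in both rRNA fractions.
#'
#' The generative model: each ASV receives a lognormal baseline relative
#' abundance, a habitat class (\code{EPI}/\code{MES}/\code{BOTH}) and a
#' lineage from a fixed PR2-like catalogue. The expected ca composition of a
#' layer multiplies baselines by \code{2^depth_effect_log2} for ASVs whose
#' habitat matches the layer (\code{BOTH} ASVs get no depth effect) and
#' renormalises. The expected cf composition reweights the ca composition by
#' per-ASV lysis multipliers (\code{2^lysis_log2fc} for ASVs designated lysed
#' in that layer, 1 otherwise) and renormalises. Counts are drawn
#' NB(mean = composition x library size, dispersion \code{phi}); \code{phi =
#' 0} gives Poisson sampling. Lysed ASVs are drawn among ASVs whose baseline
#' relative abundance exceeds \code{lysis_min_baseline} (a spike below the
#' detection floor of the library would be unobservable by construction), and
#' by default from the habitat classes observed to dominate each lysis depth
#' in field data (epipelagic lysed from \code{BOTH}-habitat, mesopelagic
#' lysed from \code{EPI}-habitat ASVs); set \code{lysis_source_habitat} to
#' \code{NULL} entries for unbiased designation.
#'
#' @param n_asvs number of ASVs
#' @param n_stations number of stations
#' @param depth_layout named numeric vector of sublayer depths (m); names are
#'   sublayer labels and must be a subset of surface/SCM/mesopelagic
#' @param library_size expected reads per ca sample before rarefaction
#' @param rarefy_depth target rarefaction depth (reads)
#' @param habitat_mix named proportions of EPI, MES, BOTH ASVs (sum 1)
#' @param depth_effect_log2 log2 ca-abundance boost in the matching layer
#' @param lysis_fraction_per_depth named proportions (epipelagic,
#'   mesopelagic) of ASVs designated lysed in each layer
#' @param lysis_log2fc cf-enrichment effect (log2) for lysed ASVs
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2)
#' @param base_abundance_logsd sdlog of the lognormal baseline
#' @param cf_lib_ratio cf:ca expected library-size ratio before rarefaction
#' @param lysis_min_baseline baseline relative-abundance floor for lysed-ASV
#'   designation
#' @param lysis_source_habitat named character (epipelagic, mesopelagic):
#'   habitat class lysed ASVs are drawn from, or \code{NA} for any
#' @param seed integer RNG seed (all generator draws are functions of it)
#' @return \code{simConfig}: a validated \code{SimConfig} list.
#' @examples
#' cfg <- simConfig(n_asvs = 200, seed = 1)
#' truth <- simulateTruth(cfg)
#' mors <- simulateCounts(truth, cfg)
#' mors
#' @export
simConfig <- function(n_asvs = 1500,
                      n_stations = 5,
                      depth_layout = c(surface = 10, SCM = 50,
                                       mesopelagic = 300),
                      library_size = 60000,
                      rarefy_depth = 25878,
                      habitat_mix = c(EPI = 0.25, MES = 0.15, BOTH = 0.60),
                      depth_effect_log2 = 4,
                      lysis_fraction_per_depth = c(epipelagic = 0.03,
                                                   mesopelagic = 0.05),
                      lysis_log2fc = 3,
                      dispersion = 0.1,
                      base_abundance_logsd = 1.5,
                      cf_lib_ratio = 1,
                      lysis_min_baseline = 5e-4,
                      lysis_source_habitat = c(epipelagic = "BOTH",
                                               mesopelagic = "EPI"),
                      seed = 1) {
    cfg <- list(n_asvs = as.integer(n_asvs), n_stations = as.integer(n_stations),
                depth_layout = depth_layout, library_size = library_size,
                rarefy_depth = rarefy_depth, habitat_mix = habitat_mix,
                depth_effect_log2 = depth_effect_log2,
                lysis_fraction_per_depth = lysis_fraction_per_depth,
                lysis_log2fc = lysis_log2fc, dispersion = dispersion,
                base_abundance_logsd = base_abundance_logsd,
                cf_lib_ratio = cf_lib_ratio,
                lysis_min_baseline = lysis_min_baseline,
                lysis_source_habitat = lysis_source_habitat,
                seed = as.integer(seed))
    if (cfg$n_asvs < 1) stop("n_asvs must be >= 1")
    if (abs(sum(cfg$habitat_mix) - 1) > 1e-9)
        stop("habitat_mix must sum to 1")
    if (any(cfg$habitat_mix < 0) || any(cfg$habitat_mix > 1))
        stop("habitat_mix proportions must lie in [0, 1]")
    if (!identical(sort(names(cfg$habitat_mix)),
                   sort(c("EPI", "MES", "BOTH"))))
        stop("habitat_mix must be named EPI, MES, BOTH")
    if (any(cfg$lysis_fraction_per_depth < 0) ||
        any(cfg$lysis_fraction_per_depth > 1))
        stop("lysis fractions must lie in [0, 1]")
    if (cfg$dispersion < 0) stop("dispersion must be >= 0")
    if (cfg$library_size < cfg$rarefy_depth)
        stop("library_size must be >= rarefy_depth")
    if (!all(names(cfg$depth_layout) %in% .SUBLAYERS))
        stop("depth_layout names must be among: ",
             paste(.SUBLAYERS, collapse = ", "))
    class(cfg) <- "SimConfig"
    cfg
}

# TMM assumes the majority of features are non-differential between the
# compared conditions; the default habitat_mix therefore makes the
# depth-indifferent (BOTH) class the majority, so the trimmed mean of the
# depth contrast sits on non-differential ASVs.

# fixed PR2-like lineage catalogue (Lv4 subdivision / Lv5 class)
.LINEAGE_CATALOGUE <- data.frame(
    Lv4 = c("Ciliophora", "Ciliophora", "Dinoflagellata", "Dinoflagellata",
            "Haptophyta_X", "Gyrista", "Gyrista", "Chlorophyta_X",
            "Radiolaria", "Choanoflagellata", "Cryptophyta_X"),
    Lv5 = c("Spirotrichea", "Oligohymenophorea", "Dinophyceae", "Syndiniales",
            "Prymnesiophyceae", "Bacillariophyceae", "Chrysophyceae",
            "Mamiellophyceae", "Acantharea", "Choanoflagellatea",
            "Cryptophyceae"),
    stringsAsFactors = FALSE)

#' Lineage catalogue used by the generator
#'
#' The fixed subdivision (Lv4) / class (Lv5) pairs the generator samples
#' lineage labels from, so class-level aggregation is testable.
#' @return data.frame with columns \code{Lv4}, \code{Lv5}
#' @export
lineageCatalogue <- function() .LINEAGE_CATALOGUE

#' @rdname simConfig
#' @param config a \code{SimConfig} from \code{\link{simConfig}}
#' @return \code{simulateTruth}: a \code{SimTruth} data.frame, one row per
#'   ASV, with the habitat class, baseline relative abundance, lineage
#'   labels, per-layer lysis multipliers and per-layer expected ca/cf
#'   compositions (columns \code{ca_comp_*}, \code{cf_comp_*}; each sums
#'   to 1). The config is attached as \code{attr(, "config")}.
#' @export
simulateTruth <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    n <- config$n_asvs
    ids <- sprintf("asv%04d", seq_len(n))
    habitat <- sample(names(config$habitat_mix), n, replace = TRUE,
                      prob = config$habitat_mix)
    base <- rlnorm(n, 0, config$base_abundance_logsd)
    base <- base / sum(base)
    lin <- .LINEAGE_CATALOGUE[sample.int(nrow(.LINEAGE_CATALOGUE), n,
                                         replace = TRUE), ]
    mult <- sapply(.LAYERS, function(layer) {
        frac <- config$lysis_fraction_per_depth[[layer]]
        nLysed <- round(frac * n)
        m <- rep(1, n)
        if (nLysed > 0) {
            elig <- which(base >= config$lysis_min_baseline)
            src <- config$lysis_source_habitat[[layer]]
            if (!is.null(src) && !is.na(src))
                elig <- elig[habitat[elig] == src]
            if (length(elig) < nLysed) {
                warning("layer ", layer, ": only ", length(elig),
                        " eligible ASVs for ", nLysed, " lysis slots")
                nLysed <- length(elig)
            }
            lysed <- if (length(elig)) sample(elig, nLysed) else integer()
            m[lysed] <- 2^config$lysis_log2fc
        }
        m
    })
    comp <- lapply(.LAYERS, function(layer) {
        boost <- ifelse((habitat == "EPI" & layer == "epipelagic") |
                        (habitat == "MES" & layer == "mesopelagic"),
                        2^config$depth_effect_log2, 1)
        ca <- base * boost
        ca <- ca / sum(ca)
        cf <- ca * mult[, layer]
        cf <- cf / sum(cf)
        list(ca = ca, cf = cf)
    })
    names(comp) <- .LAYERS
    truth <- data.frame(
        asv_id = ids, habitat = habitat, baseline = base,
        Lv4 = lin$Lv4, Lv5 = lin$Lv5,
        lysis_mult_epipelagic = mult[, "epipelagic"],
        lysis_mult_mesopelagic = mult[, "mesopelagic"],
        ca_comp_epipelagic = comp$epipelagic$ca,
        cf_comp_epipelagic = comp$epipelagic$cf,
        ca_comp_mesopelagic = comp$mesopelagic$ca,
        cf_comp_mesopelagic = comp$mesopelagic$cf,
        stringsAsFactors = FALSE)
    attr(truth, "config") <- config
    class(truth) <- c("SimTruth", "data.frame")
    truth
}

#' @rdname simConfig
#' @param truth a \code{SimTruth} from \code{\link{simulateTruth}}
#' @return \code{simulateCounts}: a \linkS4class{MorsExperiment} with one ca
#'   and one cf sample per station x sublayer.
#' @export
simulateCounts <- function(truth, config = attr(truth, "config")) {
    stopifnot(inherits(truth, "SimTruth"), inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    n <- nrow(truth)
    samples <- expand.grid(
        fraction = .FRACTIONS, sublayer = names(config$depth_layout),
        station = seq_len(config$n_stations),
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples$depth_m <- config$depth_layout[samples$sublayer]
    samples$layer <- ifelse(samples$sublayer == "mesopelagic",
                            "mesopelagic", "epipelagic")
    samples$station <- sprintf("st%02d", samples$station)
    samples$sample_id <- sprintf("%s_%s_%s", samples$station,
                                 samples$sublayer,
                                 ifelse(samples$fraction == "cell_free",
                                        "cf", "ca"))
    phi <- config$dispersion
    cnt <- vapply(seq_len(nrow(samples)), function(i) {
        layer <- samples$layer[i]
        comp <- if (samples$fraction[i] == "cell_free")
            truth[[paste0("cf_comp_", layer)]]
        else truth[[paste0("ca_comp_", layer)]]
        lib <- config$library_size *
            if (samples$fraction[i] == "cell_free") config$cf_lib_ratio else 1
        mu <- comp * lib
        if (phi <= 0) as.integer(stats::rpois(n, mu))
        else as.integer(rnbinom(n, size = 1 / phi, mu = mu))
    }, integer(n))
    dimnames(cnt) <- list(truth$asv_id, samples$sample_id)
    tax <- data.frame(asv_id = truth$asv_id, Lv1 = "Eukaryota",
                      Lv2 = "Eukaryota_X", Lv3 = "Eukaryota_XX",
                      Lv4 = truth$Lv4, Lv5 = truth$Lv5, protist = TRUE,
                      stringsAsFactors = FALSE)
    MorsExperiment(cnt, samples[, c("sample_id", "station", "depth_m",
                                    "sublayer", "layer", "fraction")], tax)
}

#' @rdname simConfig
#' @return \code{simulateMorsExperiment}: list with elements \code{mors}
#'   (the \linkS4class{MorsExperiment}) and \code{truth}.
#' @export
simulateMorsExperiment <- function(config = simConfig()) {
    truth <- simulateTruth(config)
    list(mors = simulateCounts(truth, config), truth = truth)
}

#' Simulate a first-order decay time series
#'
#' Concentrations \eqn{C_0 e^{-kt}} with multiplicative lognormal noise of a
#' given coefficient of variation (unit mean); \code{noise_cv = 0} returns
#' the exact curve.
#'
#' @param c0 initial concentration (> 0)
#' @param k decay rate constant, h^-1 (>= 0)
#' @param times observation times, hours (>= 0)
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed optional RNG seed
#' @return data.frame with columns \code{t}, \code{concentration}
#' @examples
#' simulateDecaySeries(1, 0.121, c(0, 24))
#' @export
simulateDecaySeries <- function(c0, k, times, noise_cv = 0, seed = NULL) {
    if (c0 <= 0) stop("'c0' must be > 0")
    if (k < 0) stop("'k' must be >= 0")
    if (any(times < 0)) stop("'times' must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    conc <- c0 * exp(-k * times)
    if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        conc <- conc * rlnorm(length(times), -sdlog^2 / 2, sdlog)
    }
    data.frame(t = times, concentration = conc)
}
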