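test_that("simConfig validates proportions and sizes", {
    expect_error(simConfig(habitat_mix = c(EPI = 0.6, MES = 0.3, BOTH = 0.3)),
                 "sum to 1")
    expect_error(simConfig(library_size = 1000, rarefy_depth = 25878),
                 "rarefy_depth")
    expect_error(simConfig(dispersion = -1), "dispersion")
    expect_error(simConfig(n_asvs = 0), "n_asvs")
})

test_that("simulateTruth respects lysis and habitat settings and the seed", {
    cfg0 <- simConfig(n_asvs = 100, seed = 5,
                      lysis_fraction_per_depth = c(epipelagic = 0,
                                                   mesopelagic = 0))
    tr0 <- simulateTruth(cfg0)
    expect_true(all(tr0$lysis_mult_epipelagic == 1))
    expect_true(all(tr0$lysis_mult_mesopelagic == 1))
    # determinism
    expect_identical(simulateTruth(cfg0), tr0)
    # degenerate mixture
    cfgE <- simConfig(n_asvs = 50, seed = 5,
                      habitat_mix = c(EPI = 1, MES = 0, BOTH = 0),
                      lysis_source_habitat = c(epipelagic = "EPI",
                                               mesopelagic = "EPI"))
    expect_true(all(simulateTruth(cfgE)$habitat == "EPI"))
    # expected compositions sum to 1 per layer, lineages from the catalogue
    expect_equal(sum(tr0$ca_comp_epipelagic), 1)
    expect_equal(sum(tr0$cf_comp_mesopelagic), 1)
    expect_true(all(tr0$Lv4 %in% lineageCatalogue()$Lv4))
})

test_that("lysed ASVs are designated at the configured rate and magnitude", {
    cfg <- simConfig(n_asvs = 1000, seed = 2, lysis_log2fc = 3)
    tr <- simulateTruth(cfg)
    expect_identical(sum(tr$lysis_mult_mesopelagic > 1), 50L)  # 0.05 x 1000
    expect_identical(sum(tr$lysis_mult_epipelagic > 1), 30L)   # 0.03 x 1000
    expect_true(all(tr$lysis_mult_mesopelagic %in% c(1, 8)))
    # default source habitats
    expect_true(all(tr$habitat[tr$lysis_mult_mesopelagic > 1] == "EPI"))
    expect_true(all(tr$habitat[tr$lysis_mult_epipelagic > 1] == "BOTH"))
})

test_that("simulateCounts is deterministic and matches the study layout", {
    sim <- smallSim(seed = 21, n_asvs = 120)
    sim2 <- smallSim(seed = 21, n_asvs = 120)
    expect_identical(counts(sim$mors), counts(sim2$mors))
    si <- sampleInfo(sim$mors)
    expect_identical(nrow(si), 30L)   # 5 stations x 3 sublayers x 2 fractions
    expect_identical(sum(si$fraction == "cell_free"), 15L)
    expect_identical(sum(si$layer == "mesopelagic"), 10L)
})

test_that("without lysis, cf composition tracks ca composition", {
    cfg <- simConfig(n_asvs = 100, n_stations = 2, library_size = 4e7,
                     rarefy_depth = 25878, dispersion = 0,
                     lysis_fraction_per_depth = c(epipelagic = 0,
                                                  mesopelagic = 0),
                     seed = 8)
    sim <- simulateMorsExperiment(cfg)
    m <- relativeAbundance(sim$mors)
    si <- sampleInfo(sim$mors)
    epiCa <- rowMeans(m[, si$layer == "epipelagic" &
                          si$fraction == "cell_associated"])
    epiCf <- rowMeans(m[, si$layer == "epipelagic" &
                          si$fraction == "cell_free"])
    ab <- epiCa > 0.001
    expect_true(all(abs(epiCf[ab] / epiCa[ab] - 1) < 0.01))
})

test_that("estimated cf/ca log-ratio of lysed ASVs matches the expectation", {
    cfg <- simConfig(n_asvs = 1000, n_stations = 5, library_size = 2e5,
                     rarefy_depth = 25878, dispersion = 0.05,
                     lysis_log2fc = 3, seed = 31)
    sim <- simulateMorsExperiment(cfg)
    tr <- sim$truth
    lysed <- tr$lysis_mult_mesopelagic > 1
    # oracle: exact expected compositions from the truth table
    oracle <- mean(log2(tr$cf_comp_mesopelagic[lysed] /
                        tr$ca_comp_mesopelagic[lysed]))
    m <- relativeAbundance(sim$mors)
    si <- sampleInfo(sim$mors)
    ca <- rowMeans(m[, si$layer == "mesopelagic" &
                       si$fraction == "cell_associated"])
    cf <- rowMeans(m[, si$layer == "mesopelagic" &
                       si$fraction == "cell_free"])
    est <- mean(log2(cf[lysed] / ca[lysed]))
    expect_lt(abs(est - oracle), 0.3)
    # and the oracle itself is the nominal effect minus the compositional
    # renormalisation offset
    expect_equal(oracle, 3 + mean(log2(
        sum(tr$ca_comp_mesopelagic * tr$lysis_mult_mesopelagic)^-1)),
        tolerance = 1e-10)
})

test_that("simulateDecaySeries follows the first-order curve", {
    s <- simulateDecaySeries(1, 0.121, c(0, 24), noise_cv = 0)
    expect_equal(s$concentration[2], exp(-0.121 * 24), tolerance = 1e-12)
    expect_equal(round(s$concentration[2], 4), 0.0548)
    # k = 0: constant
    s0 <- simulateDecaySeries(2, 0, c(0, 5, 10), noise_cv = 0)
    expect_true(all(s0$concentration == 2))
    # half-life identity
    k <- 0.2
    sh <- simulateDecaySeries(1, k, log(2) / k, noise_cv = 0)
    expect_equal(sh$concentration, 0.5, tolerance = 1e-12)
    expect_error(simulateDecaySeries(1, -0.1, 1), "k")
    # reproducible noise
    a <- simulateDecaySeries(1, 0.1, 0:5, noise_cv = 0.2, seed = 4)
    b <- simulateDecaySeries(1, 0.1, 0:5, noise_cv = 0.2, seed = 4)
    expect_identical(a, b)
})
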