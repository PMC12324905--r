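# shared fixtures, built in code

# tiny valid MorsExperiment: 3 ASVs x 4 samples (ca/cf at two depths)
toyMors <- function() {
    cnt <- matrix(c(10L, 5L, 0L,
                    8L, 6L, 1L,
                    2L, 0L, 12L,
                    3L, 1L, 9L), nrow = 3,
                  dimnames = list(paste0("asv", 1:3),
                                  c("s_epi_ca", "s_epi_cf",
                                    "s_mes_ca", "s_mes_cf")))
    si <- data.frame(
        sample_id = colnames(cnt),
        station = "st01",
        depth_m = c(10, 10, 300, 300),
        sublayer = c("surface", "surface", "mesopelagic", "mesopelagic"),
        layer = c("epipelagic", "epipelagic", "mesopelagic", "mesopelagic"),
        fraction = c("cell_associated", "cell_free",
                     "cell_associated", "cell_free"))
    tx <- data.frame(asv_id = rownames(cnt),
                     Lv4 = c("Ciliophora", "Haptophyta_X", "Radiolaria"),
                     Lv5 = c("Spirotrichea", "Prymnesiophyceae", "Acantharea"),
                     protist = TRUE)
    MorsExperiment(cnt, si, tx)
}

# small simulated experiment for pipeline tests
smallSim <- function(seed = 11, n_asvs = 300, ...) {
    simulateMorsExperiment(simConfig(n_asvs = n_asvs, seed = seed, ...))
}

quietRarefy <- function(x, depth = 25878, seed = 1) {
    suppressMessages(rarefy(x, depth = depth, seed = seed))
}
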