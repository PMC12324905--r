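test_that("zeroValueFilter keeps only ASVs with both computable measures", {
    cli <- S4Vectors::DataFrame(
        asv_id = c("a", "b", "c"), logFC = c(3, 1, 2), FDR = c(.01, .5, .02),
        call = factor(c("up", "ns", "up"), c("up", "down", "ns")),
        allZeroGroup = c(FALSE, FALSE, TRUE))
    eei <- S4Vectors::DataFrame(
        asv_id = c("a", "c", "d"), logFC = c(2.5, 1, 0), FDR = c(.01, .2, .9),
        call = factor(c("up", "ns", "ns"), c("up", "down", "ns")),
        allZeroGroup = c(FALSE, FALSE, FALSE))
    j <- zeroValueFilter(cli, eei)
    expect_identical(j$asv_id, "a")      # b absent from eei, c all-zero
    expect_equal(j$cli_logFC, 3)
    expect_equal(j$eei_logFC, 2.5)
    expect_warning(
        zeroValueFilter(cli[0, ], eei), "no ASVs shared")
})

test_that("DA intersection percentages reproduce printed-count arithmetic", {
    cli <- data.frame(asv_id = paste0("x", 1:171), call = "up")
    eei <- data.frame(asv_id = paste0("x", c(1:147, 1000:1289)),
                      call = "up")
    out <- intersectDA(cli, eei)
    expect_identical(out$n_shared, 147L)
    expect_equal(out$pct_of_cli_mes, 86.0)
    expect_equal(out$pct_of_eei, 33.6)
    # disjoint sets
    d <- intersectDA(data.frame(asv_id = "a", call = "up"),
                     data.frame(asv_id = "b", call = "up"))
    expect_identical(d$n_shared, 0L)
    expect_equal(d$pct_of_cli_mes, 0)
    # empty DA set gives NA percentages
    e <- intersectDA(data.frame(asv_id = character(), call = character()),
                     data.frame(asv_id = "b", call = "up"))
    expect_true(is.na(e$pct_of_cli_mes))
})

test_that("sankey counts conserve the joined ASV set with marginals", {
    hab <- data.frame(asv_id = paste0("a", 1:10),
                      habitat = factor(rep("BOTH", 10),
                                       c("EPI", "MES", "BOTH")))
    cliE <- data.frame(asv_id = paste0("a", 1:10), call = "up")
    cliM <- data.frame(asv_id = paste0("a", 1:10), call = "ns")
    sk <- sankeyCounts(hab, cliE, cliM)
    expect_equal(unname(sk["BOTH", "lysed_EPI"]), 10)
    expect_equal(unname(sk["Sum", "Sum"]), 10)
    # random toy: total equals number of joined ASVs
    set.seed(8)
    n <- 40
    hab2 <- data.frame(asv_id = paste0("b", 1:n),
                       habitat = factor(sample(c("EPI", "MES", "BOTH"), n,
                                               TRUE),
                                        c("EPI", "MES", "BOTH")))
    cliE2 <- data.frame(asv_id = paste0("b", 1:n),
                        call = sample(c("up", "ns"), n, TRUE))
    cliM2 <- data.frame(asv_id = paste0("b", 1:n),
                        call = sample(c("up", "down", "ns"), n, TRUE))
    sk2 <- sankeyCounts(hab2, cliE2, cliM2)
    expect_equal(unname(sk2["Sum", "Sum"]), n)
    # lysis marginals equal the DA counts within the joined set
    expect_equal(unname(sum(sk2[1:3, c("lysed_EPI", "lysed_both")])),
                 sum(cliE2$call == "up"))
})

test_that("spearmanCorr matches rank-based oracles", {
    # monotone transform: rho 1; reversal negates
    x <- c(0.3, 1.2, 2.5, 3.1, 7)
    expect_equal(spearmanCorr(x, exp(x))$rho, 1)
    expect_equal(spearmanCorr(rev(x), exp(x))$rho, -1)
    # tied case frozen from the mid-rank Pearson oracle
    s <- spearmanCorr(1:5, c(5, 6, 7, 8, 7))
    expect_equal(s$rho, 8 / sqrt(95), tolerance = 1e-10)
    expect_equal(s$rho, 0.8207827, tolerance = 1e-6)
    # untied data: closed form 1 - 6*sum(d^2)/(n(n^2-1))
    set.seed(10)
    a <- sample(100, 20); b <- sample(100, 20)
    d <- rank(a) - rank(b)
    expect_equal(spearmanCorr(a, b)$rho,
                 1 - 6 * sum(d^2) / (20 * (20^2 - 1)))
    # agreement with the established implementation
    ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
    expect_equal(spearmanCorr(a, b)$rho, unname(ct$estimate))
    expect_true(is.na(spearmanCorr(rep(1, 5), 1:5)$rho))
})

test_that("wilcoxonRankSum exact enumeration and symmetry", {
    w <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_identical(w$method, "exact")
    expect_equal(w$p, 0.1)       # 2 of the 20 orderings are as extreme
    # identical multisets: p = 1 under midranks
    expect_equal(wilcoxonRankSum(c(1, 2, 2), c(2, 1, 2))$p, 1)
    # label swap leaves p unchanged
    set.seed(11)
    a <- rnorm(6); b <- rnorm(5, 1)
    expect_equal(wilcoxonRankSum(a, b)$p, wilcoxonRankSum(b, a)$p)
    # large-sample path agrees with the established implementation
    set.seed(12)
    a2 <- rnorm(20); b2 <- rnorm(25, 0.7)
    w2 <- wilcoxonRankSum(a2, b2)
    expect_identical(w2$method, "normal")
    ref <- wilcox.test(a2, b2, exact = FALSE, correct = TRUE)
    expect_equal(w2$p, ref$p.value, tolerance = 1e-10)
    expect_equal(w2$U, unname(ref$statistic))
    expect_error(wilcoxonRankSum(numeric(), 1:3), "nonempty")
})

test_that("habitat read fractions sum to one per sample category", {
    x <- toyMors()
    hab <- data.frame(asv_id = paste0("asv", 1:3),
                      habitat = factor(c("EPI", "EPI", "MES"),
                                       c("EPI", "MES", "BOTH")))
    rf <- habitatReadFractions(x, hab)
    sums <- tapply(rf$read_fraction,
                   paste(rf$layer, rf$fraction), sum)
    expect_equal(as.numeric(sums), rep(1, 4))
    # single-class input: fraction 1 for that class
    hab1 <- data.frame(asv_id = paste0("asv", 1:3),
                       habitat = factor(rep("BOTH", 3),
                                        c("EPI", "MES", "BOTH")))
    rf1 <- habitatReadFractions(x, hab1)
    expect_true(all(rf1$read_fraction[rf1$habitat == "BOTH"] == 1))
    # 75/25 toy in one category
    epiCa <- rf[rf$layer == "epipelagic" &
                rf$fraction == "cell_associated", ]
    expect_equal(epiCa$read_fraction[epiCa$habitat == "EPI"], 15 / 15)
})
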