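test_that("TMM factors are 1 for identical and scaled columns", {
    set.seed(2)
    a <- rpois(50, 40) + 1L
    m <- cbind(s1 = a, s2 = a)
    rownames(m) <- paste0("g", 1:50)
    nf <- tmmFactors(m)
    expect_equal(unname(nf$factors), c(1, 1))
    # column B = 2 x column A: library size absorbs the scaling
    m2 <- cbind(s1 = a, s2 = 2L * a)
    expect_equal(unname(tmmFactors(m2)$factors), c(1, 1))
    # near-invariance to scaling any single sample (the precision weights
    # depend weakly on absolute counts, as in the reference implementation)
    set.seed(5)
    m3 <- matrix(rnbinom(300, mu = 30, size = 5), 60, 5,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:5)))
    f3 <- tmmFactors(m3)$factors
    m3b <- m3; m3b[, 3] <- 7L * m3b[, 3]
    expect_equal(tmmFactors(m3b)$factors, f3, tolerance = 0.02)
})

test_that("TMM equals a direct enumeration of M/A values, trims, weights", {
    m <- matrix(c(100L, 20L, 35L, 4L, 60L, 10L,
                  180L, 18L, 70L, 30L, 62L, 8L), 6, 2,
                dimnames = list(paste0("g", 1:6), c("s1", "s2")))
    nf <- tmmFactors(m, refColumn = 1)
    # oracle: explicit sort-based double trimming against sample 1
    lo <- colSums(m)[2]; lr <- colSums(m)[1]
    o <- m[, 2]; r <- m[, 1]
    M <- log2((o / lo) / (r / lr))
    A <- 0.5 * log2((o / lo) * (r / lr))
    w <- 1 / ((lo - o) / (lo * o) + (lr - r) / (lr * r))
    n <- length(M)
    keepM <- order(M)[(floor(n * 0.3) + 1):(n - floor(n * 0.3))]
    keepA <- order(A)[(floor(n * 0.05) + 1):(n - floor(n * 0.05))]
    keep <- intersect(keepM, keepA)
    f2 <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
    expected <- c(1, f2) / exp(mean(log(c(1, f2))))
    expect_equal(unname(nf$factors), unname(expected), tolerance = 1e-12)
    expect_true(abs(mean(log(nf$factors))) < 1e-8)   # geometric mean 1
})

test_that("TMM agrees with the established reference implementation", {
    skip_if_not_installed("edgeR")
    set.seed(42)
    m <- matrix(rnbinom(200 * 8, mu = 50, size = 5), 200, 8,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
    m[sample(length(m), 300)] <- 0L
    nf <- tmmFactors(m)
    ref <- edgeR::calcNormFactors(edgeR::DGEList(m), method = "TMM")
    expect_equal(unname(nf$factors),
                 unname(ref$samples$norm.factors), tolerance = 1e-10)
})

test_that("a sample sharing no positive ASVs with the reference gets 1", {
    m <- matrix(c(5L, 8L, 0L, 0L,
                  6L, 7L, 0L, 0L,
                  0L, 0L, 9L, 4L), 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
    expect_warning(nf <- tmmFactors(m, refColumn = 1), "no positive ASVs")
    expect_true(all(is.finite(nf$factors)))
})

test_that("dispersion estimation recovers known truth", {
    des <- cbind(1, rep(0:1, each = 5))
    set.seed(14)
    # Poisson data: phi near zero
    mp <- matrix(rpois(200 * 10, 40), 200, 10,
                 dimnames = list(paste0("g", 1:200), NULL))
    expect_lte(estimateDispersionNB(mp, des)$common, 0.02)
    # NB data with phi = 0.2
    mn <- matrix(rnbinom(500 * 10, mu = 40, size = 5), 500, 10,
                 dimnames = list(paste0("g", 1:500), NULL))
    dn <- estimateDispersionNB(mn, des)
    expect_gte(dn$common, 0.15)
    expect_lte(dn$common, 0.25)
    # shrinkage limit: huge prior df pins tagwise at the common value
    dInf <- estimateDispersionNB(mn[1:50, ], des, priorDf = 1e8)
    expect_equal(unname(dInf$tagwise), rep(dInf$common, 50),
                 tolerance = 1e-6)
})

test_that("LRT statistic matches brute-force NB maximum likelihood", {
    # small two-group instances with fixed dispersion, equal offsets: the
    # oracle profiles each group mean by direct numeric optimisation
    cases <- list(list(a = c(2, 3, 4), b = c(9, 11, 10), phi = 0.1),
                  list(a = c(0, 1, 2), b = c(5, 3, 6), phi = 0.2),
                  list(a = c(7, 7, 7), b = c(7, 7, 7), phi = 0.1))
    for (cs in cases) {
        y <- matrix(c(cs$a, cs$b), 1, 6)
        res <- glmLRTest(y, cbind(1, rep(0:1, each = 3)), coef = 2,
                         dispersion = cs$phi, offset = rep(log(100), 6))
        nll <- function(mu, yy)
            -sum(dnbinom(yy, size = 1 / cs$phi, mu = mu, log = TRUE))
        bf <- function(yy) optimize(nll, c(1e-4, 100), yy = yy)$objective
        lrtBF <- 2 * (bf(c(cs$a, cs$b)) - (bf(cs$a) + bf(cs$b)))
        expect_equal(res$LRT, max(lrtBF, 0), tolerance = 1e-4)
    }
})

test_that("GLM logFC attains the closed-form limit and is antisymmetric", {
    y <- matrix(rep(c(1000, 16000), each = 4), 1, 8)
    des <- cbind(1, rep(0:1, each = 4))
    r <- glmLRTest(y, des, coef = 2, dispersion = 1e-6,
                   offset = rep(log(1e5), 8))
    expect_equal(r$logFC, 4, tolerance = 0.05)
    # swapping group labels negates logFC, leaves p unchanged
    r2 <- glmLRTest(y, cbind(1, rep(1:0, each = 4)), coef = 2,
                    dispersion = 1e-6, offset = rep(log(1e5), 8))
    expect_equal(r2$logFC, -r$logFC, tolerance = 1e-8)
    expect_equal(r2$PValue, r$PValue, tolerance = 1e-10)
})

test_that("null-mean input gives near-zero logFC and LRT", {
    y <- matrix(c(20, 20, 20, 20, 20, 20), 1, 6)
    r <- glmLRTest(y, cbind(1, rep(0:1, each = 3)), coef = 2,
                   dispersion = 0.1, offset = rep(log(100), 6))
    expect_lt(abs(r$logFC), 0.05)
    expect_lt(r$LRT, 0.1)
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(bhFdr(0.03), 0.03)
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
    p <- c(0.001, NA, 0.5)
    out <- bhFdr(p)
    expect_true(is.na(out[2]))
    expect_error(bhFdr(c(0.5, 1.2)), "outside")
    # monotone in sorted order
    set.seed(6)
    p2 <- runif(50)
    f <- bhFdr(p2)
    expect_true(all(diff(f[order(p2)]) >= -1e-12))
    expect_true(all(f >= p2))
})

test_that("DA calls use strict FDR and logFC thresholds", {
    res <- data.frame(logFC = c(2.5, 2.0, 5, -3, 1),
                      FDR = c(0.05, 0.05, 0.10, 0.01, 0.001))
    out <- callDA(res)
    expect_equal(as.character(out$call), c("up", "ns", "ns", "down", "ns"))
})

test_that("runContrast recovers simulated lysis and controls errors", {
    sim <- smallSim(seed = 11, n_asvs = 300)
    r <- quietRarefy(sim$mors)
    res <- runContrast(r, "CLI_MES")
    expect_s4_class(res, "ContrastResults")
    lysed <- sim$truth$asv_id[sim$truth$lysis_mult_mesopelagic > 1]
    up <- res$asv_id[res$call == "up"]
    expect_gte(mean(lysed %in% up), 0.8)
    # prevalence filter: tested ASVs appear in >= 4 selected samples
    si <- sampleInfo(r)
    mes <- counts(r)[, si$layer == "mesopelagic"]
    expect_true(all(rowSums(mes[res$asv_id, ] > 0) >= 4))
    # p-values invariant to ASV row order
    res2 <- runContrast(r[rev(seq_len(nrow(r))), ], "CLI_MES")
    expect_equal(res2[res$asv_id, "PValue"], res$PValue, tolerance = 1e-10)
})
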