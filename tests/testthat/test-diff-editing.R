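test_that("editing level is alt over alt+ref with NA for empty cells", {
    expect_identical(editingLevel(5, 95), 0.05)
    expect_identical(editingLevel(0, 50), 0)
    expect_identical(editingLevel(10, 0), 1)
    expect_warning(lv <- editingLevel(0, 0), "undefined")
    expect_true(is.na(lv))
})

test_that("beta-binomial log-likelihood matches closed forms", {
    # Beta(1,1) mixture is discrete uniform on 0..n
    expect_equal(bbLogLik(1, 1, 0, 1), log(1 / 2), tolerance = 1e-12)
    for (k in c(0, 3, 7, 10))
        expect_equal(bbLogLik(1, 1, k, 10), log(1 / 11),
                     tolerance = 1e-12)
    expect_error(bbLogLik(0, 1, 1, 2), "positive")
    expect_error(bbLogLik(1, 1, 3, 2), ">=")
})

test_that("MLE fit recovers simulated parameters and handles degeneracy", {
    set.seed(41)
    k <- rBetaBinom(200, 100, 0.2, 0.1)
    fit <- fitBetaBinomial(cbind(k, rep(100L, 200)))
    expect_true(fit@converged)
    expect_lt(abs(fit@mean - 0.2), 0.02)
    expect_equal(fit@mean, fit@alpha / (fit@alpha + fit@beta),
                 tolerance = 1e-12)
    # all-zero edited counts: boundary fit with near-zero mean
    f0 <- fitBetaBinomial(cbind(rep(0L, 10), rep(20L, 10)))
    expect_true(f0@boundary)
    expect_lte(f0@mean, 1 / 20)
    expect_error(fitBetaBinomial(cbind(0L, 0L)), "no observed cells")
})

test_that("LLR test: no signal on identical groups, power on strong ones", {
    cells <- cbind(c(5L, 8L, 3L, 6L), c(50L, 60L, 40L, 55L))
    r <- reditLlrTest(cells, cells)
    expect_lt(r$llr, 1e-6)
    expect_gt(r$pvalue, 0.999)
    set.seed(42)
    g1 <- cbind(rBetaBinom(50, 80, 0.05, 0.05), rep(80L, 50))
    g2 <- cbind(rBetaBinom(50, 80, 0.5, 0.05), rep(80L, 50))
    expect_lt(reditLlrTest(g1, g2)$pvalue, 1e-6)
    expect_error(reditLlrTest(cells[1, , drop = FALSE], cells), ">= 2")
})

test_that("LLR is invariant to sample order and to group swap", {
    set.seed(43)
    g1 <- cbind(rBetaBinom(10, 60, 0.2, 0.05), rep(60L, 10))
    g2 <- cbind(rBetaBinom(8, 60, 0.35, 0.05), rep(60L, 8))
    a <- reditLlrTest(g1, g2)
    b <- reditLlrTest(g1[sample(10), ], g2[sample(8), ])
    expect_equal(a$llr, b$llr, tolerance = 1e-8)
    sw <- reditLlrTest(g2, g1)
    expect_equal(sw$llr, a$llr, tolerance = 1e-8)
    # delta negates under the swap
    expect_equal(sw$fit_g1@mean - sw$fit_g2@mean,
                 -(a$fit_g1@mean - a$fit_g2@mean), tolerance = 1e-6)
})

test_that("BH wrapper agrees with the step-up definition", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_identical(bhFdr(numeric()), numeric())
    expect_equal(bhFdr(0.2), 0.2)
    set.seed(44)
    for (i in 1:20) {
        p <- runif(sample(1:40, 1))
        expect_equal(bhFdr(p), bhOracle(p), tolerance = 1e-12)
    }
    expect_error(bhFdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("fold change follows the pseudocount definition", {
    expect_equal(foldChange(0.4, 0.1), log2(0.4001 / 0.1001),
                 tolerance = 1e-12)
    expect_identical(foldChange(0.3, 0.3), 0)
    expect_identical(foldChange(0, 0), 0)
    expect_equal(foldChange(0.1 * 2^2.5, 0.1), 2.4988, tolerance = 1e-3)
    expect_equal(foldChange(0.2, 0.05, pseudo = 0), 2, tolerance = 1e-12)
})

test_that("DES selection applies the conjunction and direction rule", {
    set.seed(45)
    n <- 20
    res <- data.frame(pvalue = runif(n, 0, 0.2),
                      fdr = runif(n, 0, 0.3),
                      log2fc = runif(n, -4, 4))
    res$delta <- sign(res$log2fc) * abs(res$log2fc) / 10
    out <- selectDes(res)
    manual <- res$pvalue < 0.05 & res$fdr < 0.1 & abs(res$log2fc) >= 2.5
    expect_identical(out$is_des, manual)
    expect_identical(out$direction,
                     ifelse(res$delta > 0, "LOW_SENSITIVITY",
                            "HIGH_SENSITIVITY"))
    # ratio scale: |log2fc| >= log2(2.5)
    outR <- selectDes(res, fc_scale = "ratio")
    expect_identical(outR$is_des,
                     res$pvalue < 0.05 & res$fdr < 0.1 &
                         2^abs(res$log2fc) >= 2.5)
})

test_that("differential scan skips under-covered sites and adjusts FDR", {
    set.seed(46)
    alt <- matrix(rbinom(40, 50, 0.1), 4, 10)
    tot <- matrix(50L, 4, 10)
    alt[1, 3:10] <- NA; tot[1, 3:10] <- NA  # 2 cells in g1, 0 in g2
    ee <- makeEE(alt, tot)
    groups <- factor(rep(c("g1", "g2"), each = 5))
    res <- diffEditing(ee, groups)
    expect_identical(res$skipped[1],
                     "fewer than 2 observed cells in a group")
    expect_false(res$is_des[1])
    tested <- is.na(res$skipped)
    expect_equal(res$fdr[tested], bhOracle(res$pvalue[tested]),
                 tolerance = 1e-12)
})

test_that("AEI is the pooled ratio over Alu sites only", {
    alu <- GRanges("chr1", IRanges(1, 250))
    mcols(alu)$repeat_class <- "ALU"
    # sites at pos 100, 200 (inside), 300 (outside)
    ee <- makeEE(matrix(c(3L, 7L, 50L), 3, 1),
                 matrix(c(10L, 10L, 60L), 3, 1),
                 strand = c("+", "-", "+"))
    res <- computeAei(ee, alu)
    expect_equal(res$aei, 0.5)  # (3+7)/(10+10), not mean(0.3, 0.7)
    expect_identical(res$n_sites_used, 2L)
    expect_identical(res$total_reads_used, 20L)
    # single Alu cell: AEI equals the editing level
    ee1 <- makeEE(matrix(3L), matrix(10L))
    expect_equal(computeAei(ee1, alu)$aei, editingLevel(3, 7))
    # zero Alu reads flagged
    none <- GRanges("chr9", IRanges(1, 2))
    mcols(none)$repeat_class <- "ALU"
    expect_warning(res0 <- computeAei(ee, none), "undefined")
    expect_true(is.na(res0$aei))
})
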