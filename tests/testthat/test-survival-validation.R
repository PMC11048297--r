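test_that("hyper/hypo classification splits strictly above the mean", {
    expect_identical(classifyHyperHypo(c(0.1, 0.3)), c("HYPO", "HYPER"))
    # exactly at the mean stays HYPO
    expect_identical(classifyHyperHypo(c(0.1, 0.2, 0.3))[2], "HYPO")
    # missing stays missing and is excluded from the mean
    lab <- classifyHyperHypo(c(0.1, NA, 0.5))
    expect_true(is.na(lab[2]))
    expect_identical(lab[c(1, 3)], c("HYPO", "HYPER"))
    set.seed(61)
    lv <- runif(10)
    expect_identical(classifyHyperHypo(lv),
                     ifelse(lv > mean(lv), "HYPER", "HYPO"))
    # shift invariance
    expect_identical(classifyHyperHypo(lv + 100), classifyHyperHypo(lv))
    expect_warning(classifyHyperHypo(rep(0.2, 4)), "identical")
    expect_error(classifyHyperHypo(c(0.1, NA)), ">= 2")
})

test_that("Kaplan-Meier table matches closed forms and the oracle", {
    # all censored: survival stays 1
    km0 <- kmEstimate(c(2, 5, 9), c(0, 0, 0))
    expect_true(all(km0$survival == 1))
    # all events at distinct times: 2/3, 1/3, 0
    km1 <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
    expect_equal(km1$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
    # random cohorts match the enumeration oracle
    set.seed(62)
    for (i in 1:5) {
        t <- sample(1:15, 12, replace = TRUE)
        e <- rbinom(12, 1, 0.7)
        km <- kmEstimate(t, e)
        or <- kmOracle(t, e)
        expect_equal(km$time, or$time)
        expect_equal(km$survival, or$survival, tolerance = 1e-12)
        expect_equal(km$n_risk, or$n_risk)
        # survival is non-increasing, starts at/below 1
        expect_true(all(diff(km$survival) <= 1e-12))
        expect_true(all(km$survival >= 0 & km$survival <= 1))
    }
    # without censoring the last event-time estimate is empirical survival
    t <- c(3, 1, 4, 1, 5); e <- rep(1, 5)
    km <- kmEstimate(t, e)
    expect_equal(km$survival[km$time == 4], mean(t > 4), tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed micro-example and oracle", {
    # g1 events at 1,2; g2 events at 3,4 -> chi2 = 49/17
    lr <- logrankTest(rep(c("g1", "g2"), each = 2), c(1, 2, 3, 4),
                      rep(1, 4))
    expect_equal(lr$chi2, 49 / 17, tolerance = 1e-9)
    expect_equal(lr$pvalue, pchisq(49 / 17, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
    # identical groups give a null statistic
    same <- logrankTest(rep(c("a", "b"), 3), rep(c(1, 2, 3), each = 2),
                        rep(1, 6))
    expect_lt(same$chi2, 1e-9)
    # random cohorts agree with the direct O-E/V enumeration
    set.seed(63)
    for (i in 1:5) {
        lab <- rep(c("x", "y"), c(12, 13))
        t <- sample(1:30, 25, replace = TRUE)
        e <- rbinom(25, 1, 0.8)
        lr2 <- logrankTest(lab, t, e)
        expect_equal(lr2$chi2, logrankOracle(lab, t, e),
                     tolerance = 1e-9)
        # group-name swap leaves the statistic unchanged
        expect_equal(logrankTest(ifelse(lab == "x", "y", "x"),
                                 t, e)$chi2, lr2$chi2, tolerance = 1e-9)
    }
    expect_error(logrankTest(rep("a", 4), 1:4, rep(1, 4)), "two")
})

test_that("survival scan bookkeeping: per-site n, skips and KM output", {
    set.seed(64)
    lv <- simulatePatientLevels(setNames(c(0.3, 0.4, 0.5),
                                         c("sA", "sB", "sC")),
                                20, seed = 64)
    lv["sB", ] <- NA           # observed in no patient
    lv["sC", 1:18] <- NA       # observed in 2 < 4 patients
    surv <- simulateSurvival(rep(0.3, 20),
                             SurvSimConfig(n_patients = 20, seed = 65))
    scan <- siteSurvivalScan(lv, surv)
    expect_identical(scan$results$site, "sA")
    nObs <- sum(!is.na(lv["sA", ]))
    expect_identical(scan$results$n_hyper + scan$results$n_hypo, nObs)
    expect_identical(sort(scan$skipped$site), c("sB", "sC"))
    km <- scan$km[["sA"]]
    expect_identical(km$hyper$n_risk[1], scan$results$n_hyper)
    expect_true(all(diff(km$hypo$survival) <= 1e-12))
})

test_that("repeat-class annotation respects boundaries and precedence", {
    reps <- GRanges("chr1", IRanges(c(100, 150, 400), c(200, 300, 500)))
    mcols(reps)$repeat_class <- c("ALU", "NON_ALU_REPEAT",
                                  "NON_ALU_REPEAT")
    sites <- data.frame(chrom = "chr1",
                        pos = c(100, 99, 250, 450, 600))
    cls <- annotateRepeatClass(sites, reps)
    expect_identical(cls, c("ALU",            # first covered base
                            "NON_REPETITIVE", # one before the interval
                            "NON_ALU_REPEAT", "NON_ALU_REPEAT",
                            "NON_REPETITIVE"))
    # Alu wins where classes overlap
    overlap <- data.frame(chrom = "chr1", pos = 180)
    expect_identical(annotateRepeatClass(overlap, reps), "ALU")
    # BED convention end-to-end: "chr1 99 200 ALU" covers 100..200 only
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines("chr1\t99\t200\tALU", f)
    bed <- readBedRepeats(f)
    cls2 <- annotateRepeatClass(
        data.frame(chrom = "chr1", pos = c(99, 100, 200, 201)), bed)
    expect_identical(cls2, c("NON_REPETITIVE", "ALU", "ALU",
                             "NON_REPETITIVE"))
})
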