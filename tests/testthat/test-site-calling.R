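test_that("calling thresholds act on edited reads and allele frequency", {
    obs <- rbind(obsRow("s1", "chr1", 100L, "+", 95L, 5L),   # AF 0.05
                 obsRow("s1", "chr1", 200L, "+", 4L, 4L),    # AF 0.5
                 obsRow("s1", "chr1", 300L, "+", 200L, 6L))  # AF ~0.029
    called <- callCandidateSites(obs)
    expect_identical(called$called, c(TRUE, FALSE, FALSE))
    # thresholds configurable
    expect_identical(callCandidateSites(obs, 4, 0.02)$called,
                     c(TRUE, TRUE, TRUE))
})

test_that("zero-total observed cells demote to NO_COVERAGE with warning", {
    obs <- rbind(obsRow("s1", "chr1", 100L, "+", 0L, 0L),
                 obsRow("s1", "chr1", 200L, "+", 90L, 10L))
    expect_warning(called <- callCandidateSites(obs), "zero total")
    expect_identical(nrow(called), 1L)
})

test_that("missingness resolution backfills covered sub-threshold cells", {
    obs <- rbind(obsRow("s1", "chr1", 100L, "+", 90L, 10L),  # called in A
                 obsRow("s2", "chr1", 100L, "+", 50L, 0L),   # covered, 0
                 obsRow("s3", "chr1", 100L, "+", 98L, 2L))   # sub-threshold
    ee <- resolveMissing(callCandidateSites(obs),
                         samples = c("s1", "s2", "s3", "s4"))
    expect_identical(dim(ee), c(1L, 4L))
    expect_identical(altReads(ee)[1, ],
                     c(s1 = 10L, s2 = 0L, s3 = 2L, s4 = NA_integer_))
    expect_identical(totalReads(ee)[1, "s3"], 100L)
    expect_false(isObserved(ee)[1, "s4"])
})

test_that("prevalence filter is strict and supports both presence modes", {
    # site A observed in 3/5, site B in 2/5, site C called in 1/5
    alt <- matrix(c(6L, 6L, 6L, NA, NA,
                    6L, 6L, NA, NA, NA,
                    9L, 3L, 3L, 3L, 3L), 3, 5, byrow = TRUE)
    tot <- matrix(c(60L, 60L, 60L, NA, NA,
                    60L, 60L, NA, NA, NA,
                    90L, 90L, 90L, 90L, 90L), 3, 5, byrow = TRUE)
    ee <- makeEE(alt, tot)
    kept <- prevalenceFilter(ee, 0.5, "observed")
    expect_identical(siteIds(kept), siteIds(ee)[c(1, 3)])  # 0.6 and 1.0
    # exactly 50% is removed (strict >): site B is observed in 2/4
    ee2 <- makeEE(alt[, 1:4], tot[, 1:4])
    kept2 <- prevalenceFilter(ee2, 0.5, "observed")
    expect_identical(siteIds(kept2), siteIds(ee2)[c(1, 3)])
    # called mode: site C passes thresholds in only 1/5 samples
    keptCalled <- prevalenceFilter(ee, 0.5, "called")
    expect_identical(siteIds(keptCalled), siteIds(ee)[1])
})

test_that("variant subtraction matches by chrom, pos and alleles", {
    ee <- makeEE(matrix(c(10L, 10L), 2, 1), matrix(c(100L, 100L), 2, 1),
                 strand = c("+", "-"))
    # site 1 is chr1:100 A>G, site 2 is chr1:200 T>C
    hit <- subtractDnaVariants(ee, data.frame(
        chrom = "chr1", pos = 100L, ref = "A", alt = "G"))
    expect_identical(hit$removed, "chr1:100:+")
    expect_identical(nrow(hit$experiment), 1L)
    # allele mismatch retains the site
    miss <- subtractDnaVariants(ee, data.frame(
        chrom = "chr1", pos = 100L, ref = "A", alt = "T"))
    expect_identical(length(miss$removed), 0L)
    # strand-aware: T>C site matches a T->C variant
    tc <- subtractDnaVariants(ee, data.frame(
        chrom = "chr1", pos = 200L, ref = "T", alt = "C"))
    expect_identical(tc$removed, "chr1:200:-")
})

test_that("cascade report matches the hand-enumerated toy cohort", {
    toy <- toyCohort()
    res <- runCascade(toy$obs, toy$variants, samples = toy$samples)
    expect_identical(res$report, toy$expectedReport)
    # report arithmetic holds at every stage
    expect_true(all(res$report$n_in - res$report$n_removed ==
                        res$report$n_out))
    # no surviving site remains in the variant set
    rr <- rowRanges(res$experiment)
    skey <- paste(seqnames(rr), start(rr), mcols(rr)$ref, mcols(rr)$alt)
    vkey <- paste(toy$variants$chrom, toy$variants$pos,
                  toy$variants$ref, toy$variants$alt)
    expect_length(intersect(skey, vkey), 0L)
})

test_that("cascade is idempotent on its own output", {
    toy <- toyCohort()
    res1 <- runCascade(toy$obs, toy$variants, samples = toy$samples)
    res2 <- runCascade(asObservations(res1$experiment), toy$variants,
                       samples = toy$samples)
    expect_identical(siteIds(res2$experiment), siteIds(res1$experiment))
    expect_identical(altReads(res2$experiment),
                     altReads(res1$experiment))
    expect_true(all(res2$report$n_removed == 0L))
})

test_that("raising thresholds never increases surviving sites", {
    set.seed(14)
    sim <- simulateEditing(SimConfig(n_sites = 120, seed = 14))
    obs <- asObservations(sim$experiment)
    v <- simulateDnaVariants(sim$truth)
    nSurv <- function(minE, minAf)
        nrow(runCascade(obs, v, min_edited_reads = minE,
                        min_af = minAf)$experiment)
    base <- nSurv(5, 0.05)
    expect_lte(nSurv(8, 0.05), base)
    expect_lte(nSurv(5, 0.20), base)
    expect_lte(nSurv(8, 0.20), min(nSurv(8, 0.05), nSurv(5, 0.20)))
})
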