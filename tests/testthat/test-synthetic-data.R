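test_that("generator honours the truth-table contract", {
    cfg <- SimConfig(n_sites = 400, seed = 11)
    sim <- simulateEditing(cfg)
    tr <- sim$truth
    expect_identical(nrow(tr), 400L)
    expect_identical(sum(tr$is_des), 40L)
    expect_identical(sum(tr$is_dna_variant), 40L)
    # variants planted among non-DES sites; null sites have equal means
    expect_false(any(tr$is_des & tr$is_dna_variant))
    expect_true(all(tr$true_mean_g1[!tr$is_des] ==
                        tr$true_mean_g2[!tr$is_des]))
    expect_true(all(abs(tr$true_log2fc[tr$is_des]) >= cfg@des_log2fc))
    expect_true(all(tr$true_log2fc[!tr$is_des] == 0))
    # raised mean matches the closed form 0.1 * 2^2.5
    raised <- pmax(tr$true_mean_g1, tr$true_mean_g2)[tr$is_des]
    expect_equal(unique(raised), 0.1 * 2^2.5, tolerance = 1e-12)
    # both directions occur
    expect_true(any(tr$true_log2fc[tr$is_des] > 0) &&
                    any(tr$true_log2fc[tr$is_des] < 0))
})

test_that("null config plants nothing and infeasible configs error", {
    sim <- simulateEditing(SimConfig(n_sites = 50, frac_des = 0,
                                     frac_dna_variant = 0, seed = 2))
    expect_identical(sum(sim$truth$is_des), 0L)
    expect_identical(nrow(simulateDnaVariants(sim$truth)), 0L)
    expect_error(
        simulateEditing(SimConfig(null_mean = 0.4, des_log2fc = 2.5)),
        "infeasible")
})

test_that("same seed reproduces bitwise-identical output", {
    cfg <- SimConfig(n_sites = 60, seed = 99)
    a <- simulateEditing(cfg)
    b <- simulateEditing(cfg)
    expect_identical(altReads(a$experiment), altReads(b$experiment))
    expect_identical(totalReads(a$experiment), totalReads(b$experiment))
    expect_identical(a$truth, b$truth)
    expect_identical(
        simulateIC50(10, seed = 5), simulateIC50(10, seed = 5))
})

test_that("null editing levels are centred on null_mean and overdispersed", {
    # ~1.3e5 cells; marginal mean within +-0.01 of the configured null
    cfg <- SimConfig(n_sites = 7500, frac_des = 0, frac_dna_variant = 0,
                     dropout_rate = 0, seed = 31)
    sim <- simulateEditing(cfg)
    lv <- editingLevels(sim$experiment)
    expect_gt(sum(!is.na(lv)), 1e5)
    expect_lt(abs(mean(lv, na.rm = TRUE) - cfg@null_mean), 0.01)
    # variance across cells exceeds the pure-binomial expectation
    tot <- totalReads(sim$experiment)
    mu <- mean(lv, na.rm = TRUE)
    binVar <- mu * (1 - mu) * mean(1 / tot[!is.na(tot)])
    expect_gt(var(as.vector(lv), na.rm = TRUE), 2 * binVar)
})

test_that("planted variant count follows the configured fraction", {
    sim <- simulateEditing(SimConfig(n_sites = 100, frac_des = 0,
                                     frac_dna_variant = 0.1, seed = 3))
    v <- simulateDnaVariants(sim$truth)
    expect_identical(nrow(v), 10L)  # round(0.1 * 100)
    # alleles are strand-aware
    expect_setequal(unique(paste(v$ref, v$alt)), c("A G", "T C"))
})

test_that("IC50 generator yields quartile-separable, seeded tables", {
    tab <- simulateIC50(8, drugs = "olaparib", separation = 0, seed = 7)
    lab <- assignSensitivity(tab, "olaparib")
    expect_identical(sum(lab$label == "HIGH_SENSITIVITY"), 2L)
    expect_identical(sum(lab$label == "LOW_SENSITIVITY"), 2L)
    expect_error(simulateIC50(5), ">= 8")
})

test_that("survival generator: censoring off means all events", {
    cfg <- SurvSimConfig(n_patients = 30, censor_rate = 0, seed = 4)
    s <- simulateSurvival(rep(0.3, 30), cfg)
    expect_true(all(s$event == 1L))
    expect_true(all(s$pfs_months > 0))
    # strong positive effect shortens PFS for highly edited patients
    cfg2 <- SurvSimConfig(n_patients = 2000, censor_rate = 0,
                          effect_beta = 6, seed = 5)
    lv <- rep(c(0.1, 0.6), 1000)
    s2 <- simulateSurvival(lv, cfg2)
    expect_lt(median(s2$pfs_months[lv == 0.6]),
              median(s2$pfs_months[lv == 0.1]))
})

test_that("fixtures round-trip through the io readers", {
    cfg <- SimConfig(n_sites = 40, seed = 21)
    sim <- simulateEditing(cfg)
    reps <- simulateRepeats(sim$truth, seed = 22)
    ic50 <- simulateIC50(ncol(sim$experiment),
                         sample_ids = colnames(sim$experiment),
                         seed = 23)
    d <- withr::local_tempdir()
    writeFixtures(sim, d, repeats = reps, ic50 = ic50)
    obs <- do.call(rbind, lapply(colnames(sim$experiment), function(s)
        readSiteCounts(file.path(d, "counts", paste0(s, ".tsv")), s)))
    # every observed cell survives the round trip with equal counts
    ee <- sim$experiment
    idx <- cbind(match(paste(obs$chrom, obs$pos, obs$strand, sep = ":"),
                       siteIds(ee)),
                 match(obs$sample_id, colnames(ee)))
    expect_false(anyNA(idx))
    expect_identical(obs$alt_reads, unname(altReads(ee)[idx]))
    expect_identical(obs$alt_reads + obs$ref_reads,
                     unname(totalReads(ee)[idx]))
    expect_identical(nrow(obs), sum(isObserved(ee)))
    v <- readVcfVariants(file.path(d, "variants.vcf"))
    expect_identical(nrow(v), sum(sim$truth$is_dna_variant))
    gr <- readBedRepeats(file.path(d, "repeats.bed"))
    expect_identical(length(gr), length(reps))
    expect_equal(readTsv(file.path(d, "ic50.tsv"))$ic50, ic50$ic50,
                 tolerance = 1e-12)
})

test_that("empty cohorts still write valid headered fixture files", {
    sim <- simulateEditing(SimConfig(n_sites = 5, dropout_rate = 0,
                                     frac_des = 0, frac_dna_variant = 0,
                                     seed = 1))
    # force one sample fully missing, then its file has headers only
    ee <- sim$experiment
    assay(ee, "alt")[, 1] <- NA_integer_
    assay(ee, "total")[, 1] <- NA_integer_
    f <- withr::local_tempfile(fileext = ".tsv")
    writeSiteCounts(ee, f, sample = colnames(ee)[1])
    back <- readSiteCounts(f, "x")
    expect_identical(nrow(back), 0L)
})
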