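#' Create a simulation configuration
#'
#' Constructor for [SimConfig-class] with the package's default study
#' conditions (see the class page for the meaning of each parameter).
#'
#' @param n_sites,frac_des,n_group1,n_group2,coverage_mean,
#'   coverage_dispersion,null_mean,null_overdispersion,des_log2fc,
#'   frac_dna_variant,dropout_rate,seed see [SimConfig-class].
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- SimConfig(n_sites = 100, seed = 42)
#' @export
SimConfig <- function(n_sites = 1000L, frac_des = 0.1,
                      n_group1 = 10L, n_group2 = 8L,
                      coverage_mean = 50, coverage_dispersion = 0.1,
                      null_mean = 0.1, null_overdispersion = 0.05,
                      des_log2fc = 2.5, frac_dna_variant = 0.1,
                      dropout_rate = 0.05, seed = 1L) {
    new("SimConfig", n_sites = as.integer(n_sites), frac_des = frac_des,
        n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
        coverage_mean = coverage_mean,
        coverage_dispersion = coverage_dispersion,
        null_mean = null_mean, null_overdispersion = null_overdispersion,
        des_log2fc = des_log2fc, frac_dna_variant = frac_dna_variant,
        dropout_rate = dropout_rate, seed = as.integer(seed))
}

#' Create a survival simulation configuration
#'
#' Constructor for [SurvSimConfig-class]. The default `effect_beta = 6`
#' corresponds to a hazard ratio of roughly 2.5 between hyper- and
#' hypo-edited patients when editing levels have spread ~0.1, a clearly
#' detectable clinical effect at the default cohort size.
#'
#' @param n_patients,baseline_hazard,effect_beta,censor_rate,seed see
#'   [SurvSimConfig-class].
#' @return A validated `SurvSimConfig`.
#' @export
SurvSimConfig <- function(n_patients = 86L, baseline_hazard = 0.03,
                          effect_beta = 6, censor_rate = 0.3, seed = 1L) {
    new("SurvSimConfig", n_patients = as.integer(n_patients),
        baseline_hazard = baseline_hazard, effect_beta = effect_beta,
        censor_rate = censor_rate, seed = as.integer(seed))
}

## (mu, rho) -> (alpha, beta); mean alpha/(alpha+beta) = mu, ICC = rho
.bbShapes <- function(mu, rho) {
    phi <- (1 - rho) / rho
    c(alpha = mu * phi, beta = (1 - mu) * phi)
}

#' Simulate a grouped beta-binomial editing cohort
#'
#' Generates a two-group editing count matrix with known ground truth.
#' Per cell, total coverage is negative binomial (mean
#' `coverage_mean`, variance `m + d m^2`); edited reads are beta-binomial
#' with the site's group mean and overdispersion `null_overdispersion`.
#' A fraction `frac_des` of sites is differentially edited: the raised
#' group's mean is `null_mean * 2^des_log2fc`, with the raised group split
#' 50/50 between group 1 and group 2. A disjoint fraction
#' `frac_dna_variant` of the remaining sites is planted as genomic
#' variants: they mimic heterozygous DNA polymorphisms (allelic fraction
#' around 0.5 in both groups) and are expected to be removed by
#' [subtractDnaVariants()]. Cells are set to NO_COVERAGE (`NA`) with
#' probability `dropout_rate`, or when the drawn coverage is zero.
#'
#' All randomness flows from `cfg@seed`; equal configurations reproduce
#' bitwise-identical output.
#'
#' @param cfg a [SimConfig()].
#' @return A list with elements `experiment` (an [EditingExperiment] with a
#'   `group` column in `colData`) and `truth` (data.frame: `site_id`,
#'   `chrom`, `pos`, `strand`, `ref`, `alt`, `is_des`, `is_dna_variant`,
#'   `true_mean_g1`, `true_mean_g2`, `true_log2fc`).
#' @export
simulateEditing <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    desMean <- cfg@null_mean * 2^cfg@des_log2fc
    if (cfg@frac_des > 0 && (desMean >= 1 || desMean <= 0))
        stop(sprintf(
            "infeasible config: null_mean %.3g * 2^%.3g = %.3g leaves (0,1)",
            cfg@null_mean, cfg@des_log2fc, desMean))
    set.seed(cfg@seed)
    ns <- cfg@n_sites

    chrom <- paste0("chr", sample(1:22, ns, replace = TRUE))
    pos <- sample.int(5e7L, ns, replace = FALSE)
    strand <- sample(c("+", "-"), ns, replace = TRUE)
    sites <- data.frame(
        chrom = chrom, pos = pos, strand = strand,
        ref = ifelse(strand == "+", "A", "T"),
        alt = ifelse(strand == "+", "G", "C"))

    nDes <- round(cfg@frac_des * ns)
    desIdx <- sample.int(ns, nDes)
    isDes <- seq_len(ns) %in% desIdx
    ## raised group alternates over the (already random) DES draw order
    raisedG2 <- logical(ns)
    raisedG2[desIdx] <- rep(c(TRUE, FALSE), length.out = nDes)

    nVar <- round(cfg@frac_dna_variant * ns)
    nonDes <- which(!isDes)
    if (nVar > length(nonDes))
        stop("frac_dna_variant + frac_des exceed the available sites")
    isVar <- seq_len(ns) %in% sample(nonDes, nVar)

    meanG1 <- rep(cfg@null_mean, ns)
    meanG2 <- rep(cfg@null_mean, ns)
    meanG2[isDes & raisedG2] <- desMean
    meanG1[isDes & !raisedG2] <- desMean
    meanG1[isVar] <- meanG2[isVar] <- 0.5  # het DNA polymorphism mimic

    nSamp <- cfg@n_group1 + cfg@n_group2
    group <- factor(rep(c("g1", "g2"), c(cfg@n_group1, cfg@n_group2)),
                    levels = c("g1", "g2"))
    sampleIds <- paste0(group, "_s", c(seq_len(cfg@n_group1),
                                       seq_len(cfg@n_group2)))

    drawCov <- function(n) {
        if (cfg@coverage_dispersion > 0)
            rnbinom(n, mu = cfg@coverage_mean,
                    size = 1 / cfg@coverage_dispersion)
        else
            stats::rpois(n, cfg@coverage_mean)
    }
    tot <- matrix(drawCov(ns * nSamp), ns, nSamp)
    mu <- cbind(matrix(meanG1, ns, cfg@n_group1),
                matrix(meanG2, ns, cfg@n_group2))
    phi <- (1 - cfg@null_overdispersion) / cfg@null_overdispersion
    p <- matrix(rbeta(ns * nSamp, mu * phi, (1 - mu) * phi), ns, nSamp)
    alt <- matrix(rbinom(ns * nSamp, tot, p), ns, nSamp)
    drop <- matrix(runif(ns * nSamp) < cfg@dropout_rate, ns, nSamp) |
        tot == 0L
    alt[drop] <- NA_integer_
    tot[drop] <- NA_integer_
    colnames(alt) <- colnames(tot) <- sampleIds

    ee <- EditingExperiment(alt, tot, sites,
                            colData = S4Vectors::DataFrame(
                                group = group, row.names = sampleIds))
    truth <- data.frame(
        site_id = siteIds(ee), sites,
        is_des = isDes, is_dna_variant = isVar,
        true_mean_g1 = meanG1, true_mean_g2 = meanG2,
        true_log2fc = ifelse(isDes, log2(meanG1 / meanG2), 0))
    list(experiment = ee, truth = truth)
}

#' Emit the planted genomic variants of a simulated cohort
#'
#' Returns VCF-ready records for the sites flagged `is_dna_variant` in a
#' [simulateEditing()] truth table, with strand-aware alleles (A/G on the
#' plus strand, T/C on the minus strand) matching by chromosome, position
#' and alleles.
#'
#' @param truth truth table from [simulateEditing()].
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
simulateDnaVariants <- function(truth) {
    v <- truth[truth$is_dna_variant, , drop = FALSE]
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
               row.names = NULL)
}

#' Simulate repeat annotation intervals
#'
#' Builds a repeat annotation covering a random subset of the simulated
#' sites: a fraction `frac_alu` of sites get an Alu interval spanning them
#' and a further `frac_non_alu` a non-Alu repeat interval; the rest remain
#' non-repetitive. Interval half-width 150 bp, the typical scale of an Alu
#' element.
#'
#' @param sites data.frame with `chrom` and `pos` (e.g. a truth table).
#' @param frac_alu,frac_non_alu fractions of sites covered by each class.
#' @param halfwidth interval half-width in bp.
#' @param seed integer seed.
#' @return A `GRanges` with metadata column `repeat_class`.
#' @export
simulateRepeats <- function(sites, frac_alu = 0.5, frac_non_alu = 0.2,
                            halfwidth = 150L, seed = 1L) {
    stopifnot(frac_alu + frac_non_alu <= 1)
    set.seed(seed)
    n <- nrow(sites)
    idx <- sample.int(n)
    nAlu <- round(frac_alu * n)
    nRep <- round(frac_non_alu * n)
    i <- idx[seq_len(nAlu + nRep)]
    cls <- rep(c("ALU", "NON_ALU_REPEAT"), c(nAlu, nRep))
    gr <- GRanges(sites$chrom[i],
                  IRanges(pmax(1L, sites$pos[i] - halfwidth),
                          sites$pos[i] + halfwidth))
    mcols(gr)$repeat_class <- cls
    sort(gr)
}

#' Simulate per-drug normalized IC50 values
#'
#' Draws standardized log-IC50 values for `n_samples` cell lines and
#' `drugs`, with an additive shift `separation` for the low-sensitivity
#' stratum so that quartile classes are well separated. When `group` is
#' supplied, its first level is the low-sensitivity (shifted, higher-IC50)
#' stratum; otherwise the first half of the samples is shifted.
#' `separation = 0` gives iid values.
#'
#' @param n_samples number of cell lines (>= 8).
#' @param drugs character vector of drug names.
#' @param separation IC50 shift (in SD units) of the low-sensitivity
#'   stratum.
#' @param group optional factor/character of per-sample strata.
#' @param sample_ids optional sample names.
#' @param seed integer seed.
#' @return A long data.frame with columns `sample_id`, `drug`, `ic50`.
#' @export
simulateIC50 <- function(n_samples, drugs = c("olaparib", "doxorubicin",
                                              "cisplatin"),
                         separation = 2, group = NULL, sample_ids = NULL,
                         seed = 1L) {
    if (n_samples < 8L)
        stop("n_samples must be >= 8 for quartile stratification")
    set.seed(seed)
    if (is.null(sample_ids))
        sample_ids <- sprintf("s%02d", seq_len(n_samples))
    if (is.null(group)) {
        shifted <- seq_len(n_samples) <= ceiling(n_samples / 2)
    } else {
        stopifnot(length(group) == n_samples)
        shifted <- group == (if (is.factor(group)) levels(group)[1L]
                             else sort(unique(group))[1L])
    }
    do.call(rbind, lapply(drugs, function(d) {
        data.frame(sample_id = sample_ids, drug = d,
                   ic50 = rnorm(n_samples) + separation * shifted)
    }))
}

#' Simulate progression-free survival driven by editing level
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(effect_beta * level)`; censoring times are
#' independent exponentials whose rate is chosen so the expected censored
#' fraction equals `censor_rate` at `effect_beta = 0` (`censor_rate = 0`
#' disables censoring entirely).
#'
#' @param levels per-patient editing levels in \[0,1\] at the
#'   hazard-driving site.
#' @param cfg a [SurvSimConfig()]; `cfg@n_patients` must equal
#'   `length(levels)`.
#' @return A data.frame with columns `patient_id`, `pfs_months`, `event`
#'   (1 = progressed, 0 = censored) and `level`.
#' @export
simulateSurvival <- function(levels, cfg) {
    stopifnot(is(cfg, "SurvSimConfig"))
    validObject(cfg)
    if (length(levels) != cfg@n_patients)
        stop("length(levels) must equal cfg@n_patients")
    if (any(levels < 0 | levels > 1, na.rm = TRUE))
        stop("editing levels must lie in [0,1]")
    set.seed(cfg@seed)
    n <- cfg@n_patients
    haz <- cfg@baseline_hazard * exp(cfg@effect_beta * levels)
    evt <- rexp(n, haz)
    cen <- if (cfg@censor_rate > 0) {
        rexp(n, cfg@baseline_hazard * cfg@censor_rate /
                 (1 - cfg@censor_rate))
    } else rep(Inf, n)
    data.frame(patient_id = sprintf("p%03d", seq_len(n)),
               pfs_months = pmin(evt, cen),
               event = as.integer(evt <= cen),
               level = levels)
}

#' Simulate per-patient editing levels at a set of sites
#'
#' Draws, for each site, per-patient editing levels from a beta
#' distribution with the site's mean and a common overdispersion, with
#' independent per-cell missingness — the patient-cohort analogue of the
#' cell-line generator, used to feed [siteSurvivalScan()].
#'
#' @param site_means named numeric vector of per-site mean editing levels.
#' @param n_patients cohort size.
#' @param overdispersion beta intra-class correlation rho in (0,1).
#' @param missing_rate per-cell probability the site is unobserved in a
#'   patient.
#' @param seed integer seed.
#' @return A sites x patients matrix of levels (`NA` = missing).
#' @export
simulatePatientLevels <- function(site_means, n_patients,
                                  overdispersion = 0.05,
                                  missing_rate = 0.1, seed = 1L) {
    set.seed(seed)
    phi <- (1 - overdispersion) / overdispersion
    ns <- length(site_means)
    lev <- matrix(rbeta(ns * n_patients, site_means * phi,
                        (1 - site_means) * phi), ns, n_patients)
    lev[matrix(runif(ns * n_patients) < missing_rate,
               ns, n_patients)] <- NA_real_
    dimnames(lev) <- list(names(site_means),
                          sprintf("p%03d", seq_len(n_patients)))
    lev
}

#' Write all pipeline input fixtures to disk
#'
#' Serializes a simulated cohort into the on-disk formats the pipeline
#' consumes: one site-count TSV per sample under `counts/`, the planted
#' genomic variants as VCF, repeat intervals as BED (0-based half-open),
#' and the IC50, survival and truth tables as TSV. Everything round-trips
#' through the corresponding readers.
#'
#' @param sim output of [simulateEditing()].
#' @param dir output directory (created if needed).
#' @param repeats optional `GRanges` from [simulateRepeats()].
#' @param ic50 optional IC50 table from [simulateIC50()].
#' @param survival optional survival table from [simulateSurvival()].
#' @return Named character vector of the files written, invisibly.
#' @export
writeFixtures <- function(sim, dir, repeats = NULL, ic50 = NULL,
                          survival = NULL) {
    countsDir <- file.path(dir, "counts")
    dir.create(countsDir, recursive = TRUE, showWarnings = FALSE)
    ee <- sim$experiment
    files <- c()
    for (s in colnames(ee)) {
        f <- file.path(countsDir, paste0(s, ".tsv"))
        writeSiteCounts(ee, f, sample = s)
        files[paste0("counts_", s)] <- f
    }
    files["variants"] <- writeVcfVariants(
        simulateDnaVariants(sim$truth), file.path(dir, "variants.vcf"))
    files["truth"] <- writeTsv(sim$truth, file.path(dir, "truth.tsv"))
    if (!is.null(repeats))
        files["repeats"] <- writeBedRepeats(
            repeats, file.path(dir, "repeats.bed"))
    if (!is.null(ic50))
        files["ic50"] <- writeTsv(ic50, file.path(dir, "ic50.tsv"))
    if (!is.null(survival))
        files["survival"] <- writeTsv(survival,
                                      file.path(dir, "survival.tsv"))
    invisible(files)
}
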