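#' EditingExperiment: sites-by-samples editing counts
#'
#' An [SummarizedExperiment::RangedSummarizedExperiment] subclass holding
#' A>I(G) editing observations: two integer assays, `"alt"` (edited reads:
#' G on the plus strand, C on the minus strand) and `"total"`
#' (ref + alt reads). Cells with no coverage in a sample are `NA` in both
#' assays; an observed cell with `alt == 0` is real data (a covered,
#' unedited position) and is distinct from missingness.
#'
#' Row ranges are 1-based single-base [GenomicRanges::GRanges] with strand
#' and metadata columns `ref` and `alt` obeying the strand rule: plus-strand
#' sites are A>G, minus-strand sites are T>C. `(chrom, pos, strand)` is
#' unique.
#'
#' @slot .. inherits all slots from `RangedSummarizedExperiment`.
#' @seealso [EditingExperiment()] for construction, [altReads()],
#'   [totalReads()], [editingLevels()], [isObserved()].
#' @export
setClass("EditingExperiment", contains = "RangedSummarizedExperiment")

.validEditingExperiment <- function(object) {
    msg <- NULL
    an <- assayNames(object)
    if (!all(c("alt", "total") %in% an))
        return("assays 'alt' and 'total' are required")
    alt <- assay(object, "alt")
    tot <- assay(object, "total")
    if (!identical(is.na(alt), is.na(tot)))
        msg <- c(msg, "'alt' and 'total' must share the same NA pattern")
    ok <- !is.na(alt)
    if (any(alt[ok] < 0) || any(tot[ok] < alt[ok]))
        msg <- c(msg, "observed cells require 0 <= alt <= total")
    rr <- rowRanges(object)
    if (length(rr)) {
        need <- c("ref", "alt")
        if (!all(need %in% colnames(mcols(rr))))
            return("rowRanges need metadata columns 'ref' and 'alt'")
        str <- as.character(strand(rr))
        if (any(!str %in% c("+", "-")))
            msg <- c(msg, "site strand must be '+' or '-'")
        bad <- (str == "+" & !(mcols(rr)$ref == "A" & mcols(rr)$alt == "G")) |
               (str == "-" & !(mcols(rr)$ref == "T" & mcols(rr)$alt == "C"))
        if (any(bad))
            msg <- c(msg, sprintf(
                "%d site(s) violate the strand rule (+:A>G, -:T>C)",
                sum(bad)))
        key <- paste(seqnames(rr), start(rr), str)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (chrom, pos, strand) sites")
    }
    if (is.null(msg)) TRUE else msg
}

setValidity("EditingExperiment", .validEditingExperiment)

#' Beta-binomial maximum-likelihood fit
#'
#' Result of fitting a beta-binomial distribution to per-sample
#' (edited, total) read counts at one site. The mean editing level is
#' `alpha / (alpha + beta)`.
#'
#' @slot alpha,beta positive shape parameters.
#' @slot mean mean editing level, `alpha / (alpha + beta)`.
#' @slot loglik maximized log-likelihood (nats) on the fitted cells.
#' @slot converged logical; optimizer convergence.
#' @slot boundary logical; `TRUE` when the estimate sits on the edge of the
#'   search region (degenerate data such as all-zero edited counts).
#' @seealso [fitBetaBinomial()]
#' @export
setClass("BetaBinFit", representation(
    alpha = "numeric", beta = "numeric", mean = "numeric",
    loglik = "numeric", converged = "logical", boundary = "logical"))

setValidity("BetaBinFit", function(object) {
    if (object@alpha <= 0 || object@beta <= 0)
        return("shape parameters must be positive")
    if (abs(object@mean - object@alpha / (object@alpha + object@beta)) > 1e-9)
        return("mean inconsistent with alpha/(alpha+beta)")
    TRUE
})

#' Simulation configuration for synthetic editing cohorts
#'
#' Parameters of the grouped beta-binomial generator used by
#' [simulateEditing()]. Defaults encode the study conditions the package is
#' validated under: two sensitivity groups of 10 and 8 samples, negative
#' binomial coverage with mean 50, a null editing level of 0.1 with
#' intra-site overdispersion 0.05, 10% differentially edited sites at
#' |log2 fold change| 2.5, 10% genomic-variant contaminants and 5% per-cell
#' dropout.
#'
#' @slot n_sites number of editing sites.
#' @slot frac_des fraction of sites planted as differentially edited.
#' @slot n_group1,n_group2 samples per group (>= 2).
#' @slot coverage_mean,coverage_dispersion negative-binomial coverage model:
#'   mean reads per cell and dispersion d with variance `m + d m^2`.
#' @slot null_mean shared editing level of null sites, in (0,1).
#' @slot null_overdispersion beta-binomial intra-class correlation rho in
#'   (0,1); `alpha = mu(1-rho)/rho`, `beta = (1-mu)(1-rho)/rho`.
#' @slot des_log2fc magnitude of the planted log2 fold change (>= 0).
#' @slot frac_dna_variant fraction of sites planted as genomic variants.
#' @slot dropout_rate per-cell probability of NO_COVERAGE.
#' @slot seed integer seed governing all randomness.
#' @seealso [SimConfig()], [simulateEditing()]
#' @export
setClass("SimConfig", representation(
    n_sites = "integer", frac_des = "numeric",
    n_group1 = "integer", n_group2 = "integer",
    coverage_mean = "numeric", coverage_dispersion = "numeric",
    null_mean = "numeric", null_overdispersion = "numeric",
    des_log2fc = "numeric", frac_dna_variant = "numeric",
    dropout_rate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    frc <- c(frac_des = object@frac_des,
             frac_dna_variant = object@frac_dna_variant,
             dropout_rate = object@dropout_rate)
    bad <- frc < 0 | frc > 1
    if (any(bad))
        msg <- c(msg, sprintf("fraction '%s' outside [0,1]",
                              names(frc)[bad][1L]))
    if (object@n_sites < 1L) msg <- c(msg, "n_sites must be >= 1")
    if (object@n_group1 < 2L || object@n_group2 < 2L)
        msg <- c(msg, "each group needs >= 2 samples")
    if (object@coverage_mean < 1) msg <- c(msg, "coverage_mean must be >= 1")
    if (object@coverage_dispersion < 0)
        msg <- c(msg, "coverage_dispersion must be >= 0")
    if (object@null_mean <= 0 || object@null_mean >= 1)
        msg <- c(msg, "null_mean must lie in (0,1)")
    if (object@null_overdispersion <= 0 || object@null_overdispersion >= 1)
        msg <- c(msg, "null_overdispersion must lie in (0,1)")
    if (object@des_log2fc < 0) msg <- c(msg, "des_log2fc must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Survival simulation configuration
#'
#' Parameters of the exponential proportional-hazards generator used by
#' [simulateSurvival()]: event times have hazard
#' `baseline_hazard * exp(effect_beta * level)` where `level` is the
#' patient's editing level at the driving site; censoring is independent.
#'
#' @slot n_patients cohort size (>= 4).
#' @slot baseline_hazard events per month at editing level 0.
#' @slot effect_beta log-hazard increase per unit editing level.
#' @slot censor_rate expected censored fraction in [0,1) (exact at
#'   `effect_beta = 0`).
#' @slot seed integer seed.
#' @seealso [SurvSimConfig()], [simulateSurvival()]
#' @export
setClass("SurvSimConfig", representation(
    n_patients = "integer", baseline_hazard = "numeric",
    effect_beta = "numeric", censor_rate = "numeric", seed = "integer"))

setValidity("SurvSimConfig", function(object) {
    msg <- NULL
    if (object@n_patients < 4L) msg <- c(msg, "n_patients must be >= 4")
    if (object@baseline_hazard <= 0)
        msg <- c(msg, "baseline_hazard must be > 0")
    if (object@censor_rate < 0 || object@censor_rate >= 1)
        msg <- c(msg, "censor_rate must lie in [0,1)")
    if (is.null(msg)) TRUE else msg
})
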