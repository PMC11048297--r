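## Filter cascade: candidate calling -> missingness resolution ->
## cohort prevalence -> genomic-variant subtraction.

#' Call candidate edited sites per sample
#'
#' Applies the per-sample calling rule to raw observations: a site is
#' called in a sample iff it has at least `min_edited_reads` edited reads
#' and an allele frequency (`alt / (alt + ref)`) of at least `min_af`.
#' Observed cells with zero total reads are demoted to NO_COVERAGE with a
#' warning.
#'
#' @param obs long observation data.frame (rows = OBSERVED cells), as
#'   returned by [readSiteCounts()] for one or more samples (rbind them).
#' @param min_edited_reads minimum edited-read count (default 5).
#' @param min_af minimum allele frequency (default 0.05).
#' @return `obs` with a logical column `called` (zero-total rows removed).
#' @export
callCandidateSites <- function(obs, min_edited_reads = 5, min_af = 0.05) {
    total <- obs$ref_reads + obs$alt_reads
    if (any(total == 0)) {
        warning(sum(total == 0),
                " observed cell(s) with zero total reads treated as ",
                "NO_COVERAGE")
        obs <- obs[total > 0, , drop = FALSE]
        total <- total[total > 0]
    }
    obs$called <- obs$alt_reads >= min_edited_reads &
        obs$alt_reads / total >= min_af
    obs
}

#' Resolve missing values into an editing matrix
#'
#' Builds the sites-by-samples [EditingExperiment] over the union of sites
#' called in at least one sample, disambiguating missingness from raw
#' counts: a cell of an uncalled site/sample pair is backfilled as
#' OBSERVED with its raw (possibly zero or sub-threshold) counts whenever
#' the sample has coverage there, and NO_COVERAGE otherwise. Sub-threshold
#' cells are kept as data even though they were never "called".
#'
#' @param obs output of [callCandidateSites()] (must carry `called`).
#' @param samples optional character vector fixing the sample universe and
#'   order (defaults to the samples present in `obs`).
#' @return An [EditingExperiment] over the called-site union.
#' @export
resolveMissing <- function(obs, samples = NULL) {
    stopifnot("called" %in% names(obs))
    if (is.null(samples)) samples <- unique(obs$sample_id)
    key <- paste(obs$chrom, obs$pos, obs$strand, sep = ":")
    keep <- unique(key[obs$called])
    sel <- key %in% keep
    obs <- obs[sel, , drop = FALSE]
    key <- key[sel]
    ord <- order(obs$chrom, obs$pos, obs$strand)
    first <- !duplicated(key[ord])
    sitedf <- obs[ord, ][first, c("chrom", "pos", "strand", "ref", "alt")]
    ids <- key[ord][first]
    alt <- matrix(NA_integer_, length(ids), length(samples),
                  dimnames = list(ids, samples))
    tot <- alt
    i <- match(key, ids)
    j <- match(obs$sample_id, samples)
    alt[cbind(i, j)] <- obs$alt_reads
    tot[cbind(i, j)] <- obs$ref_reads + obs$alt_reads
    EditingExperiment(alt, tot, sitedf)
}

#' Cohort prevalence filter
#'
#' Keeps sites present in strictly more than `min_frac` of the samples.
#' "Present" defaults to OBSERVED (the sample has coverage at the site);
#' the alternative `presence = "called"` counts only samples where the
#' site passes the calling thresholds.
#'
#' @param ee an [EditingExperiment].
#' @param min_frac prevalence threshold, strict inequality (default 0.5).
#' @param presence `"observed"` or `"called"`.
#' @param min_edited_reads,min_af calling thresholds used when
#'   `presence = "called"`.
#' @return The filtered `EditingExperiment`.
#' @export
prevalenceFilter <- function(ee, min_frac = 0.5,
                             presence = c("observed", "called"),
                             min_edited_reads = 5, min_af = 0.05) {
    presence <- match.arg(presence)
    pres <- if (presence == "observed") {
        isObserved(ee)
    } else {
        alt <- altReads(ee)
        tot <- totalReads(ee)
        m <- !is.na(tot) & alt >= min_edited_reads & alt / tot >= min_af
        m
    }
    frac <- rowMeans(pres)
    ee[frac > min_frac, ]
}

#' Subtract genomic DNA variants
#'
#' Removes sites whose `(chrom, pos, ref, alt)` tuple exactly matches a
#' DNA variant: strand-aware, so a minus-strand T>C site is removed only
#' by a T->C variant at that position. Editing-like signals explained by a
#' genomic polymorphism are thereby excluded.
#'
#' @param ee an [EditingExperiment].
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (e.g. from [readVcfVariants()]); `NULL` means no subtraction.
#' @return A list with elements `experiment` (filtered) and `removed`
#'   (character vector of removed site ids).
#' @export
subtractDnaVariants <- function(ee, variants) {
    if (is.null(variants) || !nrow(variants))
        return(list(experiment = ee, removed = character()))
    rr <- rowRanges(ee)
    skey <- paste(as.character(seqnames(rr)), start(rr),
                  mcols(rr)$ref, mcols(rr)$alt)
    vkey <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
    hit <- skey %in% vkey
    list(experiment = ee[!hit, ], removed = siteIds(ee)[hit])
}

#' Run the full filter cascade
#'
#' Composes the stages in order — candidate calling, missingness
#' resolution, cohort prevalence, genomic-variant subtraction — and
#' returns the final [EditingExperiment] together with a `FilterReport`
#' accounting every removal (`n_in - n_removed = n_out` at each stage;
#' counts are sites).
#'
#' @inheritParams callCandidateSites
#' @inheritParams prevalenceFilter
#' @param variants DNA variant table (or `NULL`).
#' @param samples optional sample universe passed to [resolveMissing()].
#' @return A list with elements `experiment` and `report` (data.frame:
#'   `stage`, `n_in`, `n_removed`, `n_out`).
#' @export
runCascade <- function(obs, variants = NULL, min_edited_reads = 5,
                       min_af = 0.05, min_frac = 0.5,
                       presence = c("observed", "called"),
                       samples = NULL) {
    presence <- match.arg(presence)
    nIn <- length(unique(paste(obs$chrom, obs$pos, obs$strand)))
    called <- callCandidateSites(obs, min_edited_reads, min_af)
    ee <- resolveMissing(called, samples = samples)
    n1 <- nrow(ee)
    ee2 <- prevalenceFilter(ee, min_frac, presence,
                            min_edited_reads, min_af)
    n2 <- nrow(ee2)
    sub <- subtractDnaVariants(ee2, variants)
    n3 <- nrow(sub$experiment)
    report <- data.frame(
        stage = c("candidate_calling", "resolve_missing", "prevalence",
                  "variant_subtraction"),
        n_in = c(nIn, n1, n1, n2),
        n_removed = c(nIn - n1, 0L, n1 - n2, n2 - n3),
        n_out = c(n1, n1, n2, n3))
    list(experiment = sub$experiment, report = report)
}

#' Flatten an EditingExperiment back to long observations
#'
#' Inverse of [resolveMissing()] at the cell level: one row per OBSERVED
#' cell. Useful to re-feed a matrix through [runCascade()] (the cascade is
#' idempotent on its own output).
#'
#' @param ee an [EditingExperiment].
#' @return A long observation data.frame as produced by
#'   [readSiteCounts()].
#' @export
asObservations <- function(ee) {
    obs <- which(isObserved(ee), arr.ind = TRUE)
    rr <- rowRanges(ee)[obs[, 1L]]
    data.frame(
        sample_id = colnames(ee)[obs[, 2L]],
        chrom = as.character(seqnames(rr)), pos = start(rr),
        strand = as.character(strand(rr)),
        ref = mcols(rr)$ref, alt = mcols(rr)$alt,
        ref_reads = refReads(ee)[obs], alt_reads = altReads(ee)[obs])
}
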