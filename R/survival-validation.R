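## Patient-cohort validation: hyper/hypo classification, Kaplan-Meier,
## log-rank, the per-site survival scan and repeat-class annotation.

#' Classify patients as hyper- or hypo-edited at a site
#'
#' A patient is `HYPER` when their editing level strictly exceeds the mean
#' level across the patients in whom the site is observed, `HYPO`
#' otherwise (a level exactly at the mean is `HYPO`). Missing levels stay
#' missing; identical levels everywhere give all-`HYPO` with a warning.
#'
#' @param levels numeric vector of editing levels (`NA` = site not
#'   observed in that patient); needs >= 2 non-missing values.
#' @return Character vector of `"HYPER"`/`"HYPO"`/`NA`.
#' @export
classifyHyperHypo <- function(levels) {
    obs <- !is.na(levels)
    if (sum(obs) < 2L) stop("need >= 2 non-missing levels")
    m <- mean(levels[obs])
    if (all(levels[obs] == levels[obs][1L]))
        warning("all levels identical: degenerate split, all HYPO")
    out <- rep(NA_character_, length(levels))
    out[obs] <- ifelse(levels[obs] > m, "HYPER", "HYPO")
    out
}

#' Kaplan-Meier survival table
#'
#' Product-limit estimate of the survival function, via
#' [survival::survfit()]: at each distinct event time `t`,
#' `S(t) = prod(1 - d_i / n_i)`; times with only censoring change the
#' at-risk count but not the estimate. Ties between events and censorings
#' at one time are resolved events-first (the standard convention).
#'
#' @param times follow-up times (> 0).
#' @param events event indicators (1 = progressed, 0 = censored).
#' @return A data.frame step table: `time`, `n_risk`, `n_event`,
#'   `survival`, one row per distinct observed time.
#' @export
kmEstimate <- function(times, events) {
    stopifnot(length(times) > 0L, length(times) == length(events))
    fit <- survfit(Surv(times, events) ~ 1)
    data.frame(time = fit$time, n_risk = as.integer(fit$n.risk),
               n_event = as.integer(fit$n.event), survival = fit$surv)
}

#' Two-sample log-rank test
#'
#' Standard log-rank test via [survival::survdiff()]: observed minus
#' expected events summed over event times, variance from the
#' hypergeometric terms, referred to chi-square with 1 degree of freedom.
#'
#' @param labels two-group membership vector.
#' @param times follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return A list with `chi2` and `pvalue`.
#' @export
logrankTest <- function(labels, times, events) {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) != 2L)
        stop("log-rank requires exactly two non-empty groups")
    sd <- survdiff(Surv(times, events) ~ labels)
    list(chi2 = unname(sd$chisq),
         pvalue = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Per-site survival scan over DES editing levels
#'
#' For every site: classify patients hyper/hypo by the site-mean rule
#' ([classifyHyperHypo()]), run the log-rank test between the two classes,
#' and compute the Kaplan-Meier table of each class. Patients missing the
#' site are excluded for that site only. Sites observed in fewer than
#' `min_patients` patients, or whose split leaves an empty class, are
#' skipped with a reason. Significance is flagged on the raw log-rank p
#' (mirroring how such scans are usually reported); a BH-adjusted column
#' is provided alongside.
#'
#' @param levels sites x patients matrix of editing levels (`NA` =
#'   missing), e.g. from [simulatePatientLevels()]; rownames are site
#'   ids, colnames patient ids.
#' @param surv data.frame with columns `patient_id`, `pfs_months`,
#'   `event`.
#' @param p_max significance threshold on the raw p-value.
#' @param min_patients minimum patients with the site observed.
#' @return A list: `results` (data.frame `site`, `n_hyper`, `n_hypo`,
#'   `logrank_chi2`, `pvalue`, `fdr`, `significant`), `km` (per-site list
#'   with `hyper`/`hypo` KM tables) and `skipped` (data.frame `site`,
#'   `reason`).
#' @export
siteSurvivalScan <- function(levels, surv, p_max = 0.05,
                             min_patients = 4L) {
    levels <- as.matrix(levels)
    idx <- match(colnames(levels), surv$patient_id)
    if (anyNA(idx))
        stop("patients in 'levels' missing from the survival table")
    times <- surv$pfs_months[idx]
    events <- surv$event[idx]
    results <- list(); km <- list(); skipped <- list()
    for (i in seq_len(nrow(levels))) {
        site <- rownames(levels)[i]
        lv <- levels[i, ]
        obs <- !is.na(lv)
        if (sum(obs) < min_patients) {
            skipped[[site]] <- sprintf("observed in %d < %d patients",
                                       sum(obs), min_patients)
            next
        }
        cls <- suppressWarnings(classifyHyperHypo(lv))[obs]
        if (length(unique(cls)) < 2L) {
            skipped[[site]] <- "degenerate hyper/hypo split"
            next
        }
        lr <- logrankTest(cls, times[obs], events[obs])
        results[[site]] <- data.frame(
            site = site, n_hyper = sum(cls == "HYPER"),
            n_hypo = sum(cls == "HYPO"), logrank_chi2 = lr$chi2,
            pvalue = lr$pvalue)
        km[[site]] <- list(
            hyper = kmEstimate(times[obs][cls == "HYPER"],
                               events[obs][cls == "HYPER"]),
            hypo = kmEstimate(times[obs][cls == "HYPO"],
                              events[obs][cls == "HYPO"]))
    }
    results <- if (length(results)) do.call(rbind, results) else
        data.frame(site = character(), n_hyper = integer(),
                   n_hypo = integer(), logrank_chi2 = numeric(),
                   pvalue = numeric())
    rownames(results) <- NULL
    results$fdr <- bhFdr(results$pvalue)
    results$significant <- results$pvalue < p_max
    skipped <- data.frame(site = names(skipped),
                          reason = unlist(skipped, use.names = FALSE))
    list(results = results, km = km, skipped = skipped)
}

#' Annotate sites with their repeat class
#'
#' Classifies each 1-based site position against repeat intervals: `ALU`
#' when it falls in any Alu interval (Alu takes precedence on overlap),
#' else `NON_ALU_REPEAT` when in any other repeat, else `NON_REPETITIVE`.
#'
#' @param sites a `GRanges` (e.g. `rowRanges` of an [EditingExperiment])
#'   or a data.frame with `chrom` and `pos`.
#' @param repeats `GRanges` with metadata column `repeat_class`.
#' @return Character vector of classes, one per site.
#' @export
annotateRepeatClass <- function(sites, repeats) {
    if (is.data.frame(sites))
        sites <- GRanges(sites$chrom, IRanges(sites$pos, width = 1L))
    inAlu <- suppressWarnings(overlapsAny(
        sites, repeats[mcols(repeats)$repeat_class == "ALU"],
        ignore.strand = TRUE))
    inRep <- suppressWarnings(overlapsAny(
        sites, repeats[mcols(repeats)$repeat_class == "NON_ALU_REPEAT"],
        ignore.strand = TRUE))
    ifelse(inAlu, "ALU", ifelse(inRep, "NON_ALU_REPEAT",
                                "NON_REPETITIVE"))
}
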