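## Sample grouping by drug sensitivity and cohort-level comparisons.

#' Assign drug-sensitivity labels from IC50 quartiles
#'
#' Classifies samples per drug: IC50 strictly below the 25th percentile
#' (quartile 1) is `HIGH_SENSITIVITY`, strictly above the 75th percentile
#' (quartile 4) is `LOW_SENSITIVITY`, anything else (including exact ties
#' with either quartile) is `INTERMEDIATE`. Quartiles use linear
#' interpolation (type 7) by default.
#'
#' @param ic50 long data.frame with columns `sample_id`, `drug`, `ic50`.
#' @param drug drug name to stratify on.
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (7 = linear interpolation, 1 = nearest rank).
#' @return A data.frame `sample_id`, `drug`, `ic50`, `label`.
#' @examples
#' tab <- data.frame(sample_id = letters[1:8], drug = "olaparib",
#'                   ic50 = 1:8)
#' assignSensitivity(tab, "olaparib")
#' @export
assignSensitivity <- function(ic50, drug, quantile_type = 7) {
    tab <- ic50[ic50$drug == drug, , drop = FALSE]
    if (nrow(tab) < 8L)
        stop("need >= 8 samples with IC50 for drug '", drug, "'")
    if (length(unique(tab$ic50)) == 1L)
        stop("all IC50 values identical for drug '", drug,
             "': quartiles degenerate")
    q <- quantile(tab$ic50, c(0.25, 0.75), type = quantile_type,
                  names = FALSE)
    tab$label <- ifelse(tab$ic50 < q[1L], "HIGH_SENSITIVITY",
                 ifelse(tab$ic50 > q[2L], "LOW_SENSITIVITY",
                        "INTERMEDIATE"))
    rownames(tab) <- NULL
    tab
}

#' Combine per-drug labels into a drug-family label
#'
#' A sample joins a family sensitivity group only when its per-drug label
#' is identical (and not `INTERMEDIATE`) across all of the family's
#' drugs; otherwise it is `INTERMEDIATE` for the family.
#'
#' @param labels data.frame as returned by [assignSensitivity()] (rbind
#'   over the family's drugs).
#' @return A data.frame `sample_id`, `label`.
#' @export
combineFamilyLabels <- function(labels) {
    sp <- split(labels$label, labels$sample_id)
    lab <- vapply(sp, function(x) {
        u <- unique(x)
        if (length(u) == 1L && u != "INTERMEDIATE") u else "INTERMEDIATE"
    }, character(1L))
    data.frame(sample_id = names(lab), label = unname(lab))
}

#' Two-group comparison with a normality gate
#'
#' Compares a variable between two groups the way cohort descriptives are
#' reported: a Shapiro-Wilk normality check per group gates the choice of
#' test — a two-sided t-test when both groups look normal (p >= 0.05),
#' otherwise a two-sided Wilcoxon rank-sum test. A constant group (where
#' Shapiro-Wilk is undefined) falls back to the rank test with a warning.
#'
#' @param values_g1,values_g2 numeric vectors (>= 3 values each).
#' @param variable label carried into the result.
#' @return A one-row data.frame: `variable`, `normality_p_g1`,
#'   `normality_p_g2`, `test_used` (`"t_test"` or `"wilcoxon"`),
#'   `statistic`, `pvalue`.
#' @export
groupCompare <- function(values_g1, values_g2, variable = "") {
    if (length(values_g1) < 3L || length(values_g2) < 3L)
        stop("each group needs >= 3 values")
    sw <- function(x) tryCatch(shapiro.test(x)$p.value,
                               error = function(e) NA_real_)
    p1 <- sw(values_g1); p2 <- sw(values_g2)
    if (is.na(p1) || is.na(p2)) {
        warning("Shapiro-Wilk undefined for a constant group; ",
                "falling back to the rank test")
        normal <- FALSE
    } else {
        normal <- p1 >= 0.05 && p2 >= 0.05
    }
    ht <- if (normal) t.test(values_g1, values_g2) else
        suppressWarnings(wilcox.test(values_g1, values_g2, exact = FALSE))
    data.frame(variable = variable, normality_p_g1 = p1,
               normality_p_g2 = p2,
               test_used = if (normal) "t_test" else "wilcoxon",
               statistic = unname(ht$statistic), pvalue = ht$p.value)
}

#' Batch group comparisons with BH adjustment
#'
#' Applies [groupCompare()] to every row of a variables-by-samples matrix
#' (for example log2(TPM+1) expression) and adds BH-adjusted p-values
#' across the batch.
#'
#' @param mat numeric matrix, variables in rows.
#' @param groups two-level factor over the columns.
#' @param adjust add a BH-adjusted column (default `TRUE`).
#' @return A data.frame, one row per variable, with `adjusted_p` when
#'   requested.
#' @export
batchGroupCompare <- function(mat, groups, adjust = TRUE) {
    groups <- droplevels(as.factor(groups))
    stopifnot(nlevels(groups) == 2L, ncol(mat) == length(groups))
    i1 <- groups == levels(groups)[1L]
    vars <- rownames(mat)
    if (is.null(vars)) vars <- as.character(seq_len(nrow(mat)))
    out <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i)
        groupCompare(mat[i, i1], mat[i, !i1], variable = vars[i])))
    if (adjust) out$adjusted_p <- bhFdr(out$pvalue)
    out
}

#' Pearson correlation with a two-sided test
#'
#' Product-moment correlation between two numeric vectors (for example a
#' global editing index against deaminase expression), with the standard
#' two-sided t-based p-value.
#'
#' @param x,y equal-length numeric vectors (>= 3 finite values).
#' @return A list with elements `r` and `pvalue`.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3L)
        stop("x and y must have equal length >= 3")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("x and y must be finite")
    if (var(x) == 0 || var(y) == 0)
        stop("zero variance in an input vector")
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), pvalue = ct$p.value)
}
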