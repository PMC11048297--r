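## Beta-binomial statistics: editing level, MLE fits, likelihood-ratio
## differential test, FDR, fold change, DES selection, Alu Editing Index.

#' Per-cell editing level
#'
#' The editing level at a site is the fraction of reads carrying the
#' edited base: `alt / (alt + ref)`.
#'
#' @param alt edited (mismatch) read count(s).
#' @param ref reference (match) read count(s).
#' @return Numeric in \[0,1\]; `NA` with a warning where `alt + ref == 0`
#'   (a missing cell, not a level of zero).
#' @examples
#' editingLevel(5, 95)   # 0.05
#' @export
editingLevel <- function(alt, ref) {
    total <- alt + ref
    if (any(total == 0, na.rm = TRUE))
        warning("zero-total cell(s): editing level undefined, returning NA")
    ifelse(total > 0, alt / total, NA_real_)
}

#' Beta-binomial log-likelihood
#'
#' Exact log-likelihood of counts `k` out of `n` under a beta-binomial
#' with shapes `(alpha, beta)`:
#' `sum_i [ log C(n_i, k_i) + log B(k_i + alpha, n_i - k_i + beta)
#'          - log B(alpha, beta) ]`,
#' evaluated through log-gamma so it is finite for any admissible input.
#'
#' @param alpha,beta positive shape parameters.
#' @param k edited-read counts.
#' @param n total-read counts (`n >= k`).
#' @return Log-likelihood in nats.
#' @export
bbLogLik <- function(alpha, beta, k, n) {
    if (alpha <= 0 || beta <= 0)
        stop("shape parameters must be positive")
    if (any(n < k)) stop("totals must be >= edited counts")
    sum(lchoose(n, k) + lbeta(k + alpha, n - k + beta) -
            lbeta(alpha, beta))
}

## Negative profile log-likelihood (lchoose constant dropped) and its
## analytic gradient in unconstrained coordinates (eta = logit mu,
## tau = log phi), phi = alpha + beta.
.bbNegLL <- function(par, k, n) {
    mu <- plogis(par[1L]); phi <- exp(par[2L])
    a <- mu * phi; b <- (1 - mu) * phi
    -sum(lbeta(k + a, n - k + b) - lbeta(a, b))
}

.bbNegGrad <- function(par, k, n) {
    mu <- plogis(par[1L]); phi <- exp(par[2L])
    a <- mu * phi; b <- (1 - mu) * phi
    dla <- sum(digamma(k + a) - digamma(n + phi) + digamma(phi) -
                   digamma(a))
    dlb <- sum(digamma(n - k + b) - digamma(n + phi) + digamma(phi) -
                   digamma(b))
    -c((dla - dlb) * phi * mu * (1 - mu), dla * a + dlb * b)
}

.etaBound <- 15       # |logit mu| bound; plogis(15) ~ 3e-7
.tauBounds <- log(c(1e-3, 1e8))  # phi search region

#' Fit a beta-binomial by maximum likelihood
#'
#' Maximizes the beta-binomial likelihood over `(mu, phi)` — mean and
#' precision `phi = alpha + beta` — in unconstrained `(logit mu, log phi)`
#' coordinates with an analytic gradient, initialized by the method of
#' moments and restarted from coarser dispersion values on
#' non-convergence. The search region bounds `mu` away from 0/1 and `phi`
#' in `[1e-3, 1e8]`; estimates landing on the edge (degenerate data such
#' as all-zero edited counts) carry `boundary = TRUE`.
#'
#' @param cells two-column matrix or data.frame of `(alt, total)` counts,
#'   or `alt` as a vector when `total` is given separately.
#' @param total optional total-read vector.
#' @param grad_tol gradient max-norm required at the optimum.
#' @return A [BetaBinFit-class].
#' @examples
#' fitBetaBinomial(cbind(c(5, 8, 2), c(50, 60, 40)))
#' @export
fitBetaBinomial <- function(cells, total = NULL, grad_tol = 1e-6) {
    if (is.null(total)) {
        cells <- as.matrix(cells)
        k <- cells[, 1L]; n <- cells[, 2L]
    } else {
        k <- cells; n <- total
    }
    keep <- !is.na(k) & !is.na(n) & n > 0
    k <- k[keep]; n <- n[keep]
    if (!length(k)) stop("no observed cells with positive total")
    if (any(n < k)) stop("totals must be >= edited counts")

    muHat <- sum(k) / sum(n)
    mu0 <- min(max(muHat, 1e-4), 1 - 1e-4)
    lev <- k / n
    v <- if (length(k) > 1L) var(lev) else 0
    vBin <- mu0 * (1 - mu0) * mean(1 / n)
    rho0 <- if (!is.finite(v) || v <= vBin) 0.02 else
        min(0.9, max(0.001, (v - vBin) / (mu0 * (1 - mu0))))
    starts <- lapply(c(rho0, 0.005, 0.05, 0.3), function(r)
        c(qlogis(mu0), log((1 - r) / r)))

    lower <- c(-.etaBound, .tauBounds[1L])
    upper <- c(.etaBound, .tauBounds[2L])
    polish <- function(o) {
        ## L-BFGS-B stops on function decrease; a BFGS pass from its
        ## solution drives the gradient to the requested tolerance when
        ## the optimum is interior
        if (any(abs(o$par - lower) < 1e-6 | abs(o$par - upper) < 1e-6))
            return(o)
        p <- tryCatch(
            optim(o$par, .bbNegLL, .bbNegGrad, k = k, n = n,
                  method = "BFGS",
                  control = list(maxit = 200L, reltol = 1e-15)),
            error = function(e) NULL)
        if (!is.null(p) && p$value <= o$value &&
            all(p$par > lower & p$par < upper)) p else o
    }
    best <- NULL
    for (s in starts) {
        o <- tryCatch(
            optim(s, .bbNegLL, .bbNegGrad, k = k, n = n,
                  method = "L-BFGS-B", lower = lower, upper = upper,
                  control = list(maxit = 500L, factr = 1e4)),
            error = function(e) NULL)
        if (is.null(o)) next
        o <- polish(o)
        if (is.null(best) || o$value < best$value) best <- o
        atEdge <- any(abs(o$par - lower) < 1e-6 |
                          abs(o$par - upper) < 1e-6) ||
            exp(o$par[2L]) >= 1e6
        g <- .bbNegGrad(o$par, k, n)
        if (o$convergence == 0 && (atEdge || max(abs(g)) <= grad_tol))
            break
    }
    if (is.null(best)) stop("beta-binomial fit failed from every start")
    par <- best$par
    ## near the binomial limit (phi -> Inf) the surface is flat in tau and
    ## quasi-Newton steps stall; refine the mean alone in that direction
    o1 <- optimize(function(e) .bbNegLL(c(e, par[2L]), k, n),
                   interval = pmin(pmax(par[1L] + c(-1, 1), -.etaBound),
                                   .etaBound), tol = 1e-12)
    if (o1$objective <= best$value) {
        par[1L] <- o1$minimum
        best$value <- o1$objective
    }
    atEdge <- abs(par - lower) < 1e-6 | abs(par - upper) < 1e-6
    boundary <- any(atEdge) || exp(par[2L]) >= 1e6  # binomial limit
    g <- .bbNegGrad(par, k, n)
    ## Newton cleanup to the requested gradient tolerance (2x2 Hessian by
    ## finite differences of the analytic gradient)
    if (!boundary) {
        for (it in 1:8) {
            if (max(abs(g)) <= grad_tol) break
            h <- 1e-6
            H <- cbind((.bbNegGrad(par + c(h, 0), k, n) - g) / h,
                       (.bbNegGrad(par + c(0, h), k, n) - g) / h)
            step <- tryCatch(solve((H + t(H)) / 2, g),
                             error = function(e) NULL)
            if (is.null(step) || !all(is.finite(step))) break
            cand <- par - step
            if (any(cand <= lower) || any(cand >= upper)) break
            val <- .bbNegLL(cand, k, n)
            if (!is.finite(val) || val > best$value + 1e-9) break
            par <- cand
            best$value <- val
            g <- .bbNegGrad(par, k, n)
        }
    }
    converged <- best$convergence == 0 &&
        (boundary || max(abs(g)) <= grad_tol)
    mu <- plogis(par[1L]); phi <- exp(par[2L])
    new("BetaBinFit", alpha = mu * phi, beta = (1 - mu) * phi, mean = mu,
        loglik = bbLogLik(mu * phi, (1 - mu) * phi, k, n),
        converged = converged, boundary = boundary)
}

#' Beta-binomial likelihood-ratio test for differential editing
#'
#' Two-group likelihood-ratio test on per-sample (edited, total) counts:
#' the null model fits a single beta-binomial to the pooled cells
#' (2 parameters); the alternative fits each group independently
#' (4 parameters). The statistic `llr = 2 (ll_g1 + ll_g2 - ll_null)`,
#' clamped at zero, is referred to a chi-square upper tail with `df`
#' degrees of freedom (default 2, the parameter-count difference).
#'
#' @param cells_g1,cells_g2 two-column `(alt, total)` matrices, one row
#'   per sample; `NA`/zero-total rows are dropped. Each group needs at
#'   least 2 observed cells.
#' @param df chi-square degrees of freedom.
#' @return A list: `llr`, `pvalue`, `fit_g1`, `fit_g2`, `fit_null`, `df`.
#' @export
reditLlrTest <- function(cells_g1, cells_g2, df = 2) {
    cells_g1 <- .observedCells(cells_g1)
    cells_g2 <- .observedCells(cells_g2)
    if (nrow(cells_g1) < 2L || nrow(cells_g2) < 2L)
        stop("each group needs >= 2 observed cells")
    f1 <- fitBetaBinomial(cells_g1)
    f2 <- fitBetaBinomial(cells_g2)
    f0 <- fitBetaBinomial(rbind(cells_g1, cells_g2))
    llr <- max(0, 2 * (f1@loglik + f2@loglik - f0@loglik))
    list(llr = llr, pvalue = pchisq(llr, df = df, lower.tail = FALSE),
         fit_g1 = f1, fit_g2 = f2, fit_null = f0, df = df)
}

.observedCells <- function(cells) {
    cells <- as.matrix(cells)
    cells[!is.na(cells[, 1L]) & !is.na(cells[, 2L]) & cells[, 2L] > 0, ,
          drop = FALSE]
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard BH step-up adjustment (monotone, order-preserving), delegated
#' to [stats::p.adjust()].
#'
#' @param pvalues numeric p-values in (0, 1\].
#' @return Adjusted q-values, in the input order; empty in, empty out.
#' @export
bhFdr <- function(pvalues) {
    if (!length(pvalues)) return(numeric())
    if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
        stop("p-values must lie in (0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Log fold change of mean editing levels
#'
#' `log2((mean_g1 + pseudo) / (mean_g2 + pseudo))` with a small
#' pseudocount guarding zero means; two zero means give exactly 0.
#'
#' @param mean_g1,mean_g2 mean editing levels in \[0,1\].
#' @param pseudo pseudocount (default 1e-4).
#' @return log2 fold change(s).
#' @export
foldChange <- function(mean_g1, mean_g2, pseudo = 1e-4) {
    ifelse(mean_g1 == 0 & mean_g2 == 0, 0,
           log2((mean_g1 + pseudo) / (mean_g2 + pseudo)))
}

#' Select differentially edited sites
#'
#' Applies the DES conjunction — `pvalue < p_max`, `fdr < fdr_max` and
#' `|fold change| >= fc_min` — and assigns a direction: group 1 is the
#' low-sensitivity group by convention, so a positive delta
#' (`mean_g1 - mean_g2`) means the site is over-edited in low-sensitivity
#' samples (`LOW_SENSITIVITY`), otherwise `HIGH_SENSITIVITY`.
#'
#' @param results data.frame with columns `pvalue`, `fdr`, `log2fc`,
#'   `delta` (e.g. from [diffEditing()]).
#' @param p_max,fdr_max,fc_min DES thresholds (defaults 0.05, 0.1, 2.5).
#' @param fc_scale `"log2"` (threshold on `|log2fc|`, the default) or
#'   `"ratio"` (threshold on the raw ratio `2^|log2fc|`).
#' @return `results` with columns `is_des` and `direction` set.
#' @export
selectDes <- function(results, p_max = 0.05, fdr_max = 0.1, fc_min = 2.5,
                      fc_scale = c("log2", "ratio")) {
    fc_scale <- match.arg(fc_scale)
    mag <- abs(results$log2fc)
    fcOk <- if (fc_scale == "log2") mag >= fc_min else 2^mag >= fc_min
    results$is_des <- !is.na(results$pvalue) &
        results$pvalue < p_max & results$fdr < fdr_max & fcOk
    results$direction <- ifelse(results$delta > 0, "LOW_SENSITIVITY",
                                "HIGH_SENSITIVITY")
    results
}

#' Differential-editing scan over an EditingExperiment
#'
#' Runs [reditLlrTest()] at every site between two sample groups, computes
#' MLE group means, log2 fold change (of the MLE-mean ratio), delta
#' (`mean_g1 - mean_g2`, the difference of the fitted `alpha/(alpha+beta)`
#' ratios), BH FDR across tested sites, and the DES selection. Sites with
#' fewer than two observed cells in either group are reported as skipped
#' and excluded from the FDR (NO_COVERAGE cells are dropped per group,
#' never imputed).
#'
#' @param ee an [EditingExperiment].
#' @param groups factor of length `ncol(ee)` with exactly two levels; the
#'   first level is group 1 (by convention the low-sensitivity group).
#'   Defaults to `colData(ee)$group`.
#' @inheritParams selectDes
#' @param pseudo fold-change pseudocount.
#' @param df chi-square degrees of freedom for the LLR.
#' @return A data.frame with one row per site: `site`, `n_g1`, `n_g2`,
#'   `llr`, `pvalue`, `fdr`, `mean_g1`, `mean_g2`, `log2fc`, `delta`,
#'   `direction`, `is_des`, `skipped`.
#' @export
diffEditing <- function(ee, groups = NULL, p_max = 0.05, fdr_max = 0.1,
                        fc_min = 2.5, fc_scale = c("log2", "ratio"),
                        pseudo = 1e-4, df = 2) {
    fc_scale <- match.arg(fc_scale)
    if (is.null(groups)) groups <- colData(ee)$group
    groups <- as.factor(groups)
    if (nlevels(droplevels(groups)) != 2L)
        stop("'groups' must have exactly two levels")
    groups <- droplevels(groups)
    g1 <- which(groups == levels(groups)[1L])
    g2 <- which(groups == levels(groups)[2L])
    alt <- altReads(ee); tot <- totalReads(ee)

    res <- lapply(seq_len(nrow(ee)), function(i) {
        c1 <- .observedCells(cbind(alt[i, g1], tot[i, g1]))
        c2 <- .observedCells(cbind(alt[i, g2], tot[i, g2]))
        if (nrow(c1) < 2L || nrow(c2) < 2L)
            return(data.frame(
                n_g1 = nrow(c1), n_g2 = nrow(c2), llr = NA_real_,
                pvalue = NA_real_, mean_g1 = NA_real_, mean_g2 = NA_real_,
                log2fc = NA_real_, delta = NA_real_,
                skipped = "fewer than 2 observed cells in a group"))
        t <- reditLlrTest(c1, c2, df = df)
        m1 <- t$fit_g1@mean; m2 <- t$fit_g2@mean
        data.frame(n_g1 = nrow(c1), n_g2 = nrow(c2), llr = t$llr,
                   pvalue = t$pvalue, mean_g1 = m1, mean_g2 = m2,
                   log2fc = foldChange(m1, m2, pseudo), delta = m1 - m2,
                   skipped = NA_character_)
    })
    res <- do.call(rbind, res)
    res <- cbind(site = siteIds(ee), res)
    res$fdr <- NA_real_
    tested <- is.na(res$skipped)
    res$fdr[tested] <- bhFdr(res$pvalue[tested])
    res <- selectDes(res, p_max, fdr_max, fc_min, fc_scale)
    res$is_des[!tested] <- FALSE
    res$direction[!tested] <- NA_character_
    rownames(res) <- NULL
    res[c("site", "n_g1", "n_g2", "llr", "pvalue", "fdr", "mean_g1",
          "mean_g2", "log2fc", "delta", "direction", "is_des", "skipped")]
}

#' Alu Editing Index
#'
#' Global editing activity per sample: the pooled ratio of edited
#' (discordant) reads to total reads over all sites falling in Alu repeat
#' intervals — `sum(alt) / sum(alt + ref)`, not a mean of per-site ratios.
#' Sites outside every Alu interval contribute to neither numerator nor
#' denominator.
#'
#' @param ee an [EditingExperiment].
#' @param repeats `GRanges` with metadata column `repeat_class` (from
#'   [readBedRepeats()] or [simulateRepeats()]).
#' @param samples samples to compute (default all).
#' @return A data.frame: `sample_id`, `aei` (`NA` with a warning for a
#'   sample with zero Alu-site reads), `n_sites_used`,
#'   `total_reads_used`.
#' @export
computeAei <- function(ee, repeats, samples = colnames(ee)) {
    alu <- repeats[mcols(repeats)$repeat_class == "ALU"]
    ## sites and annotation may cover different chromosome universes
    inAlu <- suppressWarnings(
        overlapsAny(rowRanges(ee), alu, ignore.strand = TRUE))
    alt <- altReads(ee)[inAlu, , drop = FALSE]
    tot <- totalReads(ee)[inAlu, , drop = FALSE]
    out <- lapply(samples, function(s) {
        ok <- !is.na(tot[, s])
        reads <- sum(tot[ok, s])
        data.frame(sample_id = s,
                   aei = if (reads > 0) sum(alt[ok, s]) / reads
                         else NA_real_,
                   n_sites_used = sum(ok), total_reads_used = reads)
    })
    out <- do.call(rbind, out)
    if (anyNA(out$aei))
        warning("sample(s) with zero Alu-site reads: AEI undefined")
    out
}
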