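# Independent oracles used to cross-check the implementation. These are
# deliberately naive: direct definitions, enumeration and quadrature.

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j >= i} m p_(j)/j,
# capped at 1, mapped back to input order.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- pmin(1, m * ps / seq_len(m))
    q <- rev(cummin(rev(q)))
    out <- numeric(m)
    out[o] <- q
    out
}

# Product-limit estimator by enumeration; ties resolved events-first.
kmOracle <- function(times, events) {
    ts <- sort(unique(times))
    atRisk <- length(times)
    surv <- 1
    out <- data.frame(time = ts, n_risk = NA_real_, n_event = NA_real_,
                      survival = NA_real_)
    for (i in seq_along(ts)) {
        d <- sum(times == ts[i] & events == 1)
        c <- sum(times == ts[i] & events == 0)
        out$n_risk[i] <- atRisk
        out$n_event[i] <- d
        if (d > 0) surv <- surv * (1 - d / atRisk)
        out$survival[i] <- surv
        atRisk <- atRisk - d - c
    }
    out
}

# Two-sample log-rank by direct O-E / hypergeometric-variance summation.
logrankOracle <- function(labels, times, events) {
    labels <- as.factor(labels)
    g1 <- levels(labels)[1L]
    ts <- sort(unique(times[events == 1]))
    O <- E <- V <- 0
    for (t in ts) {
        atRisk <- times >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & labels == g1)
        d <- sum(times == t & events == 1)
        d1 <- sum(times == t & events == 1 & labels == g1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
}

# Beta-binomial log-likelihood of one (k, n) cell by numerical quadrature
# of the binomial-beta mixture.
quadLogLik <- function(alpha, beta, k, n) {
    f <- function(p) dbinom(k, n, p) * dbeta(p, alpha, beta)
    log(integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0,
                  subdivisions = 2000L)$value)
}

# Beta-binomial sampler used where tests need draws outside the package
# generator.
rBetaBinom <- function(nCells, size, mu, rho) {
    phi <- (1 - rho) / rho
    rbinom(nCells, size, rbeta(nCells, mu * phi, (1 - mu) * phi))
}
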