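#' Asymptotic Cramer-von Mises distribution function
#'
#' Series expansion of the limiting distribution of the Cramer-von Mises
#' statistic (four terms, modified Bessel function of the second kind).
#'
#' @param q quantile.
#' @return P(W <= q).
#' @keywords internal
pcramer <- function(q, eps = 1e-5) {
    # the expansion loses accuracy (and monotonicity) far in the upper
    # tail; beyond q = 3 the CDF is 1 to 7 digits
    if (length(q) == 1L && q >= 3) return(1)
    logEps <- log(eps)
    y <- vapply(0:3, function(k) {
        z <- gamma(k + 0.5) * sqrt(4 * k + 1) /
            (gamma(k + 1) * pi^1.5 * sqrt(q))
        u <- (4 * k + 1)^2 / (16 * q)
        ifelse(u > -logEps, 0, z * exp(-u) * besselK(x = u, nu = 0.25))
    }, numeric(length(q)))
    if (is.matrix(y)) rowSums(y) else sum(y)
}

#' Heidelberger-Welch stationarity test
#'
#' Computes the Cramer-von Mises statistic of the standardised
#' cumulative-sum (Brownian-bridge) functional of the series, with the
#' long-run variance estimated by the spectral density at frequency zero
#' (autoregressive fit, order chosen by AIC, on the first half of the
#' series). If the test rejects at \code{alpha}, the leading 10\% of the
#' series is discarded and the test repeated, up to a maximum discard of
#' 50\%.
#'
#' @param series numeric vector, length >= 100, finite values.
#' @param alpha significance level (default 0.01).
#' @return list with \code{pvalue} (of the final test), \code{nDiscard}
#'   (leading iterations discarded), and \code{passed}.
#' @export
hwStationarityTest <- function(series, alpha = 0.01) {
    stopifnot(is.numeric(series), length(series) >= 100L)
    if (any(!is.finite(series)))
        stop("series contains non-finite values")
    n <- length(series)
    if (sd(series) == 0)
        return(list(pvalue = 1, nDiscard = 0L, passed = TRUE))
    S0 <- hwSpectralVariance(series)
    pv <- NA_real_
    for (frac in seq(0, 0.5, by = 0.1)) {
        nDrop <- floor(frac * n)
        pv <- hwCvmPValue(series[(nDrop + 1L):n], S0)
        if (pv > alpha)
            return(list(pvalue = pv, nDiscard = nDrop, passed = TRUE))
    }
    list(pvalue = pv, nDiscard = floor(0.5 * n), passed = FALSE)
}

#' Long-run variance for the stationarity test
#'
#' Spectral density at frequency zero, estimated on the first half of the
#' series by an autoregressive fit with AIC-chosen order. The half is
#' linearly detrended first (as spectrum estimation conventionally does),
#' so a deterministic drift shows up in the bridge statistic instead of
#' disappearing into the variance estimate.
#' @keywords internal
hwSpectralVariance <- function(series) {
    n <- length(series)
    half <- series[seq_len(n %/% 2L)]
    tt <- seq_along(half)
    half <- half - (coef(lm0 <- stats::lm(half ~ tt))[1] + coef(lm0)[2] * tt)
    S0 <- tryCatch({
        fit <- ar(half, aic = TRUE, order.max = min(30L, length(half) - 1L))
        if (length(fit$ar)) fit$var.pred / (1 - sum(fit$ar))^2 else fit$var.pred
    }, error = function(e) var(half))
    if (!is.finite(S0) || S0 <= 0) S0 <- var(series)
    S0
}

#' One application of the Cramer-von Mises stationarity test
#'
#' The p-value of the standardised cumulative-sum (Brownian-bridge)
#' statistic on one series segment, given the long-run variance. This is
#' the test whose significance level is \code{alpha};
#' \code{\link{hwStationarityTest}} applies it repeatedly while discarding
#' leading segments.
#'
#' @param series numeric vector.
#' @param S0 long-run variance; estimated from the series when NULL.
#' @return p-value.
#' @export
hwCvmPValue <- function(series, S0 = NULL) {
    if (is.null(S0)) S0 <- hwSpectralVariance(series)
    m <- length(series)
    B <- cumsum(series) - mean(series) * seq_len(m)
    cvm <- sum(B^2 / (m * S0)) / m
    max(0, 1 - pcramer(cvm))
}

#' Chain-management protocol for one gene cluster
#'
#' Runs the sampler, applies the Heidelberger-Welch stationarity test to the
#' marginal log-posterior summed over groups, removes any extra burn-in the
#' test estimates, and -- if stationarity is rejected at \code{alpha} --
#' discards the whole output and reruns with a fresh (deterministically
#' derived) seed, up to three runs in total. If any testable gene's
#' gene-level p-value falls below 0.1, a second independent chain is run
#' through the same protocol and all estimates are recomputed on the
#' concatenated post burn-in draws.
#'
#' @param cluster a \linkS4class{GeneCluster}.
#' @param prior a \linkS4class{PriorSpec}.
#' @param groups factor of group membership per sample.
#' @param niter,burnin,allocationScale passed to the sampler.
#' @param seed base seed for this cluster; run and chain seeds derive from
#'   it deterministically.
#' @param alpha significance level of the stationarity test (default 0.01).
#' @param maxRuns maximum number of full restarts (default 3).
#' @param sampleFun the chain-running function; replaceable for testing the
#'   protocol itself (must have the signature of \code{\link{runGeneMCMC}}).
#' @return list with \code{chains} (a \linkS4class{ClusterChains}, or NULL
#'   when no run converged) and \code{report} (a
#'   \linkS4class{ConvergenceReport}).
#' @export
chainProtocol <- function(cluster, prior, groups, niter = 10000,
                          burnin = 2000, seed = 1L, alpha = 0.01,
                          maxRuns = 3L, allocationScale = "pi",
                          sampleFun = runGeneMCMC) {
    runOne <- function(chainId) {
        for (run in seq_len(maxRuns)) {
            s <- deriveSeed(seed, chainId, run)
            chains <- sampleFun(cluster, prior, groups, niter = niter,
                                burnin = burnin, seed = s,
                                allocationScale = allocationScale)
            hw <- hwStationarityTest(rowSums(chains@logPosterior),
                                     alpha = alpha)
            if (hw$passed) {
                chains <- trimChains(chains, hw$nDiscard)
                return(list(chains = chains, hw = hw, reruns = run - 1L))
            }
        }
        list(chains = NULL, hw = hw, reruns = maxRuns)
    }
    first <- runOne(1L)
    if (is.null(first$chains)) {
        return(list(chains = NULL, report = new("ConvergenceReport",
            hwPValue = first$hw$pvalue, extraBurnIn = 0L,
            nReruns = as.integer(first$reruns), converged = FALSE,
            secondChainRun = FALSE)))
    }
    report <- new("ConvergenceReport",
        hwPValue = first$hw$pvalue,
        extraBurnIn = as.integer(first$hw$nDiscard),
        nReruns = as.integer(first$reruns),
        converged = TRUE, secondChainRun = FALSE)
    chains <- first$chains
    # second-chain rule: a small gene-level p-value triggers an independent
    # chain, guarding against false positives driven by poor mixing
    if (nlevels(as.factor(groups)) >= 2L && length(chains@genes)) {
        minP <- suppressWarnings(min(vapply(chains@genes, function(g) {
            piT <- piBarTChains(chains, g)
            p <- if (length(piT) == 2L)
                geneLevelTest(piT[[1]], piT[[2]])$pvalue
            else multigroupTest(piT)$pvalue
            if (is.na(p)) Inf else p
        }, numeric(1))))
        if (is.finite(minP) && minP < 0.1) {
            second <- runOne(2L)
            if (!is.null(second$chains)) {
                chains <- bindChains(chains, second$chains)
                report@secondChainRun <- TRUE
            }
        }
    }
    list(chains = chains, report = report)
}

#' Deterministic seed derivation
#'
#' Seeds for reruns and second chains derive from the master seed so the
#' whole pipeline is reproducible; all values stay below 2^31.
#' @keywords internal
deriveSeed <- function(seed, chainId = 1L, run = 1L, clusterId = 0L) {
    ((as.numeric(seed) %% 65536) * 32749 + clusterId * 7573 +
         chainId * 911 + run * 7919) %% 2147483629 + 1
}
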