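#' Posterior mode and covariance of a set of draws
#'
#' The per-coordinate mode is the maximiser of a Gaussian-kernel density
#' estimate (Silverman's rule bandwidth) of the marginal draws; the
#' covariance is the sample covariance of the draws. A coordinate with zero
#' variance gets its constant value as mode and a variance floored at
#' 1e-12. With \code{useMode = FALSE} the posterior mean is used instead.
#'
#' @param draws numeric matrix, iterations x coordinates (R >= 1000
#'   recommended for a stable mode).
#' @param useMode use the KDE mode (default) or the mean.
#' @return list with \code{center} (vector) and \code{cov} (matrix).
#' @export
posteriorModeCov <- function(draws, useMode = TRUE) {
    draws <- as.matrix(draws)
    K <- ncol(draws)
    center <- numeric(K)
    for (k in seq_len(K)) {
        x <- draws[, k]
        if (sd(x) == 0 || !useMode) {
            center[k] <- mean(x)
        } else {
            d <- density(x)
            center[k] <- d$x[which.max(d$y)]
        }
    }
    S <- cov(draws)
    diag(S) <- pmax(diag(S), 1e-12)
    list(center = center, cov = S)
}

#' Wald statistic with pseudo-inverse fallback
#' @keywords internal
waldChisqP <- function(w, S) {
    inv <- tryCatch(solve(S), error = function(e) NULL)
    df <- length(w)
    if (is.null(inv) || rcond(S) < 1e-12) {
        inv <- MASS::ginv(S)
        df <- qr(S)$rank
        if (df < 1L) return(NA_real_)
    }
    stat <- drop(t(w) %*% inv %*% w)
    pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Gene-level multivariate Wald test
#'
#' The posterior of \eqn{\omega = \bar\pi^{T,A} - \bar\pi^{T,B}} is
#' approximated by a normal with the posterior mode and covariance of the
#' paired chains. Because the K components of \eqn{\omega} sum to zero, one
#' transcript coordinate is dropped; the test statistic
#' \eqn{\hat\omega_{-k'} \hat\Sigma^{-1}_{-k'} \hat\omega_{-k'}^T} is
#' referred to a chi-square with K-1 degrees of freedom, and the returned
#' p-value is the arithmetic mean over all K choices of the dropped
#' coordinate. Singular covariances use a Moore-Penrose pseudo-inverse with
#' rank-adjusted degrees of freedom. Chains of unequal length are paired by
#' truncating the longer one.
#'
#' @param piTA,piTB matrices of per-iteration mean relative expression
#'   draws (iterations x K) for the two groups.
#' @param useMode use KDE posterior modes (default) or means.
#' @return list with \code{pvalue}, \code{omegaHat}, \code{omegaCov}.
#' @export
geneLevelTest <- function(piTA, piTB, useMode = TRUE) {
    K <- ncol(piTA)
    if (is.null(K) || K < 2L || ncol(piTB) != K)
        return(list(pvalue = NA_real_, omegaHat = NULL, omegaCov = NULL))
    R <- min(nrow(piTA), nrow(piTB))
    omega <- piTA[seq_len(R), , drop = FALSE] -
        piTB[seq_len(R), , drop = FALSE]
    sm <- posteriorModeCov(omega, useMode = useMode)
    ps <- vapply(seq_len(K), function(kp)
        waldChisqP(sm$center[-kp], sm$cov[-kp, -kp, drop = FALSE]),
        numeric(1))
    list(pvalue = mean(ps, na.rm = TRUE), omegaHat = sm$center,
         omegaCov = sm$cov)
}

#' Transcript-level univariate Wald test
#'
#' For each transcript the marginal posterior of \eqn{\omega_k} is
#' approximated by a normal with the posterior mode and variance of its
#' draws; the squared standardised mode is referred to a chi-square with 1
#' degree of freedom. A zero-variance coordinate yields a missing p-value.
#'
#' @param omegaDraws matrix of \eqn{\omega} draws (iterations x K), e.g.
#'   the iteration-wise difference of the two groups' expression chains.
#' @param useMode use KDE posterior modes (default) or means.
#' @return data.frame with \code{omega_hat}, \code{omega_var}, \code{pvalue}.
#' @export
transcriptLevelTest <- function(omegaDraws, useMode = TRUE) {
    omegaDraws <- as.matrix(omegaDraws)
    K <- ncol(omegaDraws)
    out <- data.frame(omega_hat = numeric(K), omega_var = numeric(K),
                      pvalue = numeric(K))
    for (k in seq_len(K)) {
        x <- omegaDraws[, k]
        v <- var(x)
        if (v == 0) {
            out$omega_hat[k] <- x[1]
            out$omega_var[k] <- 0
            out$pvalue[k] <- NA_real_
            next
        }
        m <- if (useMode) {
            d <- density(x)
            d$x[which.max(d$y)]
        } else mean(x)
        out$omega_hat[k] <- m
        out$omega_var[k] <- v
        out$pvalue[k] <- pchisq(m^2 / v, df = 1, lower.tail = FALSE)
    }
    out
}

#' Multi-group Wald test (3 or more conditions)
#'
#' Contrasts \eqn{\omega^{(g)} = \bar\pi^{T,g} - \bar\pi^{T,G}} against the
#' last group are stacked, one transcript coordinate dropped from every
#' contrast, and the joint Wald statistic referred to a chi-square with
#' (G-1)(K-1) degrees of freedom; as in the two-group test, the returned
#' p-value averages over the K choices of dropped coordinate.
#'
#' @param piTList list of G >= 2 matrices of expression draws
#'   (iterations x K).
#' @param useMode use KDE posterior modes (default) or means.
#' @return list with \code{pvalue}.
#' @export
multigroupTest <- function(piTList, useMode = TRUE) {
    G <- length(piTList)
    stopifnot(G >= 2L)
    K <- ncol(piTList[[1]])
    if (K < 2L) return(list(pvalue = NA_real_))
    R <- min(vapply(piTList, nrow, integer(1)))
    ref <- piTList[[G]][seq_len(R), , drop = FALSE]
    contrasts <- lapply(seq_len(G - 1L), function(g)
        piTList[[g]][seq_len(R), , drop = FALSE] - ref)
    ps <- vapply(seq_len(K), function(kp) {
        stacked <- do.call(cbind, lapply(contrasts, function(m)
            m[, -kp, drop = FALSE]))
        sm <- posteriorModeCov(stacked, useMode = useMode)
        waldChisqP(sm$center, sm$cov)
    }, numeric(1))
    list(pvalue = mean(ps, na.rm = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over the non-missing p-values; missing entries stay missing
#' and do not count towards the family size.
#'
#' @param p numeric vector of p-values (may contain NA).
#' @return adjusted p-values, elementwise >= the input, capped at 1.
#' @export
adjustBH <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- p.adjust(p[ok], method = "BH")
    out
}

#' Conservative gene score (dominant-transcript inversion)
#'
#' The adjusted p-value is kept as is when the dominant transcript (argmax
#' of the per-group posterior-mode mean relative expression) changes
#' between the two conditions, and inflated to its square root when it does
#' not.
#'
#' @param padj adjusted p-value(s) in [0,1].
#' @param dominantChanged logical, same length.
#' @return numeric score(s), always >= \code{padj}.
#' @export
conservativeScore <- function(padj, dominantChanged) {
    ifelse(dominantChanged, padj, sqrt(padj))
}

#' Conservative transcript score
#'
#' The maximum of the transcript-level and gene-level adjusted p-values: a
#' transcript can only be called if its gene is also significant. Missing
#' gene p-value gives a missing score.
#'
#' @param padjTranscript,padjGene adjusted p-values in [0,1].
#' @return numeric score(s).
#' @export
maxGeneScore <- function(padjTranscript, padjGene) {
    ifelse(is.na(padjGene), NA_real_, pmax(padjTranscript, padjGene))
}

#' DTU effect-size measure
#'
#' The sum, over the two most expressed transcripts (largest mean relative
#' expression averaged across both groups; ties broken by the lowest
#' index), of the absolute between-group difference in mean relative
#' expression. Ranges from 0 (identical proportions) to 2 (a complete
#' isoform switch).
#'
#' @param piA,piB simplex vectors of mean relative transcript expression in
#'   the two groups.
#' @return numeric in [0, 2]; missing when K = 1.
#' @export
dtuMeasure <- function(piA, piB) {
    stopifnot(length(piA) == length(piB))
    K <- length(piA)
    if (K < 2L) return(NA_real_)
    avg <- (piA + piB) / 2
    sel <- order(-avg)[1:2]  # stable: ties keep the lowest index
    sum(abs(piA[sel] - piB[sel]))
}
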