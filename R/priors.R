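#' Dirichlet-multinomial log-likelihood
#'
#' Multinomial normalising constants are omitted (they do not depend on the
#' parameters).
#'
#' @param counts integer matrix, transcripts x samples.
#' @param alpha positive Dirichlet parameter vector (length = nrow(counts)).
#' @return scalar log-likelihood over all samples.
#' @keywords internal
dmLogLik <- function(counts, alpha) {
    a0 <- sum(alpha)
    n <- colSums(counts)
    sum(lgamma(a0) - lgamma(n + a0)) +
        sum(lgamma(counts + alpha)) - ncol(counts) * sum(lgamma(alpha))
}

#' Estimate gene-wise Dirichlet-multinomial precisions
#'
#' For each gene, the Dirichlet-multinomial likelihood of the (rounded)
#' estimated transcript counts is maximised over the full parameter vector
#' \eqn{\alpha = \delta_+ \bar\pi} (all samples pooled across groups), and
#' the precision \eqn{\hat\delta_+ = \sum_k \hat\alpha_k} is reported.
#' Optimisation is a 1-D profile search over \eqn{\log\delta_+} (with mean
#' proportions fixed at their pooled estimates) followed by a Nelder-Mead
#' refinement over all \eqn{\log\alpha_k}. Precisions are constrained to
#' [1e-2, 1e6]; genes whose estimate hits a bound are excluded (set to NA),
#' as are genes with fewer than two transcripts or all-zero counts.
#'
#' @param countsList named list of numeric matrices (transcripts x samples),
#'   one per gene.
#' @return named numeric vector of precision estimates (NA when excluded).
#' @export
estimatePrecisions <- function(countsList) {
    lb <- 1e-2
    ub <- 1e6
    out <- setNames(rep(NA_real_, length(countsList)), names(countsList))
    for (g in seq_along(countsList)) {
        x <- round(countsList[[g]])
        if (is.null(dim(x)) || nrow(x) < 2L) next
        tot <- sum(x)
        if (tot <= 0) next
        piHat <- rowSums(x) / tot
        piHat <- (piHat + 1e-6) / sum(piHat + 1e-6)
        prof <- function(ld) dmLogLik(x, exp(ld) * piHat)
        op <- optimize(prof, lower = log(lb), upper = log(ub), maximum = TRUE)
        start <- log(exp(op$maximum) * piHat)
        fit <- tryCatch(
            optim(start, function(la) -dmLogLik(x, exp(la)),
                  method = "Nelder-Mead",
                  control = list(maxit = 500, reltol = 1e-10)),
            error = function(e) NULL)
        dp <- if (is.null(fit)) exp(op$maximum) else sum(exp(fit$par))
        if (dp <= lb * 1.05 || dp >= ub * 0.95) next
        out[g] <- dp
    }
    out
}

#' Build a prior specification from gene-wise precision estimates
#'
#' With at least two finite precisions, the informative mode is used:
#' mean and unbiased variance of the log precisions become the
#' N(\code{meanLogPrec}, \code{varLogPrec}) prior for \eqn{\log\delta_+}.
#' Otherwise the vague mode (every \eqn{\log\delta_k} ~ N(0, 100)) is
#' returned with a warning when informative had been impossible.
#'
#' @param precisions numeric vector of gene-wise precision estimates (may
#'   contain NA), or NULL/empty for the vague prior.
#' @param vagueVar variance of the vague component (default 100).
#' @return a \linkS4class{PriorSpec}.
#' @export
buildPrior <- function(precisions = NULL, vagueVar = 100) {
    prec <- precisions[is.finite(precisions) & precisions > 0]
    if (length(prec) >= 2L) {
        lp <- log(prec)
        return(new("PriorSpec", mode = "informative",
                   meanLogPrec = mean(lp), varLogPrec = var(lp),
                   vagueVar = vagueVar))
    }
    if (length(precisions))
        warning("fewer than 2 usable precision estimates; vague prior used")
    new("PriorSpec", mode = "vague", meanLogPrec = 0,
        varLogPrec = NA_real_, vagueVar = vagueVar)
}

#' Read precomputed gene-wise precisions
#'
#' Two-column TSV (gene_id, precision), with or without a header line; an
#' alternative to in-package estimation when precisions come from another
#' tool.
#'
#' @param path path to the TSV.
#' @return named numeric vector of precisions.
#' @export
readPrecisions <- function(path) {
    if (!file.exists(path))
        stop("precision file not found: ", path)
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("precision table needs two columns (gene_id, precision)")
    if (is.na(suppressWarnings(as.numeric(df[1, 2]))))
        df <- df[-1, , drop = FALSE]  # header line
    prec <- as.numeric(df[[2]])
    if (any(!is.finite(prec) | prec <= 0))
        stop("precisions must be positive numbers")
    setNames(prec, as.character(df[[1]]))
}

#' Log prior density of the Dirichlet parameters (log scale)
#'
#' The density of \eqn{(\log\delta_1, ..., \log\delta_K)}. Vague mode:
#' independent N(0, \code{vagueVar}) terms. Informative mode: the prior is
#' specified on \eqn{(\log\delta_1, ..., \log\delta_{K-1}, \log\delta_+)}
#' -- the first K-1 components N(meanLogPrec - log K, vagueVar), the summed
#' precision N(meanLogPrec, varLogPrec) -- and mapped to the K component
#' logs by a change of variables whose Jacobian contributes
#' \eqn{\log\delta_K - \log\delta_+}.
#'
#' @param delta positive numeric vector (natural scale).
#' @param prior a \linkS4class{PriorSpec}.
#' @return scalar log density.
#' @export
logPriorDensity <- function(delta, prior) {
    if (any(!is.finite(delta) | delta <= 0))
        stop("delta must be positive and finite")
    K <- length(delta)
    ld <- log(delta)
    if (prior@mode == "vague")
        return(sum(dnorm(ld, 0, sqrt(prior@vagueVar), log = TRUE)))
    dp <- sum(delta)
    sum(dnorm(ld[-K], prior@meanLogPrec - log(K), sqrt(prior@vagueVar),
              log = TRUE)) +
        dnorm(log(dp), prior@meanLogPrec, sqrt(prior@varLogPrec),
              log = TRUE) +
        ld[K] - log(dp) - logPriorNormConst(prior, K)
}

.priorNormCache <- new.env(parent = emptyenv())

#' Truncation constant of the informative prior
#'
#' The construction draws \eqn{(\log\delta_1,...,\log\delta_{K-1})} and
#' \eqn{\log\delta_+} from normals, which only yields a positive
#' \eqn{\delta_K} on the region \eqn{\delta_+ > \sum_{k<K}\delta_k}; the
#' density is normalised by the probability of that region (analytic at
#' K = 2, memoised fixed-seed Monte Carlo otherwise). The constant does not
#' affect Metropolis ratios; it only matters when the density is evaluated
#' as a probability density.
#' @keywords internal
logPriorNormConst <- function(prior, K) {
    if (prior@mode == "vague" || K < 2L) return(0)
    if (K == 2L) {
        # P(e^A < e^B), A - B ~ N(-log 2, vagueVar + varLogPrec)
        return(pnorm(log(2) / sqrt(prior@vagueVar + prior@varLogPrec),
                     log.p = TRUE))
    }
    key <- paste(K, signif(prior@meanLogPrec, 12),
                 signif(prior@varLogPrec, 12), signif(prior@vagueVar, 12),
                 sep = "|")
    hit <- get0(key, envir = .priorNormCache)
    if (!is.null(hit)) return(hit)
    seedState <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(seedState))
        assign(".Random.seed", seedState, globalenv()))
    set.seed(174393L)
    n <- 2e5
    S <- rowSums(matrix(exp(rnorm(n * (K - 1L),
                                  prior@meanLogPrec - log(K),
                                  sqrt(prior@vagueVar))), n, K - 1L))
    B <- exp(rnorm(n, prior@meanLogPrec, sqrt(prior@varLogPrec)))
    z <- log(max(mean(S < B), 1e-12))
    assign(key, z, envir = .priorNormCache)
    z
}

#' Sample from the prior on delta
#'
#' Draws \eqn{(\log\delta_1,...,\log\delta_{K-1})} and \eqn{\log\delta_+}
#' from their normal priors and solves for \eqn{\delta_K}; draws violating
#' \eqn{\delta_+ > \sum_{k<K}\delta_k} are rejected (they have zero prior
#' mass). Used to validate the Jacobian-corrected density.
#'
#' @param n number of draws.
#' @param prior a \linkS4class{PriorSpec}.
#' @param K number of transcripts.
#' @return n x K matrix of delta draws (natural scale).
#' @export
rPriorDelta <- function(n, prior, K) {
    out <- matrix(NA_real_, n, K)
    if (prior@mode == "vague") {
        out[] <- exp(rnorm(n * K, 0, sqrt(prior@vagueVar)))
        return(out)
    }
    got <- 0L
    while (got < n) {
        m <- (n - got) * 2L
        dk <- matrix(exp(rnorm(m * (K - 1L), prior@meanLogPrec - log(K),
                               sqrt(prior@vagueVar))), m, K - 1L)
        dp <- exp(rnorm(m, prior@meanLogPrec, sqrt(prior@varLogPrec)))
        rest <- dp - rowSums(dk)
        ok <- which(rest > 0)
        if (length(ok)) {
            take <- head(ok, n - got)
            out[(got + 1L):(got + length(take)), ] <-
                cbind(dk[take, , drop = FALSE], rest[take])
            got <- got + length(take)
        }
    }
    out
}
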