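#' Allocate equivalence-class reads to transcripts (one Gibbs step)
#'
#' For each class j the reads are drawn multinomially over the transcripts
#' of the class, with probabilities proportional to the allocation parameter
#' restricted to the class; in multi-gene classes the probabilities are
#' additionally weighted by the current per-gene read mass. Singleton
#' classes are deterministic. If every allocation probability of a class is
#' zero, the reads are spread uniformly over the class (with a warning).
#'
#' @param classes list of integer vectors (1-based transcript indices).
#' @param f integer vector of class counts for one sample.
#' @param pi numeric simplex vector of transcript proportions (per gene).
#' @param geneOf integer vector assigning each transcript to a gene
#'   (defaults to a single gene).
#' @param geneMass numeric per-gene read mass from the previous sweep
#'   (defaults to large equal masses, i.e. no reweighting).
#' @param effLen effective lengths (needed for \code{scale = "pi_T"}).
#' @param scale allocation parameter: mapping-scale \code{"pi"} (default) or
#'   length-corrected \code{"pi_T"}.
#' @return integer vector of transcript read totals \eqn{X_k}.
#' @export
allocateReads <- function(classes, f, pi, geneOf = rep(1L, length(pi)),
                          geneMass = NULL, effLen = rep(1, length(pi)),
                          scale = c("pi", "pi_T")) {
    scale <- match.arg(scale)
    stopifnot(length(classes) == length(f), all(f >= 0))
    if (is.null(geneMass)) geneMass <- rep(1, max(geneOf))
    cl0 <- lapply(classes, function(cl) as.integer(cl) - 1L)
    .alloc_reads_once(cl0, as.integer(f), as.numeric(pi),
                      as.integer(geneOf) - 1L, as.numeric(geneMass),
                      as.numeric(effLen), scale == "pi_T")
}

#' Gibbs update of sample-level proportions
#'
#' The full conditional of \eqn{\pi^{(i)}} given the allocated transcript
#' totals and the Dirichlet parameters is Dirichlet(\eqn{\delta + X^{(i)}})
#' by multinomial-Dirichlet conjugacy; this draws from it exactly.
#'
#' @param X non-negative numeric vector of transcript totals.
#' @param delta positive Dirichlet parameter vector.
#' @return a simplex draw.
#' @export
gibbsUpdatePi <- function(X, delta) {
    stopifnot(length(X) == length(delta), all(delta > 0), all(X >= 0))
    g <- rgamma(length(X), shape = delta + X, rate = 1)
    if (sum(g) <= 0) g <- rep(1, length(X))
    g / sum(g)
}

#' Length-corrected mean relative transcript expression
#'
#' Converts Dirichlet parameters into the mean mapping proportions
#' \eqn{\bar\pi_k = \delta_k/\delta_+} and then into the mean relative
#' transcript expression \eqn{\bar\pi^T_k \propto \bar\pi_k / l_k},
#' normalised to sum to 1. With equal effective lengths the two scales
#' coincide.
#'
#' @param delta positive vector (or matrix of draws, rows = iterations) of
#'   Dirichlet parameters on the natural scale.
#' @param lengths positive effective lengths \eqn{l_k}.
#' @return simplex vector, or matrix of simplex rows.
#' @export
computePiBarT <- function(delta, lengths) {
    stopifnot(all(lengths > 0))
    if (is.matrix(delta)) {
        pib <- delta / rowSums(delta)
        pt <- sweep(pib, 2, lengths, "/")
        return(pt / rowSums(pt))
    }
    stopifnot(all(delta > 0))
    pib <- delta / sum(delta)
    pt <- pib / lengths
    pt / sum(pt)
}

#' Run the Metropolis-within-Gibbs MCMC for one gene cluster
#'
#' One sweep (a) reallocates every sample's equivalence-class reads given the
#' current proportions, (b) redraws each sample's transcript proportions from
#' their conjugate Dirichlet full conditional, and (c) updates each group's
#' Dirichlet parameters by an adaptive random-walk Metropolis step on the log
#' scale. After the burn-in, the log-\eqn{\delta} draws and the per-group
#' marginal log-posterior \eqn{\log P(\pi|\delta) + \log P(\delta)} (the
#' stationarity-diagnostic target, summed over the cluster's genes) are
#' stored. A fixed seed gives bit-identical output.
#'
#' @param cluster a \linkS4class{GeneCluster}.
#' @param prior a \linkS4class{PriorSpec}.
#' @param groups factor (or character) of group membership, one entry per
#'   sample column of the cluster.
#' @param niter stored iterations after burn-in (paper-scale default 10000).
#' @param burnin initial iterations discarded (default 2000).
#' @param seed integer seed for the chain.
#' @param allocationScale allocate reads on the mapping scale (\code{"pi"},
#'   default, consistent with the multinomial likelihood) or on the
#'   length-corrected expression scale (\code{"pi_T"}).
#' @return a \linkS4class{ClusterChains} object.
#' @export
runGeneMCMC <- function(cluster, prior, groups, niter = 10000,
                        burnin = 2000, seed = 1L,
                        allocationScale = c("pi", "pi_T")) {
    allocationScale <- match.arg(allocationScale)
    stopifnot(is(cluster, "GeneCluster"), is(prior, "PriorSpec"))
    groups <- as.factor(groups)
    if (length(groups) != ncol(cluster@counts))
        stop("groups must have one entry per sample")
    if (any(table(groups) < 1L))
        stop("every group needs at least one sample")
    if (any(table(groups) == 1L))
        warning("group(s) with a single sample: between-sample variability ",
                "is not identifiable there")
    if (sum(cluster@counts) == 0L)
        stop("cluster has no reads")
    if (length(cluster@transcripts) < 2L)
        stop("cluster must have at least 2 transcripts")
    genes <- cluster@genes
    geneIdx <- match(cluster@geneOf, genes)
    grpLevels <- levels(groups)
    set.seed(as.integer(seed %% 2147483647))
    res <- .run_cluster_mcmc(
        lapply(cluster@classes, function(cl) as.integer(cl) - 1L),
        cluster@counts,
        as.integer(geneIdx) - 1L,
        as.integer(groups) - 1L,
        cluster@effLen,
        length(genes), length(grpLevels),
        as.integer(niter), as.integer(burnin),
        if (prior@mode == "informative") 1L else 0L,
        prior@meanLogPrec,
        if (prior@mode == "informative") prior@varLogPrec else 1,
        prior@vagueVar,
        allocationScale == "pi_T")
    if (!res$conserved)
        stop("internal error: read conservation violated during sampling")
    if (res$fallbacks > 0)
        warning(res$fallbacks,
                " class allocation(s) fell back to uniform probabilities")
    kept <- which(vapply(seq_along(genes), function(g)
        sum(geneIdx == g) >= 2L, logical(1)))
    deltaList <- lapply(kept, function(g) {
        byGroup <- res$delta[[g]]
        names(byGroup) <- grpLevels
        byGroup
    })
    names(deltaList) <- genes[kept]
    txList <- lapply(kept, function(g) cluster@transcripts[geneIdx == g])
    elList <- lapply(kept, function(g) cluster@effLen[geneIdx == g])
    names(txList) <- names(elList) <- genes[kept]
    lp <- res$logPosterior
    colnames(lp) <- grpLevels
    acc <- res$acceptance[kept, , drop = FALSE]
    dimnames(acc) <- list(genes[kept], grpLevels)
    new("ClusterChains",
        genes = genes[kept], transcripts = txList, effLen = elList,
        delta = deltaList, logPosterior = lp, acceptance = acc,
        groups = grpLevels, seed = as.integer(seed),
        burnInUsed = as.integer(burnin))
}

#' Drop leading iterations from stored chains
#' @keywords internal
trimChains <- function(chains, nDrop) {
    if (nDrop <= 0L) return(chains)
    keep <- seq(nDrop + 1L, nrow(chains@logPosterior))
    chains@delta <- lapply(chains@delta, function(byGroup)
        lapply(byGroup, function(m) m[keep, , drop = FALSE]))
    chains@logPosterior <- chains@logPosterior[keep, , drop = FALSE]
    chains@burnInUsed <- chains@burnInUsed + as.integer(nDrop)
    chains
}

#' Concatenate the post burn-in draws of two chains
#' @keywords internal
bindChains <- function(a, b) {
    stopifnot(identical(a@genes, b@genes))
    a@delta <- lapply(seq_along(a@delta), function(g)
        lapply(seq_along(a@delta[[g]]), function(r)
            rbind(a@delta[[g]][[r]], b@delta[[g]][[r]])))
    names(a@delta) <- a@genes
    for (g in seq_along(a@delta))
        names(a@delta[[g]]) <- a@groups
    a@logPosterior <- rbind(a@logPosterior, b@logPosterior)
    a
}

#' Per-group length-corrected expression chains for one gene
#' @keywords internal
piBarTChains <- function(chains, gene) {
    el <- chains@effLen[[gene]]
    lapply(chains@delta[[gene]], function(m) computePiBarT(exp(m), el))
}
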