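#' @import methods
#' @importFrom stats var sd density rnorm rgamma rbinom rnbinom runif cov
#'   pchisq optim optimize setNames p.adjust rmultinom quantile ar dnorm
#'   ks.test pnorm lm coef residuals
#' @importFrom utils read.delim write.table head
#' @useDynLib latentDTU, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Equivalence-class count table
#'
#' Holds the merged equivalence classes (ECs) of one or more samples: the
#' transcript universe, the list of EC transcript-index tuples \eqn{C_j}, and
#' the J x N matrix of EC read counts \eqn{f_j^{(i)}}.
#'
#' Class tuples are stored as strictly increasing 1-based indices into
#' \code{transcripts}; classes with zero total count across all samples are
#' not kept.
#'
#' @slot transcripts character vector of transcript identifiers.
#' @slot classes list of strictly increasing integer vectors (indices into
#'   \code{transcripts}).
#' @slot counts integer matrix, one row per class, one column per sample.
#' @slot samples character vector of sample identifiers.
#' @aliases ECTable
#' @export
setClass("ECTable",
    representation(
        transcripts = "character",
        classes = "list",
        counts = "matrix",
        samples = "character"
    )
)

setValidity("ECTable", function(object) {
    msg <- NULL
    K <- length(object@transcripts)
    if (anyDuplicated(object@transcripts))
        msg <- c(msg, "duplicated transcript identifiers")
    if (nrow(object@counts) != length(object@classes))
        msg <- c(msg, "counts rows must match number of classes")
    if (ncol(object@counts) != length(object@samples))
        msg <- c(msg, "counts columns must match number of samples")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
        msg <- c(msg, "counts must be non-negative integers")
    bad <- vapply(object@classes, function(cl) {
        length(cl) == 0L || any(cl < 1L | cl > K) || is.unsorted(cl, strictly = TRUE)
    }, logical(1))
    if (any(bad))
        msg <- c(msg, "classes must be strictly increasing valid transcript indices")
    keys <- vapply(object@classes, paste, character(1), collapse = ",")
    if (anyDuplicated(keys))
        msg <- c(msg, "duplicated equivalence classes")
    if (length(object@classes) && any(rowSums(object@counts) == 0))
        msg <- c(msg, "classes with zero total count are not allowed")
    if (is.null(msg)) TRUE else msg
})

#' Gene cluster: the unit of MCMC analysis
#'
#' Genes connected by shared equivalence classes are analysed jointly so that
#' reads in multi-gene ECs can be allocated across genes. A cluster carries
#' the member genes, their transcripts with effective lengths, the local EC
#' structure, and (optionally) quantifier estimated counts used for filtering
#' and priors.
#'
#' @slot genes character vector of member gene ids.
#' @slot transcripts character vector of member transcript ids (cluster order).
#' @slot geneOf character vector, gene id of each transcript.
#' @slot effLen numeric vector of effective lengths \eqn{l_k}.
#' @slot estCounts matrix (K x N) of quantifier estimated counts, or a 0x0
#'   matrix when unavailable.
#' @slot classes list of integer vectors, local 1-based transcript indices.
#' @slot counts integer matrix (J x N) of EC counts.
#' @slot testable named logical per gene: whether a test result is emitted.
#' @export
setClass("GeneCluster",
    representation(
        genes = "character",
        transcripts = "character",
        geneOf = "character",
        effLen = "numeric",
        estCounts = "matrix",
        classes = "list",
        counts = "matrix",
        testable = "logical"
    )
)

setValidity("GeneCluster", function(object) {
    msg <- NULL
    K <- length(object@transcripts)
    if (length(object@geneOf) != K || length(object@effLen) != K)
        msg <- c(msg, "geneOf and effLen must have one entry per transcript")
    if (!all(object@geneOf %in% object@genes))
        msg <- c(msg, "geneOf contains genes outside the cluster")
    if (any(object@effLen <= 0))
        msg <- c(msg, "effective lengths must be positive")
    if (nrow(object@counts) != length(object@classes))
        msg <- c(msg, "counts rows must match number of classes")
    if (!identical(sort(names(object@testable)), sort(object@genes)))
        msg <- c(msg, "testable must be named by the cluster genes")
    bad <- vapply(object@classes, function(cl)
        length(cl) == 0L || any(cl < 1L | cl > K), logical(1))
    if (any(bad))
        msg <- c(msg, "class indices out of range")
    if (is.null(msg)) TRUE else msg
})

#' Prior specification for the Dirichlet parameters
#'
#' In the vague mode every \eqn{\log\delta_k} has an N(0, 100) prior. In the
#' informative mode the summed precision \eqn{\log\delta_+} gets
#' N(\code{meanLogPrec}, \code{varLogPrec}) (moments of the log precisions
#' estimated across genes), the first K-1 components get
#' N(\code{meanLogPrec} - log K, 100), and the density of the remaining
#' component follows by the Jacobian of the change of variables.
#'
#' @slot mode "vague" or "informative".
#' @slot meanLogPrec mean of log gene-wise precisions.
#' @slot varLogPrec variance of log gene-wise precisions.
#' @slot vagueVar variance of the vague normal prior (default 100).
#' @export
setClass("PriorSpec",
    representation(
        mode = "character",
        meanLogPrec = "numeric",
        varLogPrec = "numeric",
        vagueVar = "numeric"
    ),
    prototype(mode = "vague", meanLogPrec = 0, varLogPrec = NA_real_,
        vagueVar = 100)
)

setValidity("PriorSpec", function(object) {
    msg <- NULL
    if (!object@mode %in% c("vague", "informative"))
        msg <- c(msg, "mode must be 'vague' or 'informative'")
    if (object@mode == "informative" &&
        (!is.finite(object@varLogPrec) || object@varLogPrec <= 0))
        msg <- c(msg, "informative mode requires finite varLogPrec > 0")
    if (!is.finite(object@vagueVar) || object@vagueVar <= 0)
        msg <- c(msg, "vagueVar must be positive")
    if (is.null(msg)) TRUE else msg
})

#' MCMC output for one gene cluster
#'
#' Stores, for every gene of the cluster and every group, the post burn-in
#' draws of \eqn{\log\delta}, plus the per-group marginal log-posterior
#' series \eqn{\log P(\pi | \delta) + \log P(\delta)} summed over genes
#' (the stationarity-diagnostic target) and Metropolis acceptance rates.
#'
#' @slot genes character, genes with stored chains (K >= 2 only).
#' @slot transcripts list per gene of transcript ids.
#' @slot effLen list per gene of effective lengths.
#' @slot delta list per gene of lists per group: R x K matrices of log delta.
#' @slot logPosterior numeric matrix R x nGroups.
#' @slot acceptance numeric matrix nGenes x nGroups.
#' @slot groups character vector of group names.
#' @slot seed integer seed used for this chain.
#' @slot burnInUsed integer, burn-in iterations discarded (initial + extra).
#' @export
setClass("ClusterChains",
    representation(
        genes = "character",
        transcripts = "list",
        effLen = "list",
        delta = "list",
        logPosterior = "matrix",
        acceptance = "matrix",
        groups = "character",
        seed = "integer",
        burnInUsed = "integer"
    )
)

#' Convergence report for one gene cluster
#'
#' @slot hwPValue p-value of the final Heidelberger-Welch stationarity test.
#' @slot extraBurnIn extra leading iterations discarded by the HW test.
#' @slot nReruns number of full chain restarts (0..3).
#' @slot converged whether a stationary chain was obtained.
#' @slot secondChainRun whether a second chain was aggregated.
#' @export
setClass("ConvergenceReport",
    representation(
        hwPValue = "numeric",
        extraBurnIn = "integer",
        nReruns = "integer",
        converged = "logical",
        secondChainRun = "logical"
    ),
    prototype(hwPValue = NA_real_, extraBurnIn = 0L, nReruns = 0L,
        converged = TRUE, secondChainRun = FALSE)
)

setValidity("ConvergenceReport", function(object) {
    if (!object@converged && object@nReruns != 3L)
        return("converged = FALSE requires nReruns = 3")
    TRUE
})

#' Results of a differential transcript usage analysis
#'
#' @slot geneResults data.frame with one row per testable gene: p-value,
#'   BH-adjusted p-value, conservative inversion score, DTU measure,
#'   per-group dominant transcript and convergence flag.
#' @slot transcriptResults data.frame with one row per transcript of a
#'   testable gene: p-value, adjusted p-value, max-gene conservative score,
#'   posterior estimates of omega and per-group mean relative expression.
#' @slot prior the \linkS4class{PriorSpec} used.
#' @slot settings list of run settings (iterations, burn-in, seed, ...).
#' @export
setClass("DTUResults",
    representation(
        geneResults = "data.frame",
        transcriptResults = "data.frame",
        prior = "PriorSpec",
        settings = "list"
    )
)

#' Simulated ground truth for a DTU benchmark
#'
#' @slot info data.frame, one row per gene: gene_id, K, deltaPlus, isDU, mode.
#' @slot piA list of group-A mean relative transcript expression vectors.
#' @slot piB list of group-B vectors.
#' @slot lengths list of effective-length vectors.
#' @slot transcripts list of transcript id vectors.
#' @export
setClass("SimTruth",
    representation(
        info = "data.frame",
        piA = "list",
        piB = "list",
        lengths = "list",
        transcripts = "list"
    )
)

setMethod("show", "ECTable", function(object) {
    cat("ECTable:", length(object@classes), "equivalence classes,",
        length(object@transcripts), "transcripts,",
        length(object@samples), "samples\n")
    cat("  total reads:", sum(object@counts), "\n")
})

setMethod("show", "GeneCluster", function(object) {
    cat("GeneCluster:", length(object@genes), "gene(s),",
        length(object@transcripts), "transcripts,",
        length(object@classes), "classes;",
        sum(object@testable), "testable gene(s)\n")
})

setMethod("show", "PriorSpec", function(object) {
    if (object@mode == "vague") {
        cat("PriorSpec (vague): log delta_k ~ N(0,", object@vagueVar, ")\n")
    } else {
        cat(sprintf(
            "PriorSpec (informative): log delta_+ ~ N(%.3f, %.3f)\n",
            object@meanLogPrec, object@varLogPrec))
    }
})

setMethod("show", "ClusterChains", function(object) {
    cat("ClusterChains:", length(object@genes), "gene(s),",
        nrow(object@logPosterior), "stored iterations,",
        length(object@groups), "group(s); burn-in", object@burnInUsed, "\n")
})

setMethod("show", "ConvergenceReport", function(object) {
    cat(sprintf(
        "ConvergenceReport: converged=%s, HW p=%.4g, extra burn-in=%d, reruns=%d, second chain=%s\n",
        object@converged, object@hwPValue, object@extraBurnIn,
        object@nReruns, object@secondChainRun))
})

setMethod("show", "DTUResults", function(object) {
    cat("DTUResults:", nrow(object@geneResults), "genes,",
        nrow(object@transcriptResults), "transcripts tested\n")
    if (nrow(object@geneResults)) {
        ns <- sum(object@geneResults$p_adj < 0.05, na.rm = TRUE)
        cat("  genes with adjusted p < 0.05:", ns, "\n")
    }
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@info), "genes,",
        sum(object@info$isDU), "differentially used\n")
})

# ---- accessors ----

#' @describeIn ECTable-accessors transcript identifiers
#' @export
ecTranscripts <- function(x) x@transcripts

#' @describeIn ECTable-accessors equivalence-class tuples (1-based indices)
#' @export
ecClasses <- function(x) x@classes

#' Accessors for ECTable and DTUResults
#'
#' @param x an \linkS4class{ECTable} or \linkS4class{DTUResults} object.
#' @name ECTable-accessors
#' @describeIn ECTable-accessors EC count matrix
#' @export
ecCounts <- function(x) x@counts

#' @describeIn ECTable-accessors sample identifiers
#' @export
sampleIds <- function(x) x@samples

#' @describeIn ECTable-accessors gene-level results table
#' @export
geneResults <- function(x) x@geneResults

#' @describeIn ECTable-accessors transcript-level results table
#' @export
transcriptResults <- function(x) x@transcriptResults
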