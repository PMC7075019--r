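#' Estimate the precision prior from the data
#'
#' Rounds the quantifier's estimated transcript counts per testable gene
#' (K >= 2 kept transcripts, total counts at or above the gene filter),
#' fits Dirichlet-multinomial precisions with all samples pooled, and
#' summarises the log precisions into a \linkS4class{PriorSpec}.
#'
#' @param estCounts matrix of estimated counts (transcripts x samples) with
#'   transcript ids as row names.
#' @param geneMap named character vector transcript -> gene.
#' @param minGeneCount minimum total gene count (default 20).
#' @return list with \code{prior} (\linkS4class{PriorSpec}) and
#'   \code{precisions} (named numeric vector).
#' @export
priorFromData <- function(estCounts, geneMap, minGeneCount = 20) {
    genes <- geneMap[rownames(estCounts)]
    byGene <- split(seq_len(nrow(estCounts)), genes)
    byGene <- byGene[vapply(byGene, length, integer(1)) >= 2L]
    mats <- lapply(byGene, function(idx) estCounts[idx, , drop = FALSE])
    mats <- mats[vapply(mats, sum, numeric(1)) >= minGeneCount]
    prec <- if (length(mats)) estimatePrecisions(mats) else numeric(0)
    list(prior = buildPrior(prec), precisions = prec)
}

#' Differential transcript usage analysis
#'
#' Full pipeline on in-memory objects: transcript filtering, EC-table
#' reduction, clustering of genes connected by shared equivalence classes,
#' informative-prior construction, per-cluster MCMC with the
#' Heidelberger-Welch chain-management protocol, and gene- plus
#' transcript-level Wald testing with BH correction, conservative scores
#' and the DTU effect-size measure.
#'
#' The minimum chain settings (10000 stored iterations, 2000 burn-in) are
#' enforced unless \code{unsafe = TRUE}, which is intended for quick
#' exploratory runs and unit tests only.
#'
#' @param ec an \linkS4class{ECTable} of all samples.
#' @param geneMap named character vector transcript -> gene.
#' @param effectiveLengths named numeric vector of effective lengths.
#' @param estCounts matrix of estimated counts (transcripts x samples).
#' @param groups factor/character of group per sample (order of the EC
#'   table's samples).
#' @param prior optional \linkS4class{PriorSpec}; when NULL an informative
#'   prior is estimated from \code{estCounts} (vague fallback).
#' @param filter apply the transcript pre-filter (default TRUE).
#' @param minTranscriptCount,minRelAbundance,minGeneCount filter settings.
#' @param niter,burnin MCMC settings.
#' @param seed master seed; all cluster/rerun/second-chain seeds derive
#'   from it deterministically, so results are reproducible and independent
#'   of cluster scheduling.
#' @param allocationScale "pi" (default) or "pi_T".
#' @param useMode posterior modes (default) or means for the Wald tests.
#' @param unsafe allow smaller chain settings.
#' @param diagDir optional directory: per-cluster MCMC diagnostics are
#'   written there as TSV (iteration, per-group log-posterior and log
#'   delta_+ of the first testable gene).
#' @param nWorkers clusters processed in parallel (fork-based); because
#'   every cluster's RNG stream derives from (seed, cluster id), results
#'   are identical whatever the scheduling.
#' @param verbose print one line per cluster batch.
#' @return a \linkS4class{DTUResults}.
#' @export
runDTU <- function(ec, geneMap, effectiveLengths, estCounts, groups,
                   prior = NULL, filter = TRUE, minTranscriptCount = 10,
                   minRelAbundance = 0.01, minGeneCount = 20,
                   niter = 10000, burnin = 2000, seed = 1L,
                   allocationScale = c("pi", "pi_T"), useMode = TRUE,
                   unsafe = FALSE, diagDir = NULL, nWorkers = 1L,
                   verbose = FALSE) {
    allocationScale <- match.arg(allocationScale)
    if (!unsafe && (niter < 10000 || burnin < 2000))
        stop("niter >= 10000 and burnin >= 2000 are required ",
             "(set unsafe = TRUE to override for exploration)")
    groups <- as.factor(groups)
    stopifnot(length(groups) == length(sampleIds(ec)))
    G <- nlevels(groups)
    if (G < 2L) stop("at least two groups are required")
    if (filter) {
        kept <- filterTranscripts(estCounts, geneMap,
                                  minCount = minTranscriptCount,
                                  minRelAbundance = minRelAbundance)
        kept <- intersect(ecTranscripts(ec), kept)
        ec <- reduceECTable(ec, kept)
    }
    clusters <- buildGeneClusters(ec, geneMap, effectiveLengths, estCounts)
    clusters <- filterGenes(clusters, minGeneCount = minGeneCount)
    if (is.null(prior)) {
        keptTx <- ecTranscripts(ec)
        prior <- priorFromData(estCounts[rownames(estCounts) %in% keptTx, ,
                                         drop = FALSE],
                               geneMap, minGeneCount = minGeneCount)$prior
    }
    twoGroups <- G == 2L
    processCluster <- function(ci) {
        geneRows <- list()
        txRows <- list()
        cl <- clusters[[ci]]
        if (!any(cl@testable) || sum(cl@counts) == 0L ||
            length(cl@transcripts) < 2L)
            return(list(gene = geneRows, tx = txRows))
        baseSeed <- deriveSeed(seed, chainId = 0L, run = 0L,
                               clusterId = ci)
        prot <- chainProtocol(cl, prior, groups, niter = niter,
                              burnin = burnin, seed = baseSeed,
                              allocationScale = allocationScale)
        cvg <- prot$report
        testGenes <- names(cl@testable)[cl@testable]
        testGenes <- intersect(testGenes,
                               if (is.null(prot$chains)) character(0)
                               else prot$chains@genes)
        if (is.null(prot$chains)) {
            # no stationary chain after three runs: emit missing p-values
            for (g in names(cl@testable)[cl@testable]) {
                geneRows[[length(geneRows) + 1L]] <- data.frame(
                    gene_id = g, p = NA_real_, dtu_measure = NA_real_,
                    dominant_A = NA_character_, dominant_B = NA_character_,
                    dominant_changed = NA, converged = FALSE,
                    n_reruns = cvg@nReruns, stringsAsFactors = FALSE)
            }
            return(list(gene = geneRows, tx = txRows))
        }
        chains <- prot$chains
        if (!is.null(diagDir) && length(chains@genes)) {
            dir.create(diagDir, showWarnings = FALSE, recursive = TRUE)
            g1 <- chains@genes[1]
            diag <- data.frame(iteration = seq_len(nrow(chains@logPosterior)))
            for (grp in chains@groups) {
                diag[[paste0("log_posterior_", grp)]] <-
                    chains@logPosterior[, grp]
                diag[[paste0("log_delta_plus_", grp)]] <-
                    log(rowSums(exp(chains@delta[[g1]][[grp]])))
            }
            write.table(diag, file.path(diagDir,
                                        sprintf("cluster_%04d.tsv", ci)),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
        for (g in testGenes) {
            piT <- piBarTChains(chains, g)
            txIds <- chains@transcripts[[g]]
            K <- length(txIds)
            est <- lapply(piT, function(m) {
                cen <- posteriorModeCov(m, useMode = useMode)$center
                cen <- pmin(pmax(cen, 0), 1)
                if (sum(cen) > 0) cen / sum(cen) else rep(1 / K, K)
            })
            if (twoGroups) {
                gt <- geneLevelTest(piT[[1]], piT[[2]], useMode = useMode)
                R <- min(nrow(piT[[1]]), nrow(piT[[2]]))
                omega <- piT[[1]][seq_len(R), , drop = FALSE] -
                    piT[[2]][seq_len(R), , drop = FALSE]
                tt <- transcriptLevelTest(omega, useMode = useMode)
                domA <- which.max(est[[1]])
                domB <- which.max(est[[2]])
                geneRows[[length(geneRows) + 1L]] <- data.frame(
                    gene_id = g, p = gt$pvalue,
                    dtu_measure = dtuMeasure(est[[1]], est[[2]]),
                    dominant_A = txIds[domA], dominant_B = txIds[domB],
                    dominant_changed = domA != domB,
                    converged = cvg@converged, n_reruns = cvg@nReruns,
                    stringsAsFactors = FALSE)
                txRows[[length(txRows) + 1L]] <- data.frame(
                    transcript_id = txIds, gene_id = g, p = tt$pvalue,
                    omega_hat = tt$omega_hat, omega_var = tt$omega_var,
                    pi_T_A = est[[1]], pi_T_B = est[[2]],
                    stringsAsFactors = FALSE)
            } else {
                mt <- multigroupTest(piT, useMode = useMode)
                geneRows[[length(geneRows) + 1L]] <- data.frame(
                    gene_id = g, p = mt$pvalue, dtu_measure = NA_real_,
                    dominant_A = NA_character_, dominant_B = NA_character_,
                    dominant_changed = NA, converged = cvg@converged,
                    n_reruns = cvg@nReruns, stringsAsFactors = FALSE)
            }
        }
        if (verbose)
            message(sprintf(
                "cluster %d/%d: %d transcripts, %d gene(s), reruns=%d, accept=%.2f",
                ci, length(clusters), length(cl@transcripts),
                length(cl@genes), cvg@nReruns,
                mean(chains@acceptance)))
        list(gene = geneRows, tx = txRows)
    }
    perCluster <- if (nWorkers > 1L) {
        parallel::mclapply(seq_along(clusters), processCluster,
                           mc.cores = nWorkers, mc.preschedule = FALSE)
    } else {
        lapply(seq_along(clusters), processCluster)
    }
    geneRows <- unlist(lapply(perCluster, `[[`, "gene"), recursive = FALSE)
    txRows <- unlist(lapply(perCluster, `[[`, "tx"), recursive = FALSE)
    geneDF <- if (length(geneRows)) do.call(rbind, geneRows) else
        data.frame(gene_id = character(0), p = numeric(0),
                   dtu_measure = numeric(0), dominant_A = character(0),
                   dominant_B = character(0), dominant_changed = logical(0),
                   converged = logical(0), n_reruns = integer(0))
    txDF <- if (length(txRows)) do.call(rbind, txRows) else
        data.frame(transcript_id = character(0), gene_id = character(0),
                   p = numeric(0), omega_hat = numeric(0),
                   omega_var = numeric(0), pi_T_A = numeric(0),
                   pi_T_B = numeric(0))
    geneDF$p_adj <- adjustBH(geneDF$p)
    geneDF$inv_score <- conservativeScore(geneDF$p_adj,
                                          geneDF$dominant_changed)
    txDF$p_adj <- adjustBH(txDF$p)
    txDF$max_gene_score <- maxGeneScore(
        txDF$p_adj, geneDF$p_adj[match(txDF$gene_id, geneDF$gene_id)])
    rownames(geneDF) <- rownames(txDF) <- NULL
    new("DTUResults", geneResults = geneDF, transcriptResults = txDF,
        prior = prior,
        settings = list(niter = niter, burnin = burnin, seed = seed,
                        allocationScale = allocationScale,
                        groups = levels(groups), filter = filter,
                        useMode = useMode))
}

#' File-based differential transcript usage analysis
#'
#' Reads a design table (columns sample_id, group, eq_classes_path,
#' quant_path), the per-sample Salmon-format inputs and a gene map, then
#' runs \code{\link{runDTU}} and optionally writes the result tables.
#'
#' @param designPath path to the design TSV.
#' @param geneMapPath path to a GTF or 2-column TSV gene map.
#' @param outDir optional output directory for the result TSVs.
#' @param ... further arguments to \code{\link{runDTU}}.
#' @return a \linkS4class{DTUResults}.
#' @export
runDTUFiles <- function(designPath, geneMapPath, outDir = NULL, ...) {
    design <- readDesign(designPath)
    need <- c("eq_classes_path", "quant_path")
    if (!all(need %in% colnames(design)))
        stop("design table must contain eq_classes_path and quant_path")
    for (i in seq_len(nrow(design)))
        if (!file.exists(design$eq_classes_path[i]))
            stop("equivalence-class file for sample '", design$sample_id[i],
                 "' not found: ", design$eq_classes_path[i])
    tables <- lapply(seq_len(nrow(design)), function(i)
        readSalmonEC(design$eq_classes_path[i],
                     sample = design$sample_id[i]))
    ec <- mergeECSamples(tables, design$sample_id)
    quants <- lapply(design$quant_path, readQuantSF)
    txs <- quants[[1]]$transcript_id
    estCounts <- vapply(quants, function(q)
        q$est_count[match(txs, q$transcript_id)], numeric(length(txs)))
    estCounts <- matrix(estCounts, nrow = length(txs),
                        dimnames = list(txs, design$sample_id))
    if (anyNA(estCounts))
        stop("quantification tables disagree on the transcript set")
    effLen <- setNames(rowMeans(vapply(quants, function(q)
        q$effective_length[match(txs, q$transcript_id)],
        numeric(length(txs)))), txs)
    geneMap <- readGeneMap(geneMapPath)
    res <- runDTU(ec, geneMap, effLen, estCounts, design$group, ...)
    if (!is.null(outDir)) writeDTUResults(res, outDir)
    res
}

#' Write DTU result tables
#'
#' Writes \code{gene_results.tsv} and \code{transcript_results.tsv} with
#' p-values at 6 significant digits and missing values as "NA".
#'
#' @param res a \linkS4class{DTUResults}.
#' @param dir output directory (created if needed).
#' @export
writeDTUResults <- function(res, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fmt <- function(df) {
        for (cn in colnames(df))
            if (is.numeric(df[[cn]]))
                df[[cn]] <- signif(df[[cn]], 6)
        df
    }
    write.table(fmt(res@geneResults), file.path(dir, "gene_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    write.table(fmt(res@transcriptResults),
                file.path(dir, "transcript_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    invisible(dir)
}
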