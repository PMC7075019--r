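#' Draw from a Dirichlet distribution
#' @keywords internal
rdirichlet <- function(n, alpha) {
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n),
                       rate = 1), n, length(alpha))
    g / rowSums(g)
}

#' Simulate ground truth for a DTU benchmark
#'
#' Baseline mean relative transcript expression is drawn from a symmetric
#' Dirichlet; a fraction of the genes eligible for differential usage (at
#' least two transcripts with relative expression above 0.1) is made DU by
#' either inverting the two most expressed transcripts between groups
#' (\code{mode = "invert"}) or randomly permuting the proportions of the
#' four most expressed transcripts in one group (\code{mode = "permute"};
#' genes with two or three transcripts have all their proportions
#' permuted). Permutations are forced non-identical so DU genes genuinely
#' differ. Precisions are lognormal; effective lengths lognormal with a
#' floor of 100.
#'
#' @param nGenes number of genes.
#' @param duFraction fraction of genes made differentially used.
#' @param mode "permute" (default) or "invert".
#' @param kProbs distribution of transcript numbers: probabilities for
#'   K = 2, 3, ... (default favours small K, up to 8).
#' @param precMeanLog,precSdLog lognormal parameters of the gene precision
#'   \eqn{\delta_+} (default meanlog log(30), sdlog 0.6).
#' @param lenMeanLog,lenSdLog lognormal parameters of effective lengths.
#' @param baseAlpha symmetric Dirichlet parameter of baseline proportions.
#' @param seed integer seed.
#' @return a \linkS4class{SimTruth}.
#' @export
simulateTruth <- function(nGenes = 100, duFraction = 0.2,
                          mode = c("permute", "invert"),
                          kProbs = c(3, 3, 2, 1.5, 1, 0.7, 0.5),
                          precMeanLog = log(30), precSdLog = 0.6,
                          lenMeanLog = log(1200), lenSdLog = 0.5,
                          baseAlpha = 1, seed = 1L) {
    mode <- match.arg(mode)
    stopifnot(duFraction >= 0, duFraction <= 1)
    set.seed(as.integer(seed %% 2147483647))
    Ks <- sample(seq_along(kProbs) + 1L, nGenes, replace = TRUE,
                 prob = kProbs)
    piA <- piB <- lengths <- txs <- vector("list", nGenes)
    deltaPlus <- exp(rnorm(nGenes, precMeanLog, precSdLog))
    geneIds <- sprintf("G%04d", seq_len(nGenes))
    for (g in seq_len(nGenes)) {
        K <- Ks[g]
        piA[[g]] <- as.vector(rdirichlet(1, rep(baseAlpha, K)))
        piB[[g]] <- piA[[g]]
        lengths[[g]] <- pmax(100, round(exp(rnorm(K, lenMeanLog, lenSdLog))))
        txs[[g]] <- sprintf("%s.T%d", geneIds[g], seq_len(K))
    }
    eligible <- which(vapply(piA, function(p) sum(p > 0.1) >= 2L, logical(1)))
    nDU <- round(duFraction * nGenes)
    if (nDU > 0 && length(eligible) == 0L)
        stop("no genes eligible for differential usage")
    duGenes <- if (nDU > 0)
        sample(eligible, min(nDU, length(eligible))) else integer(0)
    isDU <- seq_len(nGenes) %in% duGenes
    for (g in duGenes) {
        p <- piA[[g]]
        K <- length(p)
        if (mode == "invert") {
            top <- order(-p)[1:2]
            q <- p
            q[top] <- p[rev(top)]
            piB[[g]] <- q
        } else {
            m <- if (K <= 3L) K else 4L
            top <- order(-p)[seq_len(m)]
            repeat {
                perm <- sample(m)
                if (any(perm != seq_len(m)) &&
                    any(p[top][perm] != p[top])) break
            }
            q <- p
            q[top] <- p[top][perm]
            piB[[g]] <- q
        }
    }
    new("SimTruth",
        info = data.frame(gene_id = geneIds, K = Ks,
                          deltaPlus = deltaPlus, isDU = isDU,
                          mode = ifelse(isDU, mode, NA_character_),
                          stringsAsFactors = FALSE),
        piA = setNames(piA, geneIds), piB = setNames(piB, geneIds),
        lengths = setNames(lengths, geneIds),
        transcripts = setNames(txs, geneIds))
}

#' Simulate per-sample transcript counts from the truth
#'
#' Gene totals are negative binomial around the mean depth; within each
#' sample, transcript proportions are Dirichlet around the group's mean
#' (concentration \eqn{\delta_+}) and counts multinomial. The truth is
#' specified on the expression scale \eqn{\bar\pi^T}; mapping-scale
#' proportions \eqn{\bar\pi_k \propto \bar\pi^T_k l_k} drive the counts, so
#' the pipeline's length correction is genuinely exercised.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param nPerGroup samples per group (default 6).
#' @param depth mean reads per gene (default 500).
#' @param nbDispersion negative-binomial dispersion (var = mu + disp*mu^2;
#'   default 0.1).
#' @param seed integer seed.
#' @return list with \code{counts} (transcripts x samples matrix),
#'   \code{design} (data.frame sample_id, group), \code{txInfo}
#'   (transcript_id, gene_id, effective_length).
#' @export
simulateCounts <- function(truth, nPerGroup = 6, depth = 500,
                           nbDispersion = 0.1, seed = 1L) {
    stopifnot(depth > 0)
    set.seed(as.integer(seed %% 2147483647) + 1L)
    nGenes <- nrow(truth@info)
    N <- 2L * nPerGroup
    groups <- rep(c("A", "B"), each = nPerGroup)
    sampleIds <- sprintf("sample%02d", seq_len(N))
    allTx <- unlist(truth@transcripts, use.names = FALSE)
    counts <- matrix(0L, length(allTx), N,
                     dimnames = list(allTx, sampleIds))
    offset <- 0L
    for (g in seq_len(nGenes)) {
        K <- truth@info$K[g]
        el <- truth@lengths[[g]]
        dp <- truth@info$deltaPlus[g]
        for (i in seq_len(N)) {
            piT <- if (groups[i] == "A") truth@piA[[g]] else truth@piB[[g]]
            piMap <- piT * el
            piMap <- piMap / sum(piMap)
            tot <- rnbinom(1, mu = depth, size = 1 / nbDispersion)
            if (tot > 0) {
                p <- as.vector(rdirichlet(1, dp * piMap))
                counts[offset + seq_len(K), i] <-
                    as.integer(rmultinom(1, tot, p))
            }
        }
        offset <- offset + K
    }
    list(counts = counts,
         design = data.frame(sample_id = sampleIds, group = groups,
                             stringsAsFactors = FALSE),
         txInfo = data.frame(
             transcript_id = allTx,
             gene_id = rep(truth@info$gene_id, truth@info$K),
             effective_length = unlist(truth@lengths, use.names = FALSE),
             stringsAsFactors = FALSE))
}

#' Build an equivalence-class table from simulated transcript counts
#'
#' Each gene gets a random compatibility structure: one singleton class per
#' transcript plus random within-gene subsets of size 2..\code{maxClassSize}
#' (and, with probability \code{crossGeneProb}, one class joining a
#' transcript of the gene with one of the next gene, exercising the
#' multi-gene allocation path). For every sample, a binomial
#' \code{ambiguity} fraction of each transcript's reads is routed to the
#' shared classes containing it (uniformly), the rest to its singleton.
#' Matching quantification tables report the true transcript counts.
#'
#' @param sim output of \code{\link{simulateCounts}}.
#' @param ambiguity fraction of reads routed to shared classes (default 0.5).
#' @param maxClassSize largest within-gene class (default 3).
#' @param crossGeneProb probability a gene shares a class with the next
#'   gene (default 0.05).
#' @param seed integer seed.
#' @return list with \code{ec} (an \linkS4class{ECTable}), \code{quant}
#'   (list per sample of quant.sf-style data.frames), \code{geneMap},
#'   \code{effectiveLengths}, \code{estCounts}.
#' @export
simulateECTable <- function(sim, ambiguity = 0.5, maxClassSize = 3,
                            crossGeneProb = 0.05, seed = 1L) {
    stopifnot(ambiguity >= 0, ambiguity <= 1)
    set.seed(as.integer(seed %% 2147483647) + 2L)
    tx <- sim$txInfo$transcript_id
    geneOf <- sim$txInfo$gene_id
    genes <- unique(geneOf)
    nTx <- length(tx)
    N <- ncol(sim$counts)
    txOfGene <- split(seq_len(nTx), factor(geneOf, levels = genes))
    classes <- as.list(seq_len(nTx))  # singletons first
    # Within-gene shared classes partition a random permutation of the
    # gene's transcripts into disjoint subsets, so each transcript routes
    # its ambiguous reads to (at most) one shared class. Disjointness
    # keeps the generator consistent with the allocation model's uniform
    # coverage assumption: the fraction of a transcript's reads landing in
    # a class must be a property of the class, not of the transcript.
    for (gi in seq_along(genes)) {
        idx <- txOfGene[[gi]]
        K <- length(idx)
        if (K >= 2L && ambiguity > 0) {
            perm <- if (K == 2L) sample(idx, 2L) else sample(idx)
            pos <- 1L
            while (K - pos + 1L >= 2L) {
                maxSz <- min(maxClassSize, K - pos + 1L)
                sz <- if (maxSz == 2L) 2L else sample(2:maxSz, 1L)
                # avoid leaving a stranded single transcript when possible
                if (K - pos + 1L - sz == 1L && sz < maxSz) sz <- sz + 1L
                classes[[length(classes) + 1L]] <-
                    sort(perm[pos:(pos + sz - 1L)])
                pos <- pos + sz
            }
        }
        if (gi < length(genes) && runif(1) < crossGeneProb) {
            nxt <- txOfGene[[gi + 1L]]
            classes[[length(classes) + 1L]] <-
                sort(c(sample(idx, 1L), sample(nxt, 1L)))
        }
    }
    J <- length(classes)
    counts <- matrix(0L, J, N)
    sharedOf <- vector("list", nTx)  # class rows sharing each transcript
    for (j in seq((nTx + 1L), J)) {
        if (j > J) break
        for (k in classes[[j]]) sharedOf[[k]] <- c(sharedOf[[k]], j)
    }
    if (J > nTx) {
        for (i in seq_len(N)) {
            for (k in seq_len(nTx)) {
                ck <- sim$counts[k, i]
                if (ck == 0L) next
                sh <- sharedOf[[k]]
                if (is.null(sh)) {
                    counts[k, i] <- counts[k, i] + ck
                    next
                }
                nAmb <- rbinom(1, ck, ambiguity)
                counts[k, i] <- counts[k, i] + (ck - nAmb)
                if (nAmb > 0) {
                    split <- as.integer(rmultinom(1, nAmb,
                                                  rep(1, length(sh))))
                    counts[sh, i] <- counts[sh, i] + split
                }
            }
        }
    } else {
        counts[seq_len(nTx), ] <- sim$counts
    }
    keep <- which(rowSums(counts) > 0L)
    colnames(counts) <- colnames(sim$counts)
    classes <- classes[keep]
    counts <- counts[keep, , drop = FALSE]
    ord <- canonicalClassOrder(classes)
    ec <- new("ECTable", transcripts = tx, classes = classes[ord],
              counts = counts[ord, , drop = FALSE],
              samples = colnames(sim$counts))
    el <- setNames(sim$txInfo$effective_length, tx)
    quant <- lapply(seq_len(N), function(i) {
        nr <- sim$counts[, i]
        tpm <- nr / el
        tpm <- if (sum(tpm) > 0) 1e6 * tpm / sum(tpm) else tpm
        data.frame(Name = tx, Length = round(el + 200),
                   EffectiveLength = el, TPM = tpm, NumReads = nr,
                   stringsAsFactors = FALSE)
    })
    names(quant) <- colnames(sim$counts)
    list(ec = ec, quant = quant,
         geneMap = setNames(geneOf, tx),
         effectiveLengths = el,
         estCounts = sim$counts)
}

#' One-call synthetic dataset generator
#'
#' Chains \code{\link{simulateTruth}}, \code{\link{simulateCounts}} and
#' \code{\link{simulateECTable}} with a single seed.
#'
#' @param nGenes,duFraction,mode,seed see \code{\link{simulateTruth}}.
#' @param nPerGroup,depth,nbDispersion see \code{\link{simulateCounts}}.
#' @param ambiguity,maxClassSize,crossGeneProb see
#'   \code{\link{simulateECTable}}.
#' @param ... further arguments to \code{\link{simulateTruth}}.
#' @return list with all \code{simulateECTable} components plus
#'   \code{truth} and \code{design}.
#' @export
simulateDTUData <- function(nGenes = 100, duFraction = 0.2,
                            mode = "permute", nPerGroup = 6, depth = 500,
                            nbDispersion = 0.1, ambiguity = 0.5,
                            maxClassSize = 3, crossGeneProb = 0.05,
                            seed = 1L, ...) {
    truth <- simulateTruth(nGenes = nGenes, duFraction = duFraction,
                           mode = mode, seed = seed, ...)
    sim <- simulateCounts(truth, nPerGroup = nPerGroup, depth = depth,
                          nbDispersion = nbDispersion, seed = seed)
    out <- simulateECTable(sim, ambiguity = ambiguity,
                           maxClassSize = maxClassSize,
                           crossGeneProb = crossGeneProb, seed = seed)
    out$truth <- truth
    out$design <- sim$design
    out
}

#' Write a simulated dataset as Salmon-format files
#'
#' Produces, under \code{dir}, one \code{<sample>/eq_classes.txt} and
#' \code{<sample>/quant.sf} per sample, a 2-column gene map
#' (\code{gene_map.tsv}), a design table (\code{design.tsv}) and the truth
#' table (\code{truth.tsv}).
#'
#' @param simData output of \code{\link{simulateDTUData}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulatedData <- function(simData, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    samples <- sampleIds(simData$ec)
    ecPaths <- file.path(dir, samples, "eq_classes.txt")
    for (s in samples)
        dir.create(file.path(dir, s), showWarnings = FALSE)
    writeSalmonEC(simData$ec, ecPaths)
    for (s in samples)
        write.table(simData$quant[[s]], file.path(dir, s, "quant.sf"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = unname(simData$geneMap),
                           transcript = names(simData$geneMap)),
                file.path(dir, "gene_map.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    design <- data.frame(sample_id = samples,
                         group = simData$design$group,
                         eq_classes_path = ecPaths,
                         quant_path = file.path(dir, samples, "quant.sf"),
                         stringsAsFactors = FALSE)
    write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tr <- simData$truth
    write.table(cbind(tr@info,
                      piA = vapply(tr@piA, paste, character(1),
                                   collapse = ","),
                      piB = vapply(tr@piB, paste, character(1),
                                   collapse = ",")),
                file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(dir)
}

#' Observed FDR and TPR of DTU calls against the simulated truth
#'
#' @param results gene-level results data.frame with columns
#'   \code{gene_id} and \code{p_adj}.
#' @param truth a \linkS4class{SimTruth} (or its \code{info} data.frame).
#' @param thresholds adjusted-p significance thresholds.
#' @return data.frame with threshold, calls, FDR and TPR.
#' @export
evaluateCalls <- function(results, truth, thresholds = c(0.01, 0.05, 0.1)) {
    info <- if (is(truth, "SimTruth")) truth@info else truth
    isDU <- setNames(info$isDU, info$gene_id)
    res <- results[!is.na(results$p_adj) &
                       results$gene_id %in% names(isDU), ]
    pos <- sum(isDU[res$gene_id])
    do.call(rbind, lapply(thresholds, function(th) {
        called <- res$gene_id[res$p_adj <= th]
        tp <- sum(isDU[called])
        fp <- length(called) - tp
        data.frame(threshold = th, calls = length(called),
                   FDR = fp / max(1, length(called)),
                   TPR = if (pos > 0) tp / pos else 0)
    }))
}
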