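#' Filter lowly abundant transcripts
#'
#' Keeps transcripts with (a) total estimated counts across all samples of at
#' least \code{minCount} and (b) mean within-gene relative abundance of at
#' least \code{minRelAbundance}. Relative abundance is computed per sample
#' among the gene's transcripts and averaged over the samples in which the
#' gene has nonzero counts; a gene expressed in no sample loses all its
#' transcripts. Both thresholds are inclusive.
#'
#' @param estCounts numeric matrix of estimated counts, transcripts x samples,
#'   with transcript ids as row names.
#' @param geneMap named character vector mapping transcript id to gene id.
#' @param minCount minimum total estimated count (default 10).
#' @param minRelAbundance minimum mean within-gene relative abundance
#'   (default 0.01).
#' @return character vector of kept transcript ids.
#' @export
filterTranscripts <- function(estCounts, geneMap, minCount = 10,
                              minRelAbundance = 0.01) {
    stopifnot(is.matrix(estCounts), !is.null(rownames(estCounts)))
    txs <- rownames(estCounts)
    genes <- geneMap[txs]
    if (anyNA(genes))
        stop("transcripts missing from the gene map: ",
             paste(head(txs[is.na(genes)], 5), collapse = ", "))
    passCount <- rowSums(estCounts) >= minCount
    meanRel <- rep(0, length(txs))
    for (idx in split(seq_along(txs), genes)) {
        sub <- estCounts[idx, , drop = FALSE]
        tot <- colSums(sub)
        expressed <- tot > 0
        if (!any(expressed)) next
        props <- sweep(sub[, expressed, drop = FALSE], 2, tot[expressed], "/")
        meanRel[idx] <- rowMeans(props)
    }
    txs[passCount & meanRel >= minRelAbundance]
}

#' Reduce an equivalence-class table to a kept transcript set
#'
#' Dropped transcripts are removed from every class tuple; classes that
#' become empty are discarded (their reads are removed and reported via the
#' \code{discardedReads} attribute); classes that become identical after the
#' reduction are merged with counts summed.
#'
#' @param ec an \linkS4class{ECTable}.
#' @param kept character vector of transcript ids to keep (subset of the
#'   table's transcripts).
#' @return reduced \linkS4class{ECTable} with attribute
#'   \code{discardedReads}.
#' @export
reduceECTable <- function(ec, kept) {
    stopifnot(all(kept %in% ec@transcripts))
    newTx <- ec@transcripts[ec@transcripts %in% kept]
    remap <- match(ec@transcripts, newTx)  # NA for dropped
    keyEnv <- new.env(parent = emptyenv())
    classList <- list()
    counts <- NULL
    nS <- length(ec@samples)
    rows <- list()
    discarded <- 0
    for (j in seq_along(ec@classes)) {
        cl <- remap[ec@classes[[j]]]
        cl <- sort(cl[!is.na(cl)])
        if (length(cl) == 0L) {
            discarded <- discarded + sum(ec@counts[j, ])
            next
        }
        key <- paste(cl, collapse = ",")
        row <- get0(key, envir = keyEnv)
        if (is.null(row)) {
            classList[[length(classList) + 1L]] <- cl
            row <- length(classList)
            rows[[row]] <- integer(nS)
            assign(key, row, envir = keyEnv)
        }
        rows[[row]] <- rows[[row]] + ec@counts[j, ]
    }
    J <- length(classList)
    counts <- if (J) do.call(rbind, rows) else
        matrix(0L, 0L, nS)
    colnames(counts) <- ec@samples
    keep <- if (J) which(rowSums(counts) > 0) else integer(0)
    classList <- classList[keep]
    counts <- counts[keep, , drop = FALSE]
    ord <- canonicalClassOrder(classList)
    out <- new("ECTable", transcripts = newTx,
               classes = classList[ord],
               counts = matrix(as.integer(counts[ord, , drop = FALSE]),
                               ncol = nS, dimnames = list(NULL, ec@samples)),
               samples = ec@samples)
    attr(out, "discardedReads") <- discarded
    out
}

#' Group genes into clusters connected by shared equivalence classes
#'
#' Builds the graph whose nodes are genes and whose edges join genes sharing
#' at least one equivalence class, and returns one \linkS4class{GeneCluster}
#' per connected component. Each EC belongs to exactly one cluster.
#' Transcripts absent from the gene map are dropped (with a warning) before
#' clustering. Genes with fewer than 2 transcripts are retained for read
#' allocation but flagged untestable.
#'
#' @param ec an \linkS4class{ECTable}.
#' @param geneMap named character vector transcript -> gene.
#' @param effectiveLengths named numeric vector of effective lengths per
#'   transcript.
#' @param estCounts optional matrix of estimated counts (transcripts x
#'   samples) carried along for gene-level filtering and priors.
#' @return list of \linkS4class{GeneCluster} objects.
#' @export
buildGeneClusters <- function(ec, geneMap, effectiveLengths,
                              estCounts = NULL) {
    unmapped <- setdiff(ec@transcripts, names(geneMap))
    if (length(unmapped)) {
        warning(length(unmapped),
                " transcript(s) missing from the gene map were dropped")
        ec <- reduceECTable(ec, setdiff(ec@transcripts, unmapped))
    }
    txs <- ec@transcripts
    if (length(txs) == 0L) return(list())
    genes <- geneMap[txs]
    if (!all(txs %in% names(effectiveLengths)))
        stop("effective lengths missing for some transcripts")
    ugenes <- unique(genes)
    # union-find over genes
    parent <- seq_along(ugenes)
    names(parent) <- ugenes
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    gidx <- match(genes, ugenes)
    for (cl in ec@classes) {
        gs <- unique(gidx[cl])
        if (length(gs) > 1L) {
            r <- findRoot(gs[1])
            for (g in gs[-1]) {
                r2 <- findRoot(g)
                if (r2 != r) parent[r2] <- r
            }
        }
    }
    roots <- vapply(seq_along(ugenes), findRoot, integer(1))
    comp <- match(roots, unique(roots))
    clusters <- vector("list", max(comp))
    for (ci in seq_len(max(comp))) {
        memberGenes <- ugenes[comp == ci]
        txIdx <- which(genes %in% memberGenes)
        localTx <- txs[txIdx]
        localMap <- match(txs, localTx)  # global -> local, NA outside
        classSel <- vapply(ec@classes, function(cl)
            !is.na(localMap[cl[1]]), logical(1))
        localClasses <- lapply(ec@classes[classSel], function(cl)
            sort(localMap[cl]))
        cnt <- ec@counts[classSel, , drop = FALSE]
        kPer <- table(factor(geneMap[localTx], levels = memberGenes))
        testable <- setNames(as.vector(kPer) >= 2L, memberGenes)
        estSub <- if (is.null(estCounts)) {
            matrix(numeric(0), 0, 0)
        } else {
            m <- estCounts[localTx, , drop = FALSE]
            rownames(m) <- localTx
            m
        }
        clusters[[ci]] <- new("GeneCluster",
            genes = memberGenes,
            transcripts = localTx,
            geneOf = unname(geneMap[localTx]),
            effLen = unname(effectiveLengths[localTx]),
            estCounts = estSub,
            classes = localClasses,
            counts = matrix(as.integer(cnt), ncol = ncol(cnt),
                            dimnames = dimnames(cnt)),
            testable = testable)
    }
    clusters
}

#' Flag genes below the expression filter as untestable
#'
#' Gene-level estimated counts are the sum of the member transcripts'
#' estimated counts across all samples; genes below \code{minGeneCount}
#' (inclusive threshold: a gene at exactly the threshold is kept) are
#' flagged. Flagged genes still receive read-allocation mass inside
#' multi-gene clusters but emit no test result.
#'
#' @param clusters list of \linkS4class{GeneCluster}.
#' @param minGeneCount minimum total estimated gene count (default 20).
#' @return the cluster list with updated \code{testable} flags.
#' @export
filterGenes <- function(clusters, minGeneCount = 20) {
    lapply(clusters, function(cl) {
        if (nrow(cl@estCounts) == 0L) return(cl)
        tot <- tapply(rowSums(cl@estCounts),
                      factor(cl@geneOf, levels = cl@genes), sum)
        tot[is.na(tot)] <- 0
        pass <- setNames(as.vector(tot) >= minGeneCount, names(tot))
        cl@testable <- cl@testable & pass[names(cl@testable)]
        cl
    })
}
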