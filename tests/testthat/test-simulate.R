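test_that("truth generation applies the DU rules exactly", {
    tr <- simulateTruth(nGenes = 60, duFraction = 0.3, mode = "invert",
                        seed = 3)
    info <- tr@info
    expect_equal(sum(info$isDU), 18)
    for (g in which(info$isDU)) {
        a <- tr@piA[[g]]; b <- tr@piB[[g]]
        top <- order(-a)[1:2]
        expect_equal(b[top], a[rev(top)])
        expect_equal(b[-top], a[-top])
        expect_false(isTRUE(all.equal(a, b)))
    }
    for (g in which(!info$isDU))
        expect_identical(tr@piA[[g]], tr@piB[[g]])

    # permute mode: only the top-4 move, K <= 3 permutes everything
    tp <- simulateTruth(nGenes = 80, duFraction = 0.5, mode = "permute",
                        seed = 4)
    for (g in which(tp@info$isDU)) {
        a <- tp@piA[[g]]; b <- tp@piB[[g]]
        m <- min(4, length(a))
        top <- order(-a)[seq_len(m)]
        expect_setequal(b[top], a[top])
        if (m < length(a)) expect_equal(b[-top], a[-top])
        expect_false(isTRUE(all.equal(a, b)))
        expect_equal(sum(b), 1)
    }
    # du_fraction = 0: nothing differs
    t0 <- simulateTruth(nGenes = 10, duFraction = 0, seed = 5)
    expect_false(any(t0@info$isDU))
})

test_that("DU genes are drawn among eligible genes only", {
    tr <- simulateTruth(nGenes = 200, duFraction = 0.2, seed = 6)
    for (g in which(tr@info$isDU))
        expect_gte(sum(tr@piA[[g]] > 0.1), 2)
})

test_that("simulated counts respect the NB/DM hierarchy", {
    tr <- simulateTruth(nGenes = 40, duFraction = 0, seed = 7)
    sim <- simulateCounts(tr, nPerGroup = 4, depth = 300,
                          nbDispersion = 0.1, seed = 7)
    expect_equal(dim(sim$counts), c(sum(tr@info$K), 8L))
    expect_true(all(sim$counts >= 0))
    # gene totals have NB-scale spread: var/mean ratio far above Poisson
    geneTot <- rowsum(sim$counts, sim$txInfo$gene_id)
    expect_gt(var(as.vector(geneTot)) / mean(geneTot), 2)

    # dispersion -> 0: totals concentrate at the mean
    tr2 <- simulateTruth(nGenes = 200, duFraction = 0, seed = 8)
    sim2 <- simulateCounts(tr2, nPerGroup = 1, depth = 400,
                           nbDispersion = 1e-8, seed = 8)
    tot2 <- rowsum(sim2$counts, sim2$txInfo$gene_id)
    expect_lt(abs(mean(tot2) - 400), 3 * sqrt(400 / 400))
    expect_lt(var(as.vector(tot2)) / mean(tot2), 1.5)

    # delta_+ -> infinity: per-sample proportions approach the group mean
    tr3 <- simulateTruth(nGenes = 30, duFraction = 0, seed = 9,
                         precMeanLog = log(1e8), precSdLog = 0)
    sim3 <- simulateCounts(tr3, nPerGroup = 6, depth = 2000, seed = 9,
                           nbDispersion = 1e-8)
    off <- 0
    for (g in seq_len(30)) {
        K <- tr3@info$K[g]
        piMap <- tr3@piA[[g]] * tr3@lengths[[g]]
        piMap <- piMap / sum(piMap)
        cnt <- sim3$counts[off + seq_len(K), 1:6, drop = FALSE]
        props <- colSums(cnt) ; props <- sweep(cnt, 2, colSums(cnt), "/")
        expect_lt(max(abs(rowMeans(props) - piMap)), 0.05)
        off <- off + K
    }
})

test_that("EC simulation conserves reads and honours ambiguity = 0", {
    tr <- simulateTruth(nGenes = 25, duFraction = 0.2, seed = 10)
    sim <- simulateCounts(tr, nPerGroup = 3, depth = 250, seed = 10)
    # ambiguity 0: all classes singletons, EC counts = transcript counts
    ec0 <- simulateECTable(sim, ambiguity = 0, crossGeneProb = 0, seed = 10)
    expect_true(all(vapply(ecClasses(ec0$ec), length, integer(1)) == 1L))
    m <- ecCounts(ec0$ec)
    rownames(m) <- ecTranscripts(ec0$ec)[vapply(ecClasses(ec0$ec), `[`,
                                                integer(1), 1)]
    nz <- rowSums(sim$counts) > 0
    expect_equal(m[rownames(sim$counts)[nz], ],
                 sim$counts[nz, ])

    # ambiguity 0.5: totals still conserved per sample
    ec5 <- simulateECTable(sim, ambiguity = 0.5, seed = 10)
    expect_equal(unname(colSums(ecCounts(ec5$ec))),
                 unname(colSums(sim$counts)))
    # quantification tables carry the true counts
    expect_equal(ec5$quant[[1]]$NumReads,
                 unname(sim$counts[ec5$quant[[1]]$Name, 1]))
})

test_that("generator output is deterministic and passes the IO validators", {
    simA <- simulateDTUData(nGenes = 10, duFraction = 0.2, nPerGroup = 2,
                            depth = 150, seed = 11)
    simB <- simulateDTUData(nGenes = 10, duFraction = 0.2, nPerGroup = 2,
                            depth = 150, seed = 11)
    expect_identical(ecCounts(simA$ec), ecCounts(simB$ec))
    expect_identical(ecClasses(simA$ec), ecClasses(simB$ec))

    dirA <- file.path(tempfile(), "a")
    writeSimulatedData(simA, dirA)
    design <- readDesign(file.path(dirA, "design.tsv"))
    expect_equal(nrow(design), 4L)
    tabs <- lapply(seq_len(nrow(design)), function(i)
        readSalmonEC(design$eq_classes_path[i], design$sample_id[i]))
    back <- mergeECSamples(tabs, design$sample_id)
    expect_equal(sum(ecCounts(back)), sum(ecCounts(simA$ec)))
    gm <- readGeneMap(file.path(dirA, "gene_map.tsv"))
    expect_true(all(ecTranscripts(back) %in% names(gm)))
    q <- readQuantSF(design$quant_path[1])
    expect_equal(nrow(q), length(ecTranscripts(back)))
    # byte-identical files on a rewrite with the same seed
    dirB <- file.path(tempfile(), "b")
    writeSimulatedData(simB, dirB)
    fa <- file.path(dirA, design$sample_id[1], "eq_classes.txt")
    fb <- file.path(dirB, design$sample_id[1], "eq_classes.txt")
    expect_identical(readLines(fa), readLines(fb))
})

test_that("call evaluation computes FDR and TPR with the max(1, calls) guard", {
    truth <- data.frame(gene_id = paste0("G", 1:10),
                        isDU = rep(c(TRUE, FALSE), c(2, 8)))
    res <- data.frame(gene_id = paste0("G", 1:10),
                      p_adj = c(0.001, 0.002, rep(0.5, 8)))
    ev <- evaluateCalls(res, truth, thresholds = c(0.01, 0.6))
    expect_equal(ev$FDR[1], 0)
    expect_equal(ev$TPR[1], 1)
    expect_equal(ev$FDR[2], 0.8)
    # no calls: FDR 0 by the guard
    resNone <- transform(res, p_adj = 0.99)
    evn <- evaluateCalls(resNone, truth, thresholds = 0.01)
    expect_equal(evn$FDR, 0)
    expect_equal(evn$TPR, 0)
})
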