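# Fixture builders used across test files; everything is generated in code.

# write a Salmon-format eq_classes.txt and return its path
writeEcFixture <- function(lines, gz = FALSE) {
    path <- tempfile(fileext = if (gz) ".txt.gz" else ".txt")
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con)
    close(con)
    path
}

# the two-transcript example file: classes {(T1): 7, (T1,T2): 3}
tinyEcLines <- function() c("2", "2", "T1", "T2", "1 0 7", "2 0 1 3")

# a minimal quant.sf
writeQuantFixture <- function(df = NULL) {
    if (is.null(df))
        df <- data.frame(Name = c("T1", "T2"), Length = c(1500, 900),
                         EffectiveLength = c(1342.7, 742.7),
                         TPM = c(10, 5), NumReads = c(250, 60))
    path <- tempfile(fileext = ".sf")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# single-gene cluster with given classes/counts (counts: J x N)
makeCluster <- function(classes, counts, effLen = NULL, genes = NULL,
                        geneOf = NULL, estCounts = NULL) {
    K <- max(unlist(classes))
    tx <- paste0("T", seq_len(K))
    if (is.null(effLen)) effLen <- rep(1000, K)
    if (is.null(genes)) genes <- "G1"
    if (is.null(geneOf)) geneOf <- rep("G1", K)
    counts <- matrix(as.integer(counts), nrow = length(classes),
                     dimnames = list(NULL, paste0("s", seq_len(
                         length(counts) / length(classes)))))
    testable <- vapply(genes, function(g) sum(geneOf == g) >= 2L,
                       logical(1))
    new("GeneCluster", genes = genes, transcripts = tx, geneOf = geneOf,
        effLen = effLen,
        estCounts = if (is.null(estCounts)) matrix(numeric(0), 0, 0)
                    else estCounts,
        classes = lapply(classes, as.integer), counts = counts,
        testable = testable)
}

informativePrior <- function(mean = log(30), var = 0.25) {
    new("PriorSpec", mode = "informative", meanLogPrec = mean,
        varLogPrec = var, vagueVar = 100)
}

# batch-means Monte Carlo standard error
mcse <- function(x, nBatches = 50) {
    n <- length(x) - length(x) %% nBatches
    bm <- tapply(x[seq_len(n)], rep(seq_len(nBatches), each = n / nBatches),
                 mean)
    sd(bm) / sqrt(nBatches)
}
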