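#' Read a Salmon equivalence-class file
#'
#' Parses the text format written by Salmon under
#' \code{aux_info/eq_classes.txt}: two header lines (number of transcripts,
#' number of classes), the transcript names, then one line per class. Both
#' the plain dialect (\code{k t1 ... tk count}) and the weighted dialect
#' (\code{k t1 ... tk w1 ... wk count}) are recognised by token count; the
#' weights of the weighted dialect are discarded, because read allocation is
#' resampled by the model itself. Gzip compression is detected from the
#' magic bytes, not the file extension. Transcript indices in the file are
#' 0-based (Salmon convention) and converted to name-resolved tuples.
#'
#' @param path path to an \code{eq_classes.txt} file, optionally gzipped.
#' @param sample sample identifier; defaults to the directory/file name.
#' @return an \linkS4class{ECTable} with a single sample.
#' @export
readSalmonEC <- function(path, sample = NULL) {
    if (!file.exists(path))
        stop("equivalence-class file not found: ", path)
    if (is.null(sample))
        sample <- basename(dirname(path))
    if (sample %in% c(".", "", "/"))
        sample <- basename(path)
    magic <- readBin(path, "raw", n = 2L)
    con <- if (length(magic) == 2L && magic[1] == as.raw(0x1f) &&
               magic[2] == as.raw(0x8b)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2L)
        stop("malformed header in ", path, ": need transcript and class counts")
    nT <- suppressWarnings(as.integer(trimws(lines[1])))
    nC <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(nT) || is.na(nC) || nT < 0L || nC < 0L)
        stop("malformed header in ", path, " (lines 1-2)")
    if (length(lines) != 2L + nT + nC)
        stop("file ", path, " announces ", nT, " transcripts and ", nC,
             " classes but has ", length(lines) - 2L, " content lines")
    txs <- trimws(lines[seq_len(nT) + 2L])
    if (anyDuplicated(txs))
        stop("duplicated transcript names in ", path)
    classes <- vector("list", nC)
    counts <- integer(nC)
    for (j in seq_len(nC)) {
        lineNo <- 2L + nT + j
        tok <- strsplit(trimws(lines[lineNo]), "[ \t]+")[[1]]
        k <- suppressWarnings(as.integer(tok[1]))
        if (is.na(k) || k < 1L)
            stop("parse error at line ", lineNo, " of ", path,
                 ": invalid class size")
        if (length(tok) == k + 2L) {
            idx <- tok[2:(k + 1L)]
            cnt <- tok[k + 2L]
        } else if (length(tok) == 2L * k + 2L) {
            # weighted dialect: indices, then k weights (ignored), then count
            idx <- tok[2:(k + 1L)]
            cnt <- tok[2L * k + 2L]
        } else {
            stop("parse error at line ", lineNo, " of ", path,
                 ": expected ", k + 2L, " or ", 2L * k + 2L,
                 " fields, found ", length(tok))
        }
        if (!grepl("^[0-9]+$", cnt))
            stop("parse error at line ", lineNo, " of ", path,
                 ": non-integer count '", cnt, "'")
        ii <- suppressWarnings(as.integer(idx))
        if (anyNA(ii) || any(ii < 0L) || any(ii >= nT))
            stop("parse error at line ", lineNo, " of ", path,
                 ": transcript index out of range")
        ii <- ii + 1L  # to 1-based
        if (anyDuplicated(ii))
            stop("parse error at line ", lineNo, " of ", path,
                 ": repeated transcript in class")
        classes[[j]] <- sort(ii)
        counts[j] <- as.integer(cnt)
    }
    keep <- counts > 0L
    new("ECTable",
        transcripts = txs,
        classes = classes[keep],
        counts = matrix(counts[keep], ncol = 1L,
                        dimnames = list(NULL, sample)),
        samples = sample)
}

#' Write an equivalence-class table in the Salmon plain dialect
#'
#' One file per sample; classes with zero count in a sample are omitted from
#' that sample's file (re-merging the files reproduces the table). Indices
#' are written 0-based.
#'
#' @param ec an \linkS4class{ECTable}.
#' @param paths character vector of output paths, one per sample.
#' @export
writeSalmonEC <- function(ec, paths) {
    stopifnot(length(paths) == length(ec@samples))
    for (i in seq_along(paths)) {
        keep <- which(ec@counts[, i] > 0L)
        lines <- c(
            as.character(length(ec@transcripts)),
            as.character(length(keep)),
            ec@transcripts,
            vapply(keep, function(j) {
                cl <- ec@classes[[j]]
                paste(c(length(cl), cl - 1L, ec@counts[j, i]), collapse = "\t")
            }, character(1)))
        writeLines(lines, paths[i])
    }
    invisible(paths)
}

#' Read a Salmon quantification table (quant.sf layout)
#'
#' Requires columns \code{Name}, \code{Length}, \code{EffectiveLength},
#' \code{TPM}, \code{NumReads}. Non-positive effective lengths (degenerate
#' short transcripts) are replaced by 1 with a warning.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{transcript_id},
#'   \code{effective_length}, \code{est_count}.
#' @export
readQuantSF <- function(path) {
    if (!file.exists(path))
        stop("quantification file not found: ", path)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     check.names = FALSE)
    need <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("quantification table ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    el <- as.numeric(df$EffectiveLength)
    bad <- !is.finite(el) | el <= 0
    if (any(bad)) {
        warning(sum(bad), " transcript(s) with non-positive effective length",
                " set to 1 in ", path)
        el[bad] <- 1
    }
    nr <- as.numeric(df$NumReads)
    if (any(!is.finite(nr) | nr < 0))
        stop("negative or non-numeric NumReads in ", path)
    data.frame(transcript_id = as.character(df$Name),
               effective_length = el,
               est_count = nr,
               stringsAsFactors = FALSE)
}

#' Read a transcript-to-gene map
#'
#' Either a GTF/GFF file (any feature rows carrying \code{transcript_id} and
#' \code{gene_id} attributes) or a headerless 2-column TSV in
#' (gene, transcript) order. A transcript assigned to two genes is an error.
#'
#' @param path path to the map file.
#' @param format "auto" (by extension), "gtf" or "tsv".
#' @return named character vector: names are transcript ids, values gene ids.
#' @export
readGeneMap <- function(path, format = c("auto", "gtf", "tsv")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("gene map not found: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.(gtf|gff|gff3)(\\.gz)?$", path,
                            ignore.case = TRUE)) "gtf" else "tsv"
    }
    if (format == "gtf") {
        gr <- rtracklayer::import(path)
        md <- S4Vectors::mcols(gr)
        if (!all(c("transcript_id", "gene_id") %in% colnames(md)))
            stop("GTF ", path, " lacks transcript_id/gene_id attributes")
        tx <- as.character(md$transcript_id)
        gn <- as.character(md$gene_id)
        ok <- !is.na(tx) & !is.na(gn) & nzchar(tx) & nzchar(gn)
        pairs <- unique(data.frame(tx = tx[ok], gn = gn[ok],
                                   stringsAsFactors = FALSE))
    } else {
        df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
        if (ncol(df) < 2L)
            stop("gene map ", path, " needs two columns (gene, transcript)")
        pairs <- unique(data.frame(tx = as.character(df[[2]]),
                                   gn = as.character(df[[1]]),
                                   stringsAsFactors = FALSE))
    }
    if (nrow(pairs) == 0L)
        stop("gene map ", path, " is empty")
    dup <- pairs$tx[duplicated(pairs$tx)]
    if (length(dup))
        stop("transcript(s) assigned to more than one gene: ",
             paste(unique(dup), collapse = ", "))
    setNames(pairs$gn, pairs$tx)
}

#' Read a sample design table
#'
#' TSV with header columns \code{sample_id}, \code{group} and (optionally)
#' \code{eq_classes_path}, \code{quant_path}.
#'
#' @param path path to a TSV file.
#' @return data.frame.
#' @export
readDesign <- function(path) {
    if (!file.exists(path))
        stop("design file not found: ", path)
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "group") %in% colnames(df)) || nrow(df) == 0L)
        stop("design table ", path,
             " must be non-empty with columns sample_id and group")
    df
}

#' Deterministic equivalence-class ordering
#'
#' Classes are kept sorted by size, then lexicographically on their
#' transcript indices, so a table has one canonical representation however
#' it was produced (merge, reduction, simulation); downstream RNG streams
#' then do not depend on input file order.
#' @keywords internal
canonicalClassOrder <- function(classList) {
    order(vapply(classList, length, integer(1)),
          vapply(classList, function(cl)
              paste(sprintf("%09d", cl), collapse = ","), character(1)))
}

#' Merge per-sample equivalence-class tables
#'
#' Classes are matched by transcript names, so samples whose files list
#' transcripts in different orders merge identically. The result is the
#' union of classes; a class absent from a sample gets count 0 there.
#' Classes with zero count in every sample are dropped.
#'
#' @param tables list of single-sample \linkS4class{ECTable} objects.
#' @param sampleIds optional sample names (defaults to each table's own).
#' @return an \linkS4class{ECTable} with one column per sample.
#' @export
mergeECSamples <- function(tables, sampleIds = NULL) {
    stopifnot(length(tables) >= 1L)
    if (is.null(sampleIds))
        sampleIds <- vapply(tables, function(t) t@samples[1], character(1))
    stopifnot(length(sampleIds) == length(tables))
    universe <- tables[[1]]@transcripts
    uset <- sort(universe)
    for (i in seq_along(tables)) {
        ti <- sort(tables[[i]]@transcripts)
        if (!identical(ti, uset))
            stop("sample '", sampleIds[i],
                 "' has a different transcript universe than sample '",
                 sampleIds[1], "'")
    }
    keyed <- new.env(parent = emptyenv())
    classList <- list()
    nS <- length(tables)
    for (i in seq_along(tables)) {
        tb <- tables[[i]]
        # re-index this sample's classes into the shared universe
        remap <- match(tb@transcripts, universe)
        for (j in seq_along(tb@classes)) {
            cl <- sort(remap[tb@classes[[j]]])
            key <- paste(cl, collapse = ",")
            entry <- get0(key, envir = keyed)
            if (is.null(entry)) {
                classList[[length(classList) + 1L]] <- cl
                entry <- list(row = length(classList), counts = integer(nS))
            }
            entry$counts[i] <- entry$counts[i] + tb@counts[j, 1L]
            assign(key, entry, envir = keyed)
        }
    }
    J <- length(classList)
    counts <- matrix(0L, nrow = J, ncol = nS,
                     dimnames = list(NULL, sampleIds))
    for (key in ls(keyed)) {
        entry <- get(key, envir = keyed)
        counts[entry$row, ] <- entry$counts
    }
    ord <- canonicalClassOrder(classList)
    classList <- classList[ord]
    counts <- counts[ord, , drop = FALSE]
    keep <- rowSums(counts) > 0L
    new("ECTable", transcripts = universe, classes = classList[keep],
        counts = counts[keep, , drop = FALSE], samples = sampleIds)
}
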