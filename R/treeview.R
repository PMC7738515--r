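# Clustered-data-table output in the TreeView dialect: a CDT file holding
# the reordered matrix with GID/AID keys, and GTR/ATR files listing the
# feature/sample merge trees as NODEkX records. Scores are stored as
# 1 - merge height (the correlation-similarity convention), written at
# full precision so heights round-trip exactly.

.fmt <- function(x) formatC(x, format = "g", digits = 17)

.treeLines <- function(dnd, leafTag) {
    mm <- merges(dnd)
    h <- mergeHeights(dnd)
    enc <- function(c, k) if (c < 0L) sprintf("%s%dX", leafTag, -c)
        else sprintf("NODE%dX", c)
    vapply(seq_len(nrow(mm)), function(k)
        paste(sprintf("NODE%dX", k), enc(mm[k, 1]), enc(mm[k, 2]),
              .fmt(1 - h[k]), sep = "\t"), "")
}

#' Write clustered data as CDT/GTR/ATR files
#'
#' Serialises a two-dimensional clustering result in the clustered data
#' table dialect used by TreeView-style viewers: `<base>.cdt` holds the
#' matrix reordered by both dendrograms with GID/AID keys, `<base>.gtr`
#' and `<base>.atr` hold the feature and sample merge trees. Either
#' dendrogram may be `NULL`, in which case that axis keeps its input
#' order and no tree file is written.
#'
#' @param mat features x samples matrix in original (pre-clustering)
#'   order, with dimnames.
#' @param featureDendrogram,sampleDendrogram [RppaDendrogram-class]
#'   objects over the rows / columns of `mat`, or `NULL`.
#' @param basePath output path without extension.
#'
#' @return Invisibly, the vector of files written.
#' @seealso [readClusterFiles()]
#' @export
writeClusterFiles <- function(mat, featureDendrogram = NULL,
                              sampleDendrogram = NULL, basePath) {
    stopifnot(is.matrix(mat), !is.null(rownames(mat)),
              !is.null(colnames(mat)))
    fd <- featureDendrogram; sd <- sampleDendrogram
    if (!is.null(fd) && nLeaves(fd) != nrow(mat))
        stop("feature dendrogram has ", nLeaves(fd), " leaves but the ",
             "matrix has ", nrow(mat), " rows")
    if (!is.null(sd) && nLeaves(sd) != ncol(mat))
        stop("sample dendrogram has ", nLeaves(sd), " leaves but the ",
             "matrix has ", ncol(mat), " columns")
    if (!is.null(fd) && !identical(leafLabels(fd), rownames(mat)))
        stop("feature dendrogram labels do not match matrix rownames")
    if (!is.null(sd) && !identical(leafLabels(sd), colnames(mat)))
        stop("sample dendrogram labels do not match matrix colnames")

    rowOrd <- if (is.null(fd)) seq_len(nrow(mat)) else leafOrder(fd)
    colOrd <- if (is.null(sd)) seq_len(ncol(mat)) else leafOrder(sd)
    m <- mat[rowOrd, colOrd, drop = FALSE]

    files <- character(0)
    gid <- sprintf("GENE%dX", rowOrd)
    aid <- sprintf("ARRY%dX", colOrd)

    lines <- c(
        paste(c("GID", "UID", "NAME", "GWEIGHT", colnames(m)),
              collapse = "\t"),
        paste(c("AID", "", "", "", aid), collapse = "\t"),
        paste(c("EWEIGHT", "", "", "", rep("1", ncol(m))),
              collapse = "\t"),
        vapply(seq_len(nrow(m)), function(i)
            paste(c(gid[i], rownames(m)[i], rownames(m)[i], "1",
                    .fmt(m[i, ])), collapse = "\t"), ""))
    cdt <- paste0(basePath, ".cdt")
    writeLines(lines, cdt)
    files <- c(files, cdt)
    if (!is.null(fd)) {
        gtr <- paste0(basePath, ".gtr")
        writeLines(.treeLines(fd, "GENE"), gtr)
        files <- c(files, gtr)
    }
    if (!is.null(sd)) {
        atr <- paste0(basePath, ".atr")
        writeLines(.treeLines(sd, "ARRY"), atr)
        files <- c(files, atr)
    }
    invisible(files)
}

.parseTree <- function(path, leafTag, labels, leafOrd, metric) {
    lines <- readLines(path)
    n <- length(lines) + 1L
    mm <- matrix(0L, n - 1L, 2L)
    h <- numeric(n - 1L)
    dec <- function(tok) {
        if (startsWith(tok, "NODE")) as.integer(sub("^NODE(\\d+)X$", "\\1",
                                                    tok))
        else -as.integer(sub(paste0("^", leafTag, "(\\d+)X$"), "\\1", tok))
    }
    for (k in seq_along(lines)) {
        f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
        node <- as.integer(sub("^NODE(\\d+)X$", "\\1", f[1]))
        mm[node, ] <- c(dec(f[2]), dec(f[3]))
        h[node] <- 1 - as.numeric(f[4])
    }
    inv <- if (n > 2L) sum(diff(h) < -1e-12) else 0L
    new("RppaDendrogram", merges = mm, height = h, labels = labels,
        leafOrder = as.integer(leafOrd), metric = metric,
        inversions = as.integer(inv))
}

#' Read CDT/GTR/ATR files back
#'
#' Parses files written by [writeClusterFiles()], reconstructing the
#' reordered matrix, the leaf orders (from the GID/AID keys) and the
#' merge trees with their heights (`height = 1 - score`).
#'
#' @param basePath path without extension, as passed to the writer.
#' @param metric metric tag to record on the reconstructed dendrograms
#'   (the file format itself does not carry it).
#'
#' @return List with `matrix` (in clustered order), `featureDendrogram`
#'   and `sampleDendrogram` (either may be `NULL` if the tree file is
#'   absent).
#' @export
readClusterFiles <- function(basePath, metric = "unknown") {
    cdt <- paste0(basePath, ".cdt")
    lines <- readLines(cdt)
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    sampleNames <- header[-(1:4)]
    aid <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-(1:4)]
    colOrd <- as.integer(sub("^ARRY(\\d+)X$", "\\1", aid))
    body <- lines[-(1:3)]
    rowOrd <- integer(length(body))
    rowNames <- character(length(body))
    m <- matrix(NA_real_, length(body), length(sampleNames))
    for (i in seq_along(body)) {
        f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
        rowOrd[i] <- as.integer(sub("^GENE(\\d+)X$", "\\1", f[1]))
        rowNames[i] <- f[2]
        m[i, ] <- as.numeric(f[-(1:4)])
    }
    dimnames(m) <- list(rowNames, sampleNames)

    # labels in original (pre-clustering) order
    featLabels <- character(length(rowOrd)); featLabels[rowOrd] <- rowNames
    sampLabels <- character(length(colOrd)); sampLabels[colOrd] <- sampleNames

    gtr <- paste0(basePath, ".gtr")
    atr <- paste0(basePath, ".atr")
    fd <- if (file.exists(gtr))
        .parseTree(gtr, "GENE", featLabels, rowOrd, metric) else NULL
    sd <- if (file.exists(atr))
        .parseTree(atr, "ARRY", sampLabels, colOrd, metric) else NULL
    list(matrix = m, featureDendrogram = fd, sampleDendrogram = sd)
}
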