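# Unsupervised learning: rank-correlation and Euclidean distances, binary
# agglomerative hierarchical clustering with pairwise (unweighted) average
# linkage, two-dimensional clustering and PCA.

.rppaMetrics <- c("spearman", "euclidean", "kendall")

# distances between COLUMNS of m
.distColumns <- function(m, metric) {
    metric <- match.arg(metric, .rppaMetrics)
    labels <- colnames(m)
    if (is.null(labels)) labels <- as.character(seq_len(ncol(m)))
    if (ncol(m) < 2L) stop("need at least 2 items to compute distances")
    if (metric == "euclidean") {
        d <- as.matrix(dist(t(m), method = "euclidean"))
    } else {
        nComplete <- crossprod(!is.na(m))
        r <- suppressWarnings(cor(m, method = metric,
                                  use = "pairwise.complete.obs"))
        d <- 1 - r
        d[nComplete < 3L] <- NA
        diag(d) <- 0
    }
    dimnames(d) <- list(labels, labels)
    attr(d, "metric") <- metric
    d
}

#' @param axis `"columns"` (default) or `"rows"`: which margin holds the
#'   items to be compared.
#' @param metric `"spearman"`, `"euclidean"` or `"kendall"`.
#' @describeIn distanceMatrix distances between rows or columns of a
#'   plain matrix.
#' @export
setMethod("distanceMatrix", "matrix",
          function(x, axis = c("columns", "rows"),
                   metric = c("spearman", "euclidean", "kendall"), ...) {
    axis <- match.arg(axis)
    metric <- match.arg(metric)
    if (axis == "rows") x <- t(x)
    .distColumns(x, metric)
})

#' @param items for a `SummarizedExperiment`: `"features"` (assay rows,
#'   i.e. antibody columns of the study) or `"samples"`.
#' @describeIn distanceMatrix distances between features or samples of a
#'   `SummarizedExperiment` assay.
#' @export
setMethod("distanceMatrix", "SummarizedExperiment",
          function(x, items = c("features", "samples"),
                   metric = c("spearman", "euclidean", "kendall"), ...) {
    items <- match.arg(items)
    metric <- match.arg(metric)
    a <- SummarizedExperiment::assay(x)
    .distColumns(if (items == "features") t(a) else a, metric)
})

#' Binary agglomerative hierarchical clustering, pairwise average linkage
#'
#' UPGMA-style agglomeration: at each step the globally closest pair of
#' clusters is merged, and the distance from the merged cluster to any
#' other is the unweighted mean of the member pairwise distances
#' (maintained via the Lance-Williams update). Ties are broken
#' deterministically by the lowest (left, right) pair of cluster creation
#' indices; when two subtrees merge, the earlier-created one becomes the
#' left child, fixing the leaf order. Average linkage can produce height
#' inversions; they are counted and reported, not hidden.
#'
#' @param d symmetric distance matrix (from [distanceMatrix()]) or a
#'   `dist` object; must be complete (no `NA`).
#'
#' @return An [RppaDendrogram-class].
#' @examples
#' m <- matrix(rnorm(40), nrow = 8)
#' dnd <- hierarchicalCluster(distanceMatrix(m, metric = "euclidean"))
#' leafOrder(dnd)
#' @export
hierarchicalCluster <- function(d) {
    metric <- attr(d, "metric")
    if (is.null(metric)) metric <- "unknown"
    dm <- as.matrix(d)
    n <- nrow(dm)
    labels <- rownames(dm)
    if (is.null(labels)) labels <- as.character(seq_len(n))
    if (n == 1L)
        return(new("RppaDendrogram",
                   merges = matrix(integer(), ncol = 2),
                   height = numeric(), labels = labels, leafOrder = 1L,
                   metric = metric, inversions = 0L))
    if (any(is.na(dm)))
        stop("distance matrix contains missing distances; clustering ",
             "requires a complete matrix")

    # working matrix over cluster creation ids 1..(2n-1)
    N <- 2L * n - 1L
    D <- matrix(Inf, N, N)
    D[seq_len(n), seq_len(n)] <- dm
    diag(D) <- Inf
    size <- c(rep(1L, n), rep(0L, n - 1L))
    active <- rep(FALSE, N); active[seq_len(n)] <- TRUE
    mergeMat <- matrix(0L, n - 1L, 2L)
    heights <- numeric(n - 1L)
    children <- vector("list", N)  # signed hclust-style children per node

    for (step in seq_len(n - 1L)) {
        ids <- which(active)
        sub <- D[ids, ids, drop = FALSE]
        mn <- min(sub)
        w <- which(sub == mn, arr.ind = TRUE)
        # candidates as (i, j) creation-id pairs with i < j
        ii <- ids[pmin(w[, 1], w[, 2])]
        jj <- ids[pmax(w[, 1], w[, 2])]
        pick <- order(ii, jj)[1]
        i <- ii[pick]; j <- jj[pick]

        m <- n + step
        heights[step] <- D[i, j]
        enc <- function(id) if (id <= n) -id else id - n
        mergeMat[step, ] <- c(enc(i), enc(j))  # i < j: earlier-created left
        size[m] <- size[i] + size[j]
        # unweighted average linkage (Lance-Williams)
        others <- ids[!(ids %in% c(i, j))]
        if (length(others)) {
            newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
                size[m]
            D[m, others] <- newd
            D[others, m] <- newd
        }
        active[c(i, j)] <- FALSE
        active[m] <- TRUE
    }

    # leaf order: left-to-right traversal, earlier-created subtree left
    ord <- integer(0)
    traverse <- function(node) {  # node in signed encoding
        if (node < 0L) return(-node)
        c(traverse(mergeMat[node, 1]), traverse(mergeMat[node, 2]))
    }
    ord <- traverse(n - 1L)

    inv <- if (n > 2L) sum(diff(heights) < -1e-12) else 0L
    new("RppaDendrogram", merges = mergeMat, height = heights,
        labels = labels, leafOrder = as.integer(ord), metric = metric,
        inversions = as.integer(inv))
}

# leaf indices under each merge node; list of length n-1
.nodeLeaves <- function(dnd) {
    mm <- merges(dnd)
    out <- vector("list", nrow(mm))
    for (k in seq_len(nrow(mm))) {
        kids <- mm[k, ]
        out[[k]] <- unlist(lapply(kids, function(c)
            if (c < 0L) -c else out[[c]]))
    }
    out
}

# cophenetic distance matrix implied by the merge heights
.copheneticMatrix <- function(dnd) {
    n <- nLeaves(dnd)
    cm <- matrix(0, n, n, dimnames = list(leafLabels(dnd), leafLabels(dnd)))
    if (n < 2L) return(cm)
    mm <- merges(dnd)
    nl <- .nodeLeaves(dnd)
    for (k in seq_len(nrow(mm))) {
        l <- if (mm[k, 1] < 0L) -mm[k, 1] else nl[[mm[k, 1]]]
        r <- if (mm[k, 2] < 0L) -mm[k, 2] else nl[[mm[k, 2]]]
        cm[l, r] <- mergeHeights(dnd)[k]
        cm[r, l] <- mergeHeights(dnd)[k]
    }
    cm
}

#' Two-dimensional hierarchical clustering
#'
#' Clusters the features (antibody columns) and the samples of a matrix
#' independently with [hierarchicalCluster()] under the same metric, and
#' reorders the matrix by both leaf orders.
#'
#' @param x numeric matrix (features x samples) or a
#'   [SummarizedExperiment-class] / [IntegratedRppa-class].
#' @param metric distance metric, see [distanceMatrix()].
#'
#' @return List with `featureDendrogram`, `sampleDendrogram` and
#'   `matrix` (the input assay reordered by both leaf orders).
#' @export
twoWayCluster <- function(x, metric = c("spearman", "euclidean",
                                        "kendall")) {
    metric <- match.arg(metric)
    a <- if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x) else as.matrix(x)
    if (nrow(a) < 2L || ncol(a) < 2L)
        stop("need at least a 2 x 2 matrix for two-dimensional clustering")
    fd <- hierarchicalCluster(distanceMatrix(a, axis = "rows",
                                             metric = metric))
    sd <- hierarchicalCluster(distanceMatrix(a, axis = "columns",
                                             metric = metric))
    list(featureDendrogram = fd, sampleDendrogram = sd,
         matrix = a[leafOrder(fd), leafOrder(sd), drop = FALSE])
}

#' Principal component analysis of an intensity matrix
#'
#' Column-mean-centred singular value decomposition of a samples x
#' features matrix. Missing values are imputed by the feature's median
#' (for the PCA only; recorded in the result). Component signs follow a
#' deterministic convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param x samples x features numeric matrix, or a
#'   [SummarizedExperiment-class] (whose assay is transposed so samples
#'   score as observations).
#' @param nComponents number of components to keep; truncated with a
#'   warning if it exceeds the matrix rank.
#'
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), `varianceFraction`, and `nImputed`.
#' @export
rppaPca <- function(x, nComponents = 2L) {
    m <- if (is(x, "SummarizedExperiment"))
        t(SummarizedExperiment::assay(x)) else as.matrix(x)
    nImputed <- 0L
    if (anyNA(m)) {
        med <- apply(m, 2L, median, na.rm = TRUE)
        idx <- which(is.na(m), arr.ind = TRUE)
        nImputed <- nrow(idx)
        m[idx] <- med[idx[, 2]]
    }
    maxComp <- min(dim(m))
    if (nComponents > maxComp) {
        warning("nComponents reduced to ", maxComp)
        nComponents <- maxComp
    }
    pc <- prcomp(m, center = TRUE, scale. = FALSE)
    tol <- max(pc$sdev) * 1e-10
    rank <- sum(pc$sdev > tol)
    if (nComponents > rank) {
        warning("requested ", nComponents, " components but rank is ",
                rank, "; truncating")
        nComponents <- rank
    }
    keep <- seq_len(nComponents)
    scores <- pc$x[, keep, drop = FALSE]
    loadings <- pc$rotation[, keep, drop = FALSE]
    for (j in seq_len(ncol(loadings))) {
        i0 <- which.max(abs(loadings[, j]))
        if (loadings[i0, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    list(scores = scores, loadings = loadings,
         varianceFraction = (pc$sdev^2 / sum(pc$sdev^2))[keep],
         nImputed = nImputed)
}
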