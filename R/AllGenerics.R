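#' @rdname StudyDesign-accessors
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))
#' @rdname StudyDesign-accessors
#' @export
setGeneric("receptorStatus", function(x) standardGeneric("receptorStatus"))
#' @rdname StudyDesign-accessors
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))
#' @rdname StudyDesign-accessors
#' @export
setGeneric("timepointsMin", function(x) standardGeneric("timepointsMin"))
#' @rdname StudyDesign-accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))
#' @rdname StudyDesign-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname PlatformConfig-accessors
#' @export
setGeneric("platformId", function(x) standardGeneric("platformId"))
#' @rdname PlatformConfig-accessors
#' @export
setGeneric("panelInfo", function(x) standardGeneric("panelInfo"))

#' @rdname RppaDendrogram-accessors
#' @export
setGeneric("merges", function(x) standardGeneric("merges"))
#' @rdname RppaDendrogram-accessors
#' @export
setGeneric("mergeHeights", function(x) standardGeneric("mergeHeights"))
#' @rdname RppaDendrogram-accessors
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))
#' @rdname RppaDendrogram-accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))
#' @rdname RppaDendrogram-accessors
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))
#' @rdname RppaDendrogram-accessors
#' @export
setGeneric("inversions", function(x) standardGeneric("inversions"))

#' Antibody-wise median centring
#'
#' Subtracts from every antibody column its median over the samples used
#' for centring, placing platforms on a common relative scale before
#' concatenation. Missing entries are ignored by the median and carried
#' through unchanged; columns with no observed value are dropped with a
#' warning. Centring is idempotent.
#'
#' For a plain matrix the convention is samples in rows and antibodies in
#' columns (the medians run down each column); for a
#' [SummarizedExperiment-class] the assay rows are antibodies, so medians
#' run along each row.
#'
#' @param x a numeric matrix (samples x antibodies) or a
#'   `SummarizedExperiment` (antibodies x samples).
#' @param ... passed to methods.
#'
#' @return An object of the same shape with per-antibody medians removed.
#' @examples
#' medianCentre(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
setGeneric("medianCentre", function(x, ...) standardGeneric("medianCentre"))

#' Pairwise distance matrix for clustering
#'
#' Computes dissimilarities between rows or columns of an intensity matrix
#' using one of three metrics: `"spearman"` (1 - Spearman rank correlation,
#' average-tie ranks), `"kendall"` (1 - Kendall tau-b) or `"euclidean"`.
#' Rank metrics use pairwise-complete observations and require at least
#' three complete pairs; pairs with fewer yield `NA` distances, which
#' [hierarchicalCluster()] refuses.
#'
#' @param x a numeric matrix or a [SummarizedExperiment-class].
#' @param ... passed to methods (`axis`, `metric`).
#'
#' @return A symmetric numeric matrix of distances with attribute
#'   `"metric"`; zero diagonal; Spearman/Kendall entries lie in [0, 2].
#' @examples
#' m <- matrix(rnorm(30), nrow = 6)
#' d <- distanceMatrix(m, axis = "columns", metric = "spearman")
#' @export
setGeneric("distanceMatrix", function(x, ...) standardGeneric("distanceMatrix"))
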