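#' Accessors for StudyDesign
#'
#' @param x a [StudyDesign-class].
#' @return The corresponding slot; `nSamples()` returns the product of the
#'   factor cardinalities.
#' @name StudyDesign-accessors
NULL

#' @rdname StudyDesign-accessors
#' @export
setMethod("cellLines", "StudyDesign", function(x) x@cellLines)
#' @rdname StudyDesign-accessors
#' @export
setMethod("receptorStatus", "StudyDesign",
          function(x) setNames(x@receptorStatus, x@cellLines))
#' @rdname StudyDesign-accessors
#' @export
setMethod("treatments", "StudyDesign", function(x) x@treatments)
#' @rdname StudyDesign-accessors
#' @export
setMethod("timepointsMin", "StudyDesign", function(x) x@timepointsMin)
#' @rdname StudyDesign-accessors
#' @export
setMethod("nReplicates", "StudyDesign", function(x) x@nReplicates)
#' @rdname StudyDesign-accessors
#' @export
setMethod("nSamples", "StudyDesign", function(x) {
    length(x@cellLines) * length(x@treatments) * length(x@timepointsMin) *
        x@nReplicates
})

setMethod("show", "StudyDesign", function(object) {
    cat("StudyDesign:", length(object@cellLines), "cell lines x",
        length(object@treatments), "treatments x",
        length(object@timepointsMin), "timepoints x",
        object@nReplicates, "replicates =", nSamples(object), "samples\n")
    cat("  cell lines:", paste(object@cellLines, collapse = ", "), "\n")
    cat("  treatments:", paste(object@treatments, collapse = ", "), "\n")
    cat("  timepoints (min):",
        paste(object@timepointsMin, collapse = ", "), "\n")
})

#' Accessors for PlatformConfig
#'
#' @param x a [PlatformConfig-class].
#' @return `platformId()` the platform name; `panelInfo()` the antibody
#'   panel data.frame.
#' @name PlatformConfig-accessors
NULL

#' @rdname PlatformConfig-accessors
#' @export
setMethod("platformId", "PlatformConfig", function(x) x@platformId)
#' @rdname PlatformConfig-accessors
#' @export
setMethod("panelInfo", "PlatformConfig", function(x) x@panel)

setMethod("show", "PlatformConfig", function(object) {
    cat("PlatformConfig '", object@platformId, "': ",
        nrow(object@panel), " antibodies, ",
        length(unique(object@panel$antigen_class)), " antigen classes\n",
        sep = "")
    cat("  dilution steps:", object@nDilutionSteps,
        " technical replicates:", object@nTechnicalReplicates,
        " floor:", object@detectionFloor, "\n")
    cat("  normalisation:", object@normalisation, "\n")
})

#' Accessors for RppaDendrogram
#'
#' @param x an [RppaDendrogram-class].
#' @return `merges()` the (n-1) x 2 signed merge matrix (hclust
#'   convention); `mergeHeights()` the merge dissimilarities;
#'   `leafOrder()` the left-to-right leaf permutation; `leafLabels()` the
#'   labels in input order; `nLeaves()` the leaf count; `inversions()` the
#'   number of merges lower than their predecessor.
#' @name RppaDendrogram-accessors
NULL

#' @rdname RppaDendrogram-accessors
#' @export
setMethod("merges", "RppaDendrogram", function(x) x@merges)
#' @rdname RppaDendrogram-accessors
#' @export
setMethod("mergeHeights", "RppaDendrogram", function(x) x@height)
#' @rdname RppaDendrogram-accessors
#' @export
setMethod("leafOrder", "RppaDendrogram", function(x) x@leafOrder)
#' @rdname RppaDendrogram-accessors
#' @export
setMethod("leafLabels", "RppaDendrogram", function(x) x@labels)
#' @rdname RppaDendrogram-accessors
#' @export
setMethod("nLeaves", "RppaDendrogram", function(x) length(x@labels))
#' @rdname RppaDendrogram-accessors
#' @export
setMethod("inversions", "RppaDendrogram", function(x) x@inversions)

setMethod("show", "RppaDendrogram", function(object) {
    cat("RppaDendrogram:", nLeaves(object), "leaves,", object@metric,
        "distance, average linkage\n")
    if (nLeaves(object) > 1L)
        cat("  merge heights: [", format(min(object@height), digits = 4),
            ",", format(max(object@height), digits = 4), "],",
            object@inversions, "inversion(s)\n")
})

setMethod("show", "IntegratedRppa", function(object) {
    callNextMethod()
    md <- S4Vectors::metadata(object)
    if (!is.null(md$readings))
        cat("readings per platform:",
            paste(names(md$readings), unlist(md$readings), sep = "=",
                  collapse = ", "),
            "| total:", sum(unlist(md$readings)), "\n")
    if (length(md$dropped_classes))
        cat("dropped antigen classes:",
            paste(md$dropped_classes, collapse = ", "), "\n")
})
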