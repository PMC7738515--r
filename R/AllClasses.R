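#' @import methods
#' @importFrom stats median cor dist prcomp lm.fit density bw.nrd0 pnorm
#'   setNames var complete.cases
#' @importFrom utils combn head read.delim write.table packageVersion
NULL

#' Multi-platform RPPA study design
#'
#' Describes the factorial layout of a cell-line perturbation study: cell
#' lines (with receptor-status labels), treatments, timepoints and the
#' number of biological replicates per condition. The sample count implied
#' by a design is the product of the four factor cardinalities.
#'
#' @slot cellLines character vector of cell-line names.
#' @slot receptorStatus character vector of receptor-status labels, parallel
#'   to `cellLines` (e.g. `"Her2+"`, `"TNBC"`).
#' @slot treatments character vector of treatment names (drugs or vehicle).
#' @slot timepointsMin numeric vector of treatment durations in minutes.
#' @slot nReplicates integer, biological replicates per condition.
#'
#' @seealso [StudyDesign()], [defaultStudyDesign()], [generateDesign()]
#' @export
setClass("StudyDesign",
    representation(
        cellLines = "character",
        receptorStatus = "character",
        treatments = "character",
        timepointsMin = "numeric",
        nReplicates = "integer"
    )
)

setValidity("StudyDesign", function(object) {
    msg <- character()
    if (length(object@cellLines) < 1L) msg <- c(msg, "no cell lines")
    if (length(object@treatments) < 1L) msg <- c(msg, "no treatments")
    if (length(object@timepointsMin) < 1L) msg <- c(msg, "no timepoints")
    if (length(object@nReplicates) != 1L || is.na(object@nReplicates) ||
        object@nReplicates < 1L)
        msg <- c(msg, "nReplicates must be a single integer >= 1")
    if (length(object@receptorStatus) != length(object@cellLines))
        msg <- c(msg, "receptorStatus must be parallel to cellLines")
    if (anyDuplicated(object@cellLines))
        msg <- c(msg, "duplicated cell-line names")
    if (anyDuplicated(object@treatments))
        msg <- c(msg, "duplicated treatment names")
    if (anyDuplicated(object@timepointsMin))
        msg <- c(msg, "duplicated timepoints")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a StudyDesign
#'
#' @param cellLines character vector of cell-line names.
#' @param receptorStatus character vector of receptor-status labels parallel
#'   to `cellLines`; defaults to `"unknown"`.
#' @param treatments character vector of treatment names.
#' @param timepointsMin numeric vector of treatment durations (minutes).
#' @param nReplicates number of biological replicates per condition.
#'
#' @return A [StudyDesign-class] object.
#' @examples
#' d <- StudyDesign(c("SKBR3", "MCF7"), treatments = c("DMSO", "lapatinib"),
#'                  timepointsMin = 20, nReplicates = 3)
#' nSamples(d)
#' @export
StudyDesign <- function(cellLines,
                        receptorStatus = rep("unknown", length(cellLines)),
                        treatments, timepointsMin, nReplicates = 3L) {
    new("StudyDesign",
        cellLines = as.character(cellLines),
        receptorStatus = as.character(receptorStatus),
        treatments = as.character(treatments),
        timepointsMin = as.numeric(timepointsMin),
        nReplicates = as.integer(nReplicates))
}

#' Synthetic RPPA platform configuration
#'
#' Describes one RPPA platform's antibody panel and measurement model:
#' each antibody has a target antigen class, a multiplicative gain and an
#' additive offset on the log2 scale, and a spot-level noise standard
#' deviation. The platform spots each sample as a serial two-fold dilution
#' series with `nDilutionSteps` points in `nTechnicalReplicates` technical
#' replicates, and censors linear intensities at `detectionFloor`.
#'
#' @slot platformId platform name.
#' @slot panel data.frame with columns `antibody_id`, `antigen_class`,
#'   `phospho_site`, `supplier_ref`, `gain`, `offset`, `noise_sd`.
#' @slot nDilutionSteps integer, number of serial two-fold dilution points
#'   (step 0 = undiluted).
#' @slot nTechnicalReplicates integer, spots per (sample, dilution).
#' @slot detectionFloor numeric, lower limit of linear intensity.
#' @slot normalisation default normalisation strategy for the platform,
#'   `"total_protein"` or `"dilution_intercept"`.
#'
#' @seealso [PlatformConfig()], [defaultPlatformConfigs()], [renderPlatform()]
#' @export
setClass("PlatformConfig",
    representation(
        platformId = "character",
        panel = "data.frame",
        nDilutionSteps = "integer",
        nTechnicalReplicates = "integer",
        detectionFloor = "numeric",
        normalisation = "character"
    )
)

setValidity("PlatformConfig", function(object) {
    msg <- character()
    p <- object@panel
    need <- c("antibody_id", "antigen_class", "phospho_site",
              "supplier_ref", "gain", "offset", "noise_sd")
    if (!all(need %in% names(p)))
        msg <- c(msg, paste("panel lacks columns:",
                            paste(setdiff(need, names(p)), collapse = ", ")))
    else {
        if (anyDuplicated(p$antibody_id))
            msg <- c(msg, "panel antibody_id values must be unique")
        if (any(p$gain <= 0)) msg <- c(msg, "panel gains must be > 0")
        if (any(p$noise_sd < 0)) msg <- c(msg, "panel noise_sd must be >= 0")
    }
    if (object@nDilutionSteps < 1L) msg <- c(msg, "nDilutionSteps must be >= 1")
    if (object@nTechnicalReplicates < 1L)
        msg <- c(msg, "nTechnicalReplicates must be >= 1")
    if (object@detectionFloor < 0) msg <- c(msg, "detectionFloor must be >= 0")
    if (!object@normalisation %in% c("total_protein", "dilution_intercept"))
        msg <- c(msg, "normalisation must be 'total_protein' or 'dilution_intercept'")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a PlatformConfig
#'
#' @param platformId platform name.
#' @param panel antibody panel data.frame (see [PlatformConfig-class]).
#' @param nDilutionSteps serial two-fold dilution points per sample.
#' @param nTechnicalReplicates spots per (sample, dilution).
#' @param detectionFloor linear-intensity lower detection limit.
#' @param normalisation default normalisation strategy.
#'
#' @return A [PlatformConfig-class] object.
#' @export
PlatformConfig <- function(platformId, panel, nDilutionSteps = 4L,
                           nTechnicalReplicates = 2L, detectionFloor = 2,
                           normalisation = c("total_protein",
                                             "dilution_intercept")) {
    panel <- as.data.frame(panel, stringsAsFactors = FALSE)
    new("PlatformConfig",
        platformId = as.character(platformId), panel = panel,
        nDilutionSteps = as.integer(nDilutionSteps),
        nTechnicalReplicates = as.integer(nTechnicalReplicates),
        detectionFloor = as.numeric(detectionFloor),
        normalisation = match.arg(normalisation))
}

#' Binary agglomerative clustering result
#'
#' A dendrogram produced by [hierarchicalCluster()]: `merges` records the
#' n-1 binary merges in the order performed, using the `hclust` sign
#' convention (negative entries are leaves, positive entries index earlier
#' merge rows); `height` is the average-linkage dissimilarity at each
#' merge. Average linkage admits height inversions; their count is kept in
#' `inversions` rather than silently reordered away.
#'
#' @slot merges two-column integer matrix of merge children.
#' @slot height numeric merge heights (dissimilarities).
#' @slot labels leaf labels in input order.
#' @slot leafOrder integer permutation of leaves (left-to-right traversal,
#'   earlier-created subtree on the left).
#' @slot metric distance metric the tree was built from.
#' @slot inversions number of merges lower than their predecessor.
#'
#' @seealso [hierarchicalCluster()], [leafOrder()], [writeClusterFiles()]
#' @export
setClass("RppaDendrogram",
    representation(
        merges = "matrix",
        height = "numeric",
        labels = "character",
        leafOrder = "integer",
        metric = "character",
        inversions = "integer"
    )
)

setValidity("RppaDendrogram", function(object) {
    n <- length(object@labels)
    msg <- character()
    if (n > 1L) {
        if (nrow(object@merges) != n - 1L)
            msg <- c(msg, "need n-1 merges for n leaves")
        if (length(object@height) != n - 1L)
            msg <- c(msg, "need n-1 heights")
        kids <- as.vector(object@merges)
        if (anyDuplicated(kids))
            msg <- c(msg, "each node may be used once as a child")
        if (any(object@height < -1e-12))
            msg <- c(msg, "heights must be non-negative")
    }
    if (length(object@leafOrder) != n ||
        !setequal(object@leafOrder, seq_len(n)))
        msg <- c(msg, "leafOrder must be a permutation of the leaves")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Integrated multi-platform RPPA matrix
#'
#' A [SummarizedExperiment-class] whose rows are antibody-platform columns
#' of the integrated study (the horizontal-concatenation axis) and whose
#' columns are samples. `rowData` carries `antibody_uid`, `antigen_class`
#' and `platform_id` for every feature; `metadata()` records the centring
#' subset, per-platform reading counts and dropped antigen classes.
#'
#' @seealso [integratePlatforms()]
#' @export
setClass("IntegratedRppa", contains = "SummarizedExperiment")

setValidity("IntegratedRppa", function(object) {
    need <- c("antibody_uid", "antigen_class", "platform_id")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(need %in% names(rd)))
        return(paste("rowData must carry:", paste(need, collapse = ", ")))
    key <- paste(rd$antibody_uid, rd$platform_id)
    if (anyDuplicated(key))
        return("duplicated (antibody_uid, platform_id) features")
    TRUE
})
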