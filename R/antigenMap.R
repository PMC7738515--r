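# Clustered antibody antigen map: antigen classes (alphabetical) as rows,
# antibody-platform columns in clustered leaf order, cells holding the
# integer index of the column's antibody within its class. Plus
# concordance scoring of the column dendrogram.

#' Build the clustered antibody antigen map
#'
#' Expands antibody antigen annotations into a matrix aligned with a
#' clustered column order: rows are antigen classes in alphabetical
#' order, columns are the antibody-platform leaves in clustered order,
#' and the single filled cell per column holds that antibody's fixed
#' integer index within its class. Indices are assigned by sorted
#' antibody uid, enumerating from 1, so they are a property of the
#' antibody, not of the leaf order.
#'
#' @param leafUids character vector of antibody uids in clustered leaf
#'   order (one entry per column; uids repeat when the same antibody is
#'   used on several platforms).
#' @param annotations data.frame with columns `antibody_uid` and
#'   `antigen_class` covering every leaf.
#' @param leafNames optional column names for the map (defaults to
#'   `leafUids`).
#'
#' @return Integer matrix (classes x leaves) with `NA` for empty cells;
#'   exactly one filled cell per column.
#' @examples
#' ann <- data.frame(antibody_uid = c("Akt_a", "Her2_a", "Her2_b"),
#'                   antigen_class = c("Akt", "Her2", "Her2"))
#' buildAntigenMap(c("Her2_b", "Akt_a", "Her2_a"), ann)
#' @export
buildAntigenMap <- function(leafUids, annotations, leafNames = NULL) {
    ann <- unique(as.data.frame(
        annotations)[, c("antibody_uid", "antigen_class")])
    if (anyDuplicated(ann$antibody_uid))
        stop("annotations map antibody uid(s) to multiple antigen ",
             "classes: ",
             paste(unique(ann$antibody_uid[duplicated(ann$antibody_uid)]),
                   collapse = ", "))
    cls <- ann$antigen_class[match(leafUids, ann$antibody_uid)]
    if (anyNA(cls))
        stop("unannotated antibody uid(s): ",
             paste(unique(leafUids[is.na(cls)]), collapse = ", "))
    classes <- sort(unique(ann$antigen_class))
    # fixed per-antibody index within its class, by sorted uid, from 1
    idx <- integer(nrow(ann))
    for (cl in classes) {
        i <- which(ann$antigen_class == cl)
        idx[i] <- match(ann$antibody_uid[i], sort(ann$antibody_uid[i]))
    }
    map <- matrix(NA_integer_, nrow = length(classes),
                  ncol = length(leafUids),
                  dimnames = list(classes,
                                  if (is.null(leafNames)) leafUids
                                  else leafNames))
    map[cbind(match(cls, classes), seq_along(leafUids))] <-
        idx[match(leafUids, ann$antibody_uid)]
    map
}

#' Score cross-platform and cross-antibody concordance
#'
#' Quantifies how often antibodies targeting the same antigen class end
#' up adjacent in a column dendrogram. Under the default `"sibling"`
#' rule, a leaf "clusters with" class C if the sibling subtree at its
#' parent merge node contains a leaf annotated with C; the sibling set is
#' computed as the leaves at minimal cophenetic distance, which equals
#' the parent-node sibling subtree on tie-free trees and extends it to
#' the whole plateau when several merges occur at the same height (as
#' happens with identical profiles). Under `"k_cophenetic_neighbours"`
#' the k leaves closest in cophenetic distance are used instead. An antigen class is concordant
#' cross-platform if any of its leaves clusters with a same-class leaf
#' from a different platform, and concordant cross-antibody if any of
#' its leaves clusters with a same-class leaf carrying a different
#' antibody uid. Summary fractions are reported over the classes
#' eligible for each criterion (measured on >= 2 platforms / by >= 2
#' distinct antibodies), with the denominators stated explicitly.
#'
#' @param dendrogram [RppaDendrogram-class] over the antibody-platform
#'   columns.
#' @param annotations data.frame with one row per leaf, in leaf *label*
#'   order (i.e. parallel to `leafLabels(dendrogram)`), with columns
#'   `antibody_uid`, `platform_id`, `antigen_class`.
#' @param rule `"sibling"` or `"k_cophenetic_neighbours"`.
#' @param k neighbourhood size for the cophenetic rule.
#'
#' @return List with `per_class` (data.frame of per-class flags,
#'   platform and antibody counts) and `summary` (the two fractions and
#'   their denominators).
#' @export
scoreConcordance <- function(dendrogram, annotations,
                             rule = c("sibling",
                                      "k_cophenetic_neighbours"),
                             k = 3L) {
    rule <- match.arg(rule)
    ann <- as.data.frame(annotations)
    need <- c("antibody_uid", "platform_id", "antigen_class")
    miss <- setdiff(need, names(ann))
    if (length(miss))
        stop("annotations lack column(s): ", paste(miss, collapse = ", "))
    n <- nLeaves(dendrogram)
    if (nrow(ann) != n)
        stop("need one annotation row per leaf")

    neighbours <- vector("list", n)
    cm <- .copheneticMatrix(dendrogram)
    if (rule == "sibling") {
        # the sibling subtree at the leaf's parent merge is exactly the
        # set of leaves at minimal cophenetic distance; phrasing it this
        # way also covers tied merges, where several subtrees join at the
        # same height and the whole plateau is the effective sibling set
        for (i in seq_len(n)) {
            others <- setdiff(seq_len(n), i)
            h <- min(cm[i, others])
            neighbours[[i]] <-
                others[cm[i, others] <= h + 1e-9 * (1 + abs(h))]
        }
    } else {
        for (i in seq_len(n)) {
            others <- setdiff(seq_len(n), i)
            neighbours[[i]] <- others[order(cm[i, others],
                                            others)][seq_len(min(k,
                                                                 n - 1L))]
        }
    }

    classes <- sort(unique(ann$antigen_class))
    per <- do.call(rbind, lapply(classes, function(cl) {
        i <- which(ann$antigen_class == cl)
        nPlat <- length(unique(ann$platform_id[i]))
        nAb <- length(unique(ann$antibody_uid[i]))
        crossPlat <- FALSE; crossAb <- FALSE
        for (leaf in i) {
            nb <- neighbours[[leaf]]
            same <- nb[ann$antigen_class[nb] == cl]
            if (length(same)) {
                if (any(ann$platform_id[same] != ann$platform_id[leaf]))
                    crossPlat <- TRUE
                if (any(ann$antibody_uid[same] != ann$antibody_uid[leaf]))
                    crossAb <- TRUE
            }
        }
        data.frame(antigen_class = cl, n_platforms = nPlat,
                   n_antibodies = nAb,
                   eligible_cross_platform = nPlat >= 2L,
                   eligible_cross_antibody = nAb >= 2L,
                   clusters_cross_platform = crossPlat,
                   clusters_cross_antibody = crossAb,
                   stringsAsFactors = FALSE)
    }))
    rownames(per) <- NULL
    ep <- per$eligible_cross_platform
    ea <- per$eligible_cross_antibody
    summary <- data.frame(
        criterion = c("same antigen, other platform",
                      "same antigen, different antibody"),
        n_eligible = c(sum(ep), sum(ea)),
        n_concordant = c(sum(per$clusters_cross_platform[ep]),
                         sum(per$clusters_cross_antibody[ea])),
        fraction = c(
            if (sum(ep)) mean(per$clusters_cross_platform[ep]) else NA_real_,
            if (sum(ea)) mean(per$clusters_cross_antibody[ea]) else NA_real_),
        stringsAsFactors = FALSE)
    list(per_class = per, summary = summary, rule = rule,
         k = if (rule == "k_cophenetic_neighbours") k else NA_integer_)
}
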