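# Cross-platform dataset integration: antigen classification, unique
# antibody identifier assignment, antibody-wise median centring and
# horizontal concatenation, keeping only antigen classes measured on all
# platforms.

#' Classify antibody targets into antigen classes
#'
#' Maps each antibody's declared target(s) to one canonical antigen
#' class. Multiple declared targets are separated by `";"`. A synonym
#' table (named character vector, raw target -> class) merges antibodies
#' recognising a protein together with a close isoform or family member
#' into one class; e.g. with the rule `c("Erk1" = "Erk1/2")`, targets
#' `"Erk1"` and `"Erk1/2"` both classify as `"Erk1/2"`. Distinct
#' phospho-sites on the same protein remain distinct classes.
#'
#' @param targets character vector of declared target descriptions, one
#'   per antibody (`";"`-separated for multi-target antibodies).
#' @param synonyms named character vector mapping raw targets to canonical
#'   classes; unlisted targets map to themselves.
#'
#' @return Character vector of antigen classes, parallel to `targets`.
#' @examples
#' classifyAntigens(c("Erk1", "Erk1/2"), synonyms = c("Erk1" = "Erk1/2"))
#' @export
classifyAntigens <- function(targets, synonyms = NULL) {
    vapply(seq_along(targets), function(i) {
        raw <- trimws(strsplit(targets[i], ";", fixed = TRUE)[[1]])
        mapped <- ifelse(raw %in% names(synonyms), synonyms[raw], raw)
        classes <- unique(mapped)
        if (length(classes) != 1L)
            stop("unresolved antigen class for antibody ", i, " ('",
                 targets[i], "'): targets map to ",
                 paste(classes, collapse = ", "),
                 "; supply a synonym rule")
        classes
    }, "")
}

# letter suffixes a, b, ..., z, aa, ab, ... for antibody uids
.uidSuffix <- function(k) {
    if (k <= 26L) letters[k]
    else paste0(letters[(k - 1L) %/% 26L], letters[(k - 1L) %% 26L + 1L])
}

#' Assign unique antibody identifiers
#'
#' Gives every distinct physical antibody a study-wide unique identifier
#' of the form `<antigen class>_<letter>` (e.g. `"Her2_a"`). Antibodies
#' are deduplicated by catalogue/supplier reference: the same
#' `supplier_ref` used on several platforms receives the same uid. Letter
#' suffixes are assigned in sorted `supplier_ref` order within each
#' antigen class, so the assignment is deterministic and independent of
#' input row order.
#'
#' @param annotations data.frame with columns `antibody_id`,
#'   `platform_id`, `antigen_class`, `supplier_ref` and optionally
#'   `phospho_site`.
#'
#' @return The input with an `antibody_uid` column added.
#' @examples
#' ann <- data.frame(antibody_id = c("x", "y", "z"),
#'                   platform_id = c("p1", "p2", "p1"),
#'                   antigen_class = "Her2",
#'                   supplier_ref = c("AB-2", "AB-1", "AB-1"))
#' assignAntibodyUids(ann)$antibody_uid  # Her2_b, Her2_a, Her2_a
#' @export
assignAntibodyUids <- function(annotations) {
    need <- c("antibody_id", "platform_id", "antigen_class", "supplier_ref")
    miss <- setdiff(need, names(annotations))
    if (length(miss))
        stop("annotations lack column(s): ", paste(miss, collapse = ", "))
    ann <- as.data.frame(annotations)
    if ("phospho_site" %in% names(ann)) {
        key <- paste(ann$supplier_ref, ann$antigen_class)
        site <- vapply(split(as.character(ann$phospho_site), key),
                       function(s) length(unique(s[!is.na(s)])), 0L)
        if (any(site > 1L))
            stop("annotation conflict: supplier reference(s) with ",
                 "inconsistent phospho_site: ",
                 paste(names(site)[site > 1L], collapse = "; "))
    }
    uid <- character(nrow(ann))
    for (cls in unique(ann$antigen_class)) {
        i <- which(ann$antigen_class == cls)
        refs <- sort(unique(ann$supplier_ref[i]))
        suffix <- vapply(seq_along(refs), .uidSuffix, "")
        uid[i] <- paste0(cls, "_",
                         suffix[match(ann$supplier_ref[i], refs)])
    }
    ann$antibody_uid <- uid
    ann
}

#' @param na.rm ignored (medians always skip missing values).
#' @describeIn medianCentre columns of a samples x antibodies matrix are
#'   centred; all-missing columns are dropped with a warning.
#' @export
setMethod("medianCentre", "matrix", function(x, na.rm = TRUE, ...) {
    med <- apply(x, 2L, median, na.rm = TRUE)
    empty <- is.na(med)
    if (any(empty)) {
        warning("dropping ", sum(empty), " all-missing column(s)")
        x <- x[, !empty, drop = FALSE]
        med <- med[!empty]
    }
    sweep(x, 2L, med, "-")
})

#' @describeIn medianCentre assay rows (antibodies) of a
#'   `SummarizedExperiment` are centred across its samples.
#' @export
setMethod("medianCentre", "SummarizedExperiment", function(x, ...) {
    a <- SummarizedExperiment::assay(x)
    centred <- t(medianCentre(t(a)))
    keep <- rownames(a) %in% rownames(centred)
    x <- x[keep, ]
    SummarizedExperiment::assay(x) <- centred
    x
})

#' Integrate processed platform matrices
#'
#' Builds the single multi-platform matrix used by all downstream
#' analyses: assigns study-wide unique antibody identifiers from supplier
#' references, median-centres each platform antibody-wise over the sample
#' subset being analysed, horizontally concatenates the platforms, and
#' drops every antigen class that is not measured on all (by default)
#' platforms. Missing values are carried, not imputed.
#'
#' @param experiments named list of processed platform
#'   [SummarizedExperiment-class] objects (from [processPlatform()]); all
#'   must share the same sample set.
#' @param samples optional character vector restricting the analysis (and
#'   the centring) to a sample subset, e.g. control samples only;
#'   `NULL` keeps all samples.
#' @param sampleData optional sample annotation data.frame (with a
#'   `sample_id` column, e.g. from [generateDesign()]) attached as
#'   `colData`.
#' @param minPlatforms antigen classes measured on fewer platforms are
#'   excluded entirely; defaults to all supplied platforms.
#'
#' @return An [IntegratedRppa-class] (features = antibody-platform
#'   columns x samples) with assay `centred`, rowData provenance, and
#'   `metadata()` entries `readings` (per-platform reading counts),
#'   `dropped_classes` and `centring_samples`.
#' @examples
#' sim <- simulateRppaStudy(seed = 1)
#' cfgs <- defaultPlatformConfigs()
#' pes <- mapply(processPlatform, sim$spots, cfgs)
#' ir <- integratePlatforms(pes)
#' dim(ir)  # 87 features x 108 samples
#' @export
integratePlatforms <- function(experiments, samples = NULL,
                               sampleData = NULL,
                               minPlatforms = length(experiments)) {
    stopifnot(length(experiments) >= 1L)
    pids <- vapply(experiments, function(e)
        S4Vectors::metadata(e)$platform_id, "")

    sampleSets <- lapply(experiments, colnames)
    all_samples <- sampleSets[[1]]
    for (k in seq_along(sampleSets)[-1]) {
        missing <- c(setdiff(all_samples, sampleSets[[k]]),
                     setdiff(sampleSets[[k]], all_samples))
        if (length(missing))
            stop("platforms do not share the same sample set; mismatched ",
                 "sample(s) for '", pids[k], "': ",
                 paste(sort(unique(missing)), collapse = ", "))
    }
    if (!is.null(samples)) {
        missing <- setdiff(samples, all_samples)
        if (length(missing))
            stop("requested sample(s) absent: ",
                 paste(missing, collapse = ", "))
        all_samples <- samples
    }

    # study-wide uid assignment over the pooled panels
    pooledAnn <- do.call(rbind, lapply(seq_along(experiments), function(k) {
        rd <- as.data.frame(SummarizedExperiment::rowData(experiments[[k]]))
        data.frame(antibody_id = rd$antibody_id,
                   platform_id = unname(pids[k]),
                   antigen_class = rd$antigen_class,
                   phospho_site = rd$phospho_site,
                   supplier_ref = rd$supplier_ref,
                   stringsAsFactors = FALSE)
    }))
    pooledAnn <- assignAntibodyUids(pooledAnn)

    parts <- lapply(seq_along(experiments), function(k) {
        e <- experiments[[k]][, all_samples]
        e <- medianCentre(e)
        a <- SummarizedExperiment::assay(e)
        ann <- pooledAnn[pooledAnn$platform_id == pids[k], ]
        ann <- ann[match(rownames(a), ann$antibody_id), ]
        rownames(a) <- paste0(ann$antibody_uid, ".", pids[k])
        list(values = a, ann = ann)
    })

    values <- do.call(rbind, lapply(parts, `[[`, "values"))
    ann <- do.call(rbind, lapply(parts, `[[`, "ann"))

    # keep only antigen classes measured on >= minPlatforms platforms
    perClass <- vapply(split(ann$platform_id, ann$antigen_class),
                       function(p) length(unique(p)), 0L)
    dropped <- sort(names(perClass)[perClass < minPlatforms])
    keep <- !(ann$antigen_class %in% dropped)
    values <- values[keep, , drop = FALSE]
    ann <- ann[keep, , drop = FALSE]

    readings <- lapply(split(seq_len(nrow(ann)), ann$platform_id),
                       function(i) length(i) * ncol(values))
    readings <- readings[unique(ann$platform_id)]

    rd <- S4Vectors::DataFrame(ann, row.names = rownames(values))
    cd <- if (!is.null(sampleData)) {
        sd <- as.data.frame(sampleData)
        stopifnot("sample_id" %in% names(sd))
        missing <- setdiff(all_samples, sd$sample_id)
        if (length(missing))
            stop("sampleData lacks sample(s): ",
                 paste(missing, collapse = ", "))
        S4Vectors::DataFrame(sd[match(all_samples, sd$sample_id), ],
                             row.names = all_samples)
    } else S4Vectors::DataFrame(row.names = all_samples)
    new("IntegratedRppa", SummarizedExperiment::SummarizedExperiment(
        assays = list(centred = values), rowData = rd, colData = cd,
        metadata = list(readings = readings, dropped_classes = dropped,
                        centring_samples = all_samples,
                        platforms = unname(pids))))
}

#' Total reading count of an integrated matrix
#'
#' Number of processed data points: retained antibody columns times
#' samples, summed over platforms.
#'
#' @param x an [IntegratedRppa-class].
#' @return Integer count.
#' @export
readingCount <- function(x) {
    stopifnot(is(x, "IntegratedRppa"))
    sum(unlist(S4Vectors::metadata(x)$readings))
}
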