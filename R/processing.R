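# Per-platform processing: spot-level raw intensities to one processed,
# normalised log2 value per (sample, antibody). Simplified stand-ins for
# the in-house pipelines: technical-replicate medians, an OLS fit to the
# serial two-fold dilution series on the log2 scale (slope -1 expected in
# range), and either the fitted undiluted intercept or total-protein
# division as the normalisation strategy.

#' Aggregate technical replicates to dilution series
#'
#' Collapses spot-level technical replicates to one intensity per
#' (sample, antibody, dilution step) using the median, robust to single
#' bad spots.
#'
#' @param spots raw spot table (see [renderPlatform()] /
#'   [readSpotTable()]).
#'
#' @return A data.table with columns `sample_id`, `antibody_id`,
#'   `dilution_step`, `intensity` (median over technical replicates),
#'   `n_spots`.
#' @examples
#' s <- data.frame(sample_id = "s1", antibody_id = "ab",
#'                 dilution_step = 0L, technical_replicate = 1:3,
#'                 intensity = c(100, 110, 90))
#' aggregateReplicates(s)$intensity  # 100
#' @export
aggregateReplicates <- function(spots) {
    need <- c("sample_id", "antibody_id", "dilution_step", "intensity")
    miss <- setdiff(need, names(spots))
    if (length(miss))
        stop("spot table lacks column(s): ", paste(miss, collapse = ", "))
    dt <- data.table::as.data.table(spots)
    intensity <- NULL  # NSE note for R CMD check
    agg <- dt[, list(intensity = stats::median(intensity),
                     n_spots = .N),
              by = c("sample_id", "antibody_id", "dilution_step")]
    data.table::setorderv(agg, c("sample_id", "antibody_id",
                                 "dilution_step"))
    agg[]
}

#' Fit a serial-dilution series
#'
#' Ordinary least squares of log2(intensity) on the integer dilution step.
#' With exact serial two-fold dilutions the slope is -1 and the intercept
#' estimates the undiluted log2 intensity; slopes far from -1 flag
#' saturation or out-of-range behaviour.
#'
#' @param dilutionStep integer dilution steps (0 = undiluted).
#' @param intensity linear intensities, same length.
#' @param detectionFloor optional linear floor; a series entirely at or
#'   below the floor is flagged unquantifiable (`NA` estimate).
#'
#' @return List with `estimate` (fitted log2 intensity at step 0), `slope`
#'   (log2 per step), `r2`, and `flag` (`"ok"`, `"unquantifiable"` or
#'   `"degenerate"`).
#' @examples
#' fitDilutionSeries(0:3, c(800, 400, 200, 100))  # slope -1, r2 1
#' @export
fitDilutionSeries <- function(dilutionStep, intensity,
                              detectionFloor = NULL) {
    stopifnot(length(dilutionStep) == length(intensity))
    ok <- is.finite(intensity) & intensity > 0
    if (!is.null(detectionFloor) && all(intensity[ok] <= detectionFloor))
        return(list(estimate = NA_real_, slope = NA_real_, r2 = NA_real_,
                    flag = "unquantifiable"))
    if (length(unique(dilutionStep[ok])) < 2L)
        return(list(estimate = NA_real_, slope = NA_real_, r2 = NA_real_,
                    flag = "degenerate"))
    x <- dilutionStep[ok]
    y <- log2(intensity[ok])
    fit <- stats::lm.fit(cbind(1, x), y)
    resid <- fit$residuals
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum(resid^2) / tss else 1
    list(estimate = unname(fit$coefficients[1]),
         slope = unname(fit$coefficients[2]), r2 = r2, flag = "ok")
}

# Vectorised dilution fitting over a balanced aggregated table.
# Returns a data.table keyed by (sample_id, antibody_id).
fitAllSeries <- function(agg, detectionFloor = NULL) {
    agg <- data.table::as.data.table(agg)
    dilution_step <- intensity <- NULL
    fits <- agg[, {
        f <- fitDilutionSeries(dilution_step, intensity, detectionFloor)
        nfl <- if (is.null(detectionFloor)) 0L
               else sum(intensity <= detectionFloor)
        list(estimate = f$estimate, slope = f$slope, r2 = f$r2,
             flag = f$flag, n_floored = nfl)
    }, by = c("sample_id", "antibody_id")]
    fits[]
}

#' Total-protein normalisation
#'
#' Divides every antibody intensity by its sample's total-protein stain
#' intensity, correcting for the amount of printed protein. Operates on
#' linear intensities; preserves the within-sample rank order of
#' antibodies.
#'
#' @param values numeric matrix of linear intensities, samples in rows,
#'   antibodies in columns.
#' @param totalProtein per-sample linear total-protein intensities, named
#'   by or ordered as the rows of `values`; must be strictly positive.
#'
#' @return The normalised matrix.
#' @export
normaliseTotalProtein <- function(values, totalProtein) {
    stopifnot(is.matrix(values))
    if (!is.null(names(totalProtein)) && !is.null(rownames(values)))
        totalProtein <- totalProtein[rownames(values)]
    if (length(totalProtein) != nrow(values))
        stop("need one total-protein value per sample")
    bad <- !is.finite(totalProtein) | totalProtein <= 0
    if (any(bad)) {
        who <- if (!is.null(rownames(values))) rownames(values)[bad]
               else which(bad)
        stop("non-positive total-protein intensity for sample(s): ",
             paste(who, collapse = ", "))
    }
    values / totalProtein
}

#' Binary-logarithm transform with missing-value guards
#'
#' Elementwise log2. Non-positive or non-finite entries cannot be
#' log-transformed; they are set to `NA` and a warning reports their
#' count. Existing `NA`s propagate.
#'
#' @param values numeric matrix.
#' @return Matrix of log2 values.
#' @export
log2Matrix <- function(values) {
    stopifnot(is.numeric(values))
    bad <- !is.na(values) & (!is.finite(values) | values <= 0)
    if (any(bad)) {
        warning(sum(bad), " non-positive value(s) set to NA before log2")
        values[bad] <- NA
    }
    log2(values)
}

#' Dynamic-range quality control of dilution fits
#'
#' Summarises fitted dilution slopes per antibody and per platform: the
#' fraction of series whose slope lies within a band around the ideal
#' two-fold value of -1, and the fraction flagged below detection.
#'
#' @param fits fit table from [fitAllSeries()] (internally produced by
#'   [processPlatform()], available in its `metadata()$qc`).
#' @param slopeBand numeric length-2, acceptable slope interval
#'   (default -1 +/- 0.5).
#'
#' @return List with `per_antibody` (data.frame: antibody, n series,
#'   fraction in range, fraction below detection) and `summary` (the same
#'   fractions over all series).
#' @export
qcDynamicRange <- function(fits, slopeBand = c(-1.5, -0.5)) {
    fits <- as.data.frame(fits)
    stopifnot(all(c("antibody_id", "slope", "flag") %in% names(fits)))
    inRange <- !is.na(fits$slope) & fits$slope >= slopeBand[1] &
        fits$slope <= slopeBand[2]
    below <- fits$flag == "unquantifiable"
    per <- do.call(rbind, lapply(split(seq_len(nrow(fits)),
                                       fits$antibody_id), function(i)
        data.frame(antibody_id = fits$antibody_id[i[1]],
                   n_series = length(i),
                   frac_in_range = mean(inRange[i]),
                   frac_below_detection = mean(below[i]))))
    rownames(per) <- NULL
    list(per_antibody = per,
         summary = data.frame(n_series = nrow(fits),
                              frac_in_range = mean(inRange),
                              frac_below_detection = mean(below)))
}

#' Process a platform's raw spots into a log2 intensity matrix
#'
#' Full simplified per-platform pipeline: technical replicates are
#' collapsed by the median, each (sample, antibody) dilution series is fit
#' by OLS on the log2 scale, and the fitted undiluted intensity is
#' normalised either by total-protein division (`"total_protein"`, using
#' the platform's total-protein stain series) or taken directly as the
#' dilution-fit intercept (`"dilution_intercept"`). The result is one
#' processed log2 value per (sample, antibody).
#'
#' @param spots raw spot table for one platform.
#' @param pconfig the platform's [PlatformConfig-class].
#' @param method normalisation strategy; defaults to the platform's
#'   configured strategy.
#'
#' @return A [SummarizedExperiment-class] with assay `log2intensity`
#'   (antibodies x samples), the panel as `rowData`, and
#'   `metadata()` entries `platform_id`, `method` and `qc` (per-series
#'   fit table).
#' @examples
#' sim <- simulateRppaStudy(seed = 1)
#' pe <- processPlatform(sim$spots$platformA,
#'                       defaultPlatformConfigs()$platformA)
#' dim(pe)
#' @export
processPlatform <- function(spots, pconfig,
                            method = c("config", "total_protein",
                                       "dilution_intercept")) {
    stopifnot(is(pconfig, "PlatformConfig"))
    method <- match.arg(method)
    if (method == "config") method <- pconfig@normalisation

    agg <- aggregateReplicates(spots)
    fits <- fitAllSeries(agg, detectionFloor = pconfig@detectionFloor)

    tp <- fits[fits$antibody_id == .TOTAL_PROTEIN_ID, ]
    fits <- fits[fits$antibody_id != .TOTAL_PROTEIN_ID, ]
    panel <- pconfig@panel
    unknown <- setdiff(unique(fits$antibody_id), panel$antibody_id)
    if (length(unknown))
        stop("spot table contains antibodies absent from the panel: ",
             paste(unknown, collapse = ", "))

    samples <- unique(agg$sample_id)
    m <- matrix(NA_real_, nrow = nrow(panel), ncol = length(samples),
                dimnames = list(panel$antibody_id, samples))
    m[cbind(match(fits$antibody_id, panel$antibody_id),
            match(fits$sample_id, samples))] <- fits$estimate

    if (method == "total_protein") {
        if (!nrow(tp))
            stop("total-protein normalisation requested but the spot table ",
                 "has no '", .TOTAL_PROTEIN_ID, "' series")
        tpEst <- setNames(tp$estimate, tp$sample_id)[samples]
        if (any(!is.finite(tpEst)))
            stop("unquantifiable total-protein series for sample(s): ",
                 paste(samples[!is.finite(tpEst)], collapse = ", "))
        # division on the linear scale == subtraction of log2 intercepts
        lin <- normaliseTotalProtein(t(2^m), 2^tpEst)
        m <- t(log2Matrix(lin))
    }

    rd <- S4Vectors::DataFrame(panel, row.names = panel$antibody_id)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2intensity = m), rowData = rd,
        metadata = list(platform_id = pconfig@platformId, method = method,
                        qc = as.data.frame(fits),
                        n_floored_spots = attr(spots, "n_floored")))
}
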