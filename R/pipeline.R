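# End-to-end pipeline: simulate -> process -> integrate -> cluster ->
# map -> correlate -> differential, driven by one validated configuration
# with a single top-level seed, writing TSV/CDT artefacts plus a JSON run
# manifest.

.configDefaults <- function() list(
    seed = 1L,
    metric = "spearman",
    concordanceRule = "sibling",
    concordanceK = 3L,
    s0 = 1,
    fdrThreshold = 0.05,
    nPermutations = 1000L,
    nEff = NULL,
    centring = "analysis-subset",
    controlTreatment = "DMSO",
    controlTimepointMin = 20,
    contrasts = "sensitive",
    design = NULL,
    antigenConfig = NULL,
    platforms = NULL)

#' Build a validated pipeline configuration
#'
#' Collects every tunable of the pipeline into one list with defaults.
#' Unknown keys are rejected before any computation. Complex components
#' (`design`, `antigenConfig`, `platforms`) default to the package's
#' standard synthetic study when left `NULL`.
#'
#' @param ... configuration overrides; the full key list (`seed`, `metric`,
#'   `concordanceRule`, `concordanceK`, `s0`, `fdrThreshold`,
#'   `nPermutations`, `nEff`, `centring`, `controlTreatment`,
#'   `controlTimepointMin`, `contrasts`, `design`, `antigenConfig`,
#'   `platforms`).
#'
#' @return A named configuration list of class `rppaPipelineConfig`.
#' @examples
#' cfg <- rppaPipelineConfig(seed = 42, metric = "kendall")
#' @export
rppaPipelineConfig <- function(...) {
    cfg <- .configDefaults()
    user <- list(...)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    if (length(user)) cfg[names(user)] <- user
    stopifnot(cfg$metric %in% c("spearman", "euclidean", "kendall"),
              cfg$concordanceRule %in% c("sibling",
                                         "k_cophenetic_neighbours"),
              cfg$s0 >= 0,
              cfg$fdrThreshold > 0, cfg$fdrThreshold < 1,
              cfg$nPermutations >= 1,
              cfg$centring %in% c("analysis-subset", "all-samples"))
    class(cfg) <- "rppaPipelineConfig"
    cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar keys of [rppaPipelineConfig()] may be set from a structured
#' text (YAML) file; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
loadPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(rppaPipelineConfig, vals)
}

#' Run the full multi-platform RPPA pipeline
#'
#' Executes simulate, process, integrate (a control-only and an
#' all-sample integration), cluster, antigen-map, correlate and
#' differential stages, writing every artefact under `outputDir`:
#' processed per-platform matrices, integrated matrices, CDT/GTR/ATR
#' cluster files, the antigen map and concordance report, the pair
#' correlation table and group medians, per-contrast differential tables,
#' and `manifest.json` echoing the configuration, seed and package
#' version. Runs are deterministic: the same configuration (including
#' seed) writes byte-identical TSV outputs.
#'
#' @param config from [rppaPipelineConfig()].
#' @param outputDir artefact directory, created if needed.
#'
#' @return Invisibly, a list with the in-memory stage results
#'   (`samples`, `platformExperiments`, `integratedControl`,
#'   `integratedAll`, `clustering`, `antigenMap`, `concordance`,
#'   `correlations`, `medianComparison`, `differential`, `files`).
#' @export
runRppaPipeline <- function(config = rppaPipelineConfig(), outputDir) {
    stopifnot(inherits(config, "rppaPipelineConfig"))
    if (missing(outputDir)) stop("outputDir is required")
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    started <- character(0)
    stage <- function(name, expr) {
        started <<- c(started, name)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    seed <- config$seed
    design <- config$design %||% defaultStudyDesign()
    antigenConfig <- config$antigenConfig %||% defaultAntigenConfig()
    platforms <- config$platforms %||% defaultPlatformConfigs()
    files <- character(0)
    out <- function(f) file.path(outputDir, f)
    keep <- function(p) files <<- c(files, p)

    sim <- stage("simulate", simulateRppaStudy(design, antigenConfig,
                                               platforms, seed))
    for (pid in names(sim$spots))
        keep(writeSpotTable(sim$spots[[pid]],
                            out(sprintf("spots_%s.tsv", pid)),
                            stage = "simulate", seed = seed,
                            config = config))

    pes <- stage("process", {
        lapply(platforms, function(p)
            processPlatform(sim$spots[[platformId(p)]], p))
    })
    for (pe in pes)
        keep(writeIntensityMatrix(
            pe, out(sprintf("processed_%s.tsv",
                            S4Vectors::metadata(pe)$platform_id)),
            stage = "process", seed = seed, config = config))

    controlSamples <- sim$samples$sample_id[
        sim$samples$treatment == config$controlTreatment &
        sim$samples$timepoint_min == config$controlTimepointMin]
    ic <- stage("integrate", integratePlatforms(
        pes,
        samples = if (config$centring == "analysis-subset")
            controlSamples else NULL,
        sampleData = sim$samples))
    if (config$centring != "analysis-subset")
        ic <- ic[, controlSamples]
    ia <- stage("integrate", integratePlatforms(pes,
                                                sampleData = sim$samples))
    keep(writeIntensityMatrix(ic, out("integrated_control.tsv"),
                              stage = "integrate", seed = seed,
                              config = config))
    keep(writeIntensityMatrix(ia, out("integrated_all.tsv"),
                              stage = "integrate", seed = seed,
                              config = config))

    cl <- stage("cluster", twoWayCluster(ia, metric = config$metric))
    keep(writeClusterFiles(SummarizedExperiment::assay(ia),
                           cl$featureDendrogram, cl$sampleDendrogram,
                           out("clustered_all")))

    rd <- as.data.frame(SummarizedExperiment::rowData(ia))
    amap <- stage("map", buildAntigenMap(rd$antibody_uid[
        leafOrder(cl$featureDendrogram)], rd,
        leafNames = rownames(ia)[leafOrder(cl$featureDendrogram)]))
    conc <- stage("map", scoreConcordance(cl$featureDendrogram, rd,
                                          rule = config$concordanceRule,
                                          k = config$concordanceK))
    mapDf <- data.frame(antigen_class = rownames(amap), amap,
                        check.names = FALSE, stringsAsFactors = FALSE)
    keep(writeTsv(mapDf, out("antigen_map.tsv"), stage = "map",
                  seed = seed, config = config))
    keep(writeTsv(conc$summary, out("concordance_summary.tsv"),
                  stage = "map", seed = seed, config = config))
    keep(writeTsv(conc$per_class, out("concordance_per_class.tsv"),
                  stage = "map", seed = seed, config = config))

    pairs <- stage("correlate", pairwiseCorrelations(ia))
    keep(writeTsv(pairs, out("correlation_pairs.tsv"),
                  stage = "correlate", seed = seed, config = config))
    grp <- summariseCorrelations(pairs, "like_vs_all")
    nEff <- config$nEff %||% ncol(ia)
    cmp <- stage("correlate", compareMedianCorrelations(
        grp$groups$like_antigen, grp$groups$all_pairs, nEff = nEff))
    keep(writeTsv(data.frame(group = names(grp$medians),
                             median_r_s = unname(grp$medians)),
                  out("correlation_medians.tsv"), stage = "correlate",
                  seed = seed, config = config))

    contrasts <- config$contrasts
    if (identical(contrasts, "sensitive")) {
        sens <- antigenConfig$sensitivity
        sens <- sens[sens$sensitive &
                     sens$cell_line %in% cellLines(design) &
                     sens$treatment %in% treatments(design),
                     c("cell_line", "treatment")]
        contrasts <- merge(sens,
                           data.frame(timepoint_min =
                                          timepointsMin(design)))
    }
    diffs <- stage("differential", {
        res <- list()
        for (i in seq_len(nrow(contrasts))) {
            key <- sprintf("%s_%s_t%g", contrasts$cell_line[i],
                           contrasts$treatment[i],
                           contrasts$timepoint_min[i])
            r <- runContrast(ia, contrasts$cell_line[i],
                             contrasts$treatment[i],
                             contrasts$timepoint_min[i],
                             vehicle = config$controlTreatment,
                             s0 = config$s0,
                             nPermutations = config$nPermutations,
                             fdrThreshold = config$fdrThreshold,
                             seed = deriveSeed(seed, key))
            res[[key]] <- r
            keep(writeTsv(volcanoTable(r),
                          out(sprintf("differential_%s.tsv",
                                      gsub("[^A-Za-z0-9_]", "-", key))),
                          stage = "differential", seed = seed,
                          config = config))
        }
        res
    })

    manifest <- list(
        package = "multiRppa",
        version = as.character(packageVersion("multiRppa")),
        seed = seed,
        config_hash = configHash(config),
        config = config[vapply(config, function(v)
            is.null(v) || is.atomic(v), TRUE)],
        stages = started,
        n_samples = nrow(sim$samples),
        readings_all = readingCount(ia),
        readings_control = readingCount(ic),
        concordance = conc$summary,
        median_comparison = cmp[c("median_1", "median_2", "z", "p")],
        files = basename(files))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    keep(out("manifest.json"))

    invisible(list(samples = sim$samples, platformExperiments = pes,
                   integratedControl = ic, integratedAll = ia,
                   clustering = cl, antigenMap = amap,
                   concordance = conc, correlations = pairs,
                   medianComparison = cmp, differential = diffs,
                   files = files))
}
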