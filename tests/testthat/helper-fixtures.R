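# Shared fixtures, built in code. The default-study objects are cached in
# an environment so expensive stages run once per test session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, .fixtureCache)) assign(key, force(expr), .fixtureCache)
    get(key, .fixtureCache)
}

defaultSim <- function() cached("sim", simulateRppaStudy(seed = 101L))

defaultProcessed <- function() cached("pes", {
    cfgs <- defaultPlatformConfigs()
    pes <- lapply(names(cfgs), function(n)
        processPlatform(defaultSim()$spots[[n]], cfgs[[n]]))
    names(pes) <- names(cfgs)
    pes
})

controlSampleIds <- function(samples)
    samples$sample_id[samples$treatment == "DMSO" &
                      samples$timepoint_min == 20]

defaultIntegratedControl <- function() cached("ic", {
    sim <- defaultSim()
    integratePlatforms(defaultProcessed(),
                       samples = controlSampleIds(sim$samples),
                       sampleData = sim$samples)
})

defaultIntegratedAll <- function() cached("ia",
    integratePlatforms(defaultProcessed(),
                       sampleData = defaultSim()$samples))

# Noise-free study: identical rendering of the latent antigens on all
# platforms — zero replicate/spot/loading noise, unit gain (Euclidean
# distance is not scale-invariant, so "the same antigen on every
# platform" requires equal gains; offsets cancel in median centring),
# and no censoring.
noiseFreeProcessed <- function() cached("nf", {
    cfg <- defaultAntigenConfig(replicateSd = 0, loadingSd = 0)
    plats <- lapply(defaultPlatformConfigs(noiseSd = 0), function(p) {
        p@detectionFloor <- 0
        p@panel$gain <- 1
        p
    })
    sim <- simulateRppaStudy(antigenConfig = cfg, platforms = plats,
                             seed = 7L)
    pes <- lapply(names(plats), function(n)
        processPlatform(sim$spots[[n]], plats[[n]]))
    names(pes) <- names(plats)
    list(sim = sim, pes = pes,
         integrated = integratePlatforms(pes, sampleData = sim$samples))
})

# a small fast study for pipeline-level tests
smallStudyConfig <- function(seed = 5L) {
    design <- StudyDesign(
        cellLines = c("MDA-MB-231", "MCF7"),
        receptorStatus = c("TNBC", "ER+"),
        treatments = c("DMSO", "selumetinib"),
        timepointsMin = 20, nReplicates = 3L)
    rppaPipelineConfig(seed = seed, design = design)
}

# tiny single-antibody platform for rendering contracts
tinyPlatform <- function(gain = 1, offset = 0, noiseSd = 0,
                         nSteps = 1L, nTech = 1L, floor = 0,
                         class = "Akt") {
    PlatformConfig(
        "tiny",
        data.frame(antibody_id = "ab1", antigen_class = class,
                   phospho_site = NA_character_, supplier_ref = "AB-1",
                   gain = gain, offset = offset, noise_sd = noiseSd),
        nDilutionSteps = nSteps, nTechnicalReplicates = nTech,
        detectionFloor = floor, normalisation = "dilution_intercept")
}

tinyLatent <- function(values, class = "Akt") {
    # values: named numeric (sample -> log2 abundance), no loading
    samples <- data.frame(
        sample_id = names(values), cell_line = "L1",
        receptor_status = "unknown", treatment = "DMSO",
        timepoint_min = 20, replicate = seq_along(values))
    m <- matrix(values, nrow = 1,
                dimnames = list(class, names(values)))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2abundance = m),
        colData = S4Vectors::DataFrame(samples,
                                       loading = rep(0, length(values)),
                                       row.names = names(values)))
}
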