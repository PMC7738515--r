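# Synthetic multi-platform RPPA study generator. Emulates a three-platform,
# six-cell-line, two-drug, two-timepoint, triplicate design with serial
# two-fold dilution series and platform-specific gains/offsets/noise, and
# keeps the latent ground truth so downstream stages can be benchmarked.

# Run `expr` under a local RNG state so generators are seed-deterministic
# without clobbering the caller's stream.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit({
            if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# One top-level seed deterministically derives per-stage seeds (kept below
# 2^31 so they remain valid R integers).
deriveSeed <- function(seed, stage) {
    stopifnot(is.character(stage), length(stage) == 1L)
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Default six-cell-line, two-drug study design
#'
#' Six breast cancer cell lines spanning distinct receptor subtypes,
#' treated with an EGFR/Her2 inhibitor (lapatinib), a MEK inhibitor
#' (selumetinib) or vehicle (DMSO) for 20 min or 24 h in biological
#' triplicate: 6 x 3 x 2 x 3 = 108 samples.
#'
#' @return A [StudyDesign-class].
#' @examples
#' nSamples(defaultStudyDesign())  # 108
#' @export
defaultStudyDesign <- function() {
    StudyDesign(
        cellLines = c("MCF7", "MDA-MB-231", "MDA-MB-468", "MDA-MB-453",
                      "HCC1954", "SKBR3"),
        receptorStatus = c("ER+", "TNBC", "TNBC", "Her2+", "Her2+", "Her2+"),
        treatments = c("DMSO", "lapatinib", "selumetinib"),
        timepointsMin = c(20, 1440),
        nReplicates = 3L)
}

#' Expand a study design into its sample records
#'
#' Produces the full factorial sample table in deterministic order: cell
#' line varies slowest, then treatment, timepoint and replicate.
#'
#' @param design a [StudyDesign-class].
#'
#' @return A data.frame with columns `sample_id`, `cell_line`,
#'   `receptor_status`, `treatment`, `timepoint_min`, `replicate`; one row
#'   per sample, `sample_id` unique.
#' @examples
#' nrow(generateDesign(defaultStudyDesign()))  # 108
#' @export
generateDesign <- function(design) {
    stopifnot(is(design, "StudyDesign"))
    validObject(design)
    g <- expand.grid(
        replicate = seq_len(design@nReplicates),
        timepoint_min = design@timepointsMin,
        treatment = design@treatments,
        cell_line = design@cellLines,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g <- g[, c("cell_line", "treatment", "timepoint_min", "replicate")]
    g$receptor_status <- receptorStatus(design)[g$cell_line]
    g$sample_id <- sprintf("%s.%s.t%g.r%d", g$cell_line, g$treatment,
                           g$timepoint_min, g$replicate)
    rownames(g) <- NULL
    g[, c("sample_id", "cell_line", "receptor_status", "treatment",
          "timepoint_min", "replicate")]
}

#' Default antigen classes of the synthetic panels
#'
#' Twenty-five protein and phospho-protein antigen classes from the
#' EGFR/Her2, MAPK and PI3K-Akt-mTOR signalling axes probed by typical
#' breast-cancer RPPA panels. Phospho-sites are distinct classes from
#' their total proteins.
#'
#' @return Character vector of antigen-class names.
#' @export
defaultAntigenClasses <- function() {
    c("Akt", "Akt_pS473", "Akt_pT308",
      "CyclinD1",
      "EGFR", "EGFR_pY1068",
      "Erk1/2", "Erk1/2_pT202/Y204",
      "GSK3b_pS9",
      "Her2", "Her2_pY1248",
      "MEK1/2", "MEK1/2_pS217/221",
      "mTOR", "mTOR_pS2448",
      "p38_pT180/Y182", "PDK1_pS241",
      "PI3K_p110a", "PTEN",
      "Rb_pS807/811",
      "S6", "S6_pS235/236",
      "Src_pY416",
      "STAT3", "STAT3_pY705")
}

#' Default drug-sensitivity flags
#'
#' Which (cell line, drug) pairs respond in the synthetic ground truth:
#' the Her2-amplified SKBR3 and HCC1954 lines are lapatinib-sensitive,
#' MDA-MB-231 is selumetinib-sensitive, and MCF7 (no Her2/EGFR
#' overexpression) is lapatinib-insensitive. Pairs absent from the table
#' are insensitive.
#'
#' @return data.frame with columns `cell_line`, `treatment`, `sensitive`.
#' @export
defaultSensitivity <- function() {
    data.frame(
        cell_line = c("SKBR3", "HCC1954", "MDA-MB-231", "MCF7", "SKBR3"),
        treatment = c("lapatinib", "lapatinib", "selumetinib", "lapatinib",
                      "selumetinib"),
        sensitive = c(TRUE, TRUE, TRUE, FALSE, FALSE),
        stringsAsFactors = FALSE)
}

# Benchmark log2 drug effects for sensitive lines. Magnitudes are
# benchmarks chosen for testability, not estimates of real biology: strong
# pathway inhibition is -2 to -2.5 log2, feedback upregulation +0.5 to
# +1.5 log2, with effects larger at 24 h than 20 min.
defaultEffects <- function() {
    e <- function(class, line, drug, tp, eff)
        data.frame(antigen_class = class, cell_line = line, treatment = drug,
                   timepoint_min = tp, effect = eff,
                   stringsAsFactors = FALSE)
    rbind(
        # MEK inhibition in the sensitive TNBC line: pErk1/2 collapses,
        # pMEK1/2 rises at 24 h through relief of negative feedback.
        e("Erk1/2_pT202/Y204", "MDA-MB-231", "selumetinib", 20, -2.0),
        e("Erk1/2_pT202/Y204", "MDA-MB-231", "selumetinib", 1440, -2.5),
        e("MEK1/2_pS217/221", "MDA-MB-231", "selumetinib", 20, 0.5),
        e("MEK1/2_pS217/221", "MDA-MB-231", "selumetinib", 1440, 1.5),
        e("S6_pS235/236", "MDA-MB-231", "selumetinib", 1440, -1.0),
        # EGFR/Her2 inhibition in Her2-amplified lines: receptor and
        # downstream Akt/Erk phosphorylation fall.
        e("Her2_pY1248", "SKBR3", "lapatinib", 20, -2.0),
        e("Her2_pY1248", "SKBR3", "lapatinib", 1440, -2.5),
        e("EGFR_pY1068", "SKBR3", "lapatinib", 20, -1.5),
        e("EGFR_pY1068", "SKBR3", "lapatinib", 1440, -2.0),
        e("Akt_pS473", "SKBR3", "lapatinib", 20, -1.5),
        e("Akt_pS473", "SKBR3", "lapatinib", 1440, -2.0),
        e("Akt_pT308", "SKBR3", "lapatinib", 1440, -1.5),
        e("Erk1/2_pT202/Y204", "SKBR3", "lapatinib", 20, -1.5),
        e("Erk1/2_pT202/Y204", "SKBR3", "lapatinib", 1440, -1.8),
        e("S6_pS235/236", "SKBR3", "lapatinib", 1440, -1.2),
        e("mTOR_pS2448", "SKBR3", "lapatinib", 1440, -0.8),
        e("Her2_pY1248", "HCC1954", "lapatinib", 20, -1.5),
        e("Her2_pY1248", "HCC1954", "lapatinib", 1440, -2.0),
        e("Akt_pS473", "HCC1954", "lapatinib", 1440, -1.5),
        e("Erk1/2_pT202/Y204", "HCC1954", "lapatinib", 1440, -1.2))
}

#' Default latent-antigen configuration
#'
#' Ground-truth model for the generator: per-(antigen, cell line) log2
#' baselines, drug effects gated by sensitivity flags, replicate noise and
#' a per-sample loading factor acting as a total-protein confounder.
#'
#' Baselines are drawn once from Normal(8, 1.5) log2 units under a fixed
#' configuration seed, giving each antigen a distinct cell-line profile
#' (config is data: the same call always returns the same table).
#'
#' @param antigenClasses antigen-class names.
#' @param cellLineNames cell-line names.
#' @param effects data.frame of log2 effects (`antigen_class`, `cell_line`,
#'   `treatment`, `timepoint_min`, `effect`).
#' @param sensitivity data.frame of sensitivity flags (see
#'   [defaultSensitivity()]).
#' @param replicateSd biological replicate noise sd, log2 units.
#' @param loadingSd per-sample loading-factor sd, log2 units (total-protein
#'   confounder; 0 disables it).
#' @param baselineSeed seed fixing the baseline table.
#'
#' @return A list with elements `baselines` (antigen x cell line matrix),
#'   `effects`, `sensitivity`, `replicateSd`, `loadingSd`.
#' @export
defaultAntigenConfig <- function(antigenClasses = defaultAntigenClasses(),
                                 cellLineNames =
                                     cellLines(defaultStudyDesign()),
                                 effects = defaultEffects(),
                                 sensitivity = defaultSensitivity(),
                                 replicateSd = 0.25,
                                 loadingSd = 0.3,
                                 baselineSeed = 1918L) {
    if (replicateSd < 0 || loadingSd < 0)
        stop("noise standard deviations must be >= 0")
    baselines <- withSeed(baselineSeed, {
        matrix(rnorm(length(antigenClasses) * length(cellLineNames),
                     8, 1.5),
               nrow = length(antigenClasses),
               dimnames = list(antigenClasses, cellLineNames))
    })
    list(baselines = baselines, effects = effects,
         sensitivity = sensitivity,
         replicateSd = replicateSd, loadingSd = loadingSd)
}

#' Simulate latent antigen abundances
#'
#' Builds the ground-truth antigen-class x sample matrix of log2
#' abundances: cell-line baseline, plus the treatment x timepoint effect
#' for (antigen, cell line, drug) combinations flagged sensitive, plus
#' replicate noise ~ Normal(0, `replicateSd`). A per-sample loading factor
#' ~ Normal(0, `loadingSd`) is drawn and stored in `colData` (platforms
#' add it to every spot; total-protein normalisation removes it).
#'
#' @param samples sample table from [generateDesign()].
#' @param antigenConfig configuration list (see [defaultAntigenConfig()]).
#' @param seed integer seed; identical (config, seed) pairs give identical
#'   output.
#'
#' @return A [SummarizedExperiment-class] with assay `log2abundance`
#'   (antigen classes x samples), the sample table plus `loading` as
#'   `colData`, and the applied effect table in `metadata()$effects`.
#' @examples
#' des <- generateDesign(defaultStudyDesign())
#' lat <- simulateLatentAntigens(des, defaultAntigenConfig(), seed = 1)
#' dim(lat)
#' @export
simulateLatentAntigens <- function(samples, antigenConfig, seed) {
    cfg <- antigenConfig
    if (cfg$replicateSd < 0) stop("replicateSd must be >= 0")
    bl <- cfg$baselines
    antigens <- rownames(bl)
    missingLines <- setdiff(unique(samples$cell_line), colnames(bl))
    if (length(missingLines))
        stop("no baselines for cell line(s): ",
             paste(missingLines, collapse = ", "))
    eff <- cfg$effects
    if (nrow(eff)) {
        bad <- !(eff$antigen_class %in% antigens)
        if (any(bad))
            stop("effects reference unknown antigen class(es): ",
                 paste(unique(eff$antigen_class[bad]), collapse = ", "))
    }

    values <- bl[, samples$cell_line, drop = FALSE]
    colnames(values) <- samples$sample_id

    # gate effects by the sensitivity flags
    sens <- cfg$sensitivity
    sensKey <- sens$sensitive[match(paste(samples$cell_line,
                                          samples$treatment),
                                    paste(sens$cell_line, sens$treatment))]
    sensKey[is.na(sensKey)] <- FALSE
    applied <- eff[0, ]
    if (nrow(eff)) {
        for (k in seq_len(nrow(eff))) {
            hit <- samples$cell_line == eff$cell_line[k] &
                samples$treatment == eff$treatment[k] &
                samples$timepoint_min == eff$timepoint_min[k] & sensKey
            if (any(hit)) {
                values[eff$antigen_class[k], hit] <-
                    values[eff$antigen_class[k], hit] + eff$effect[k]
                applied <- rbind(applied, eff[k, ])
            }
        }
    }

    withSeed(seed, {
        if (cfg$replicateSd > 0)
            values <- values + matrix(rnorm(length(values), 0,
                                            cfg$replicateSd),
                                      nrow = nrow(values))
        loading <- if (cfg$loadingSd > 0)
            rnorm(nrow(samples), 0, cfg$loadingSd) else rep(0, nrow(samples))
    })

    cd <- S4Vectors::DataFrame(samples, loading = loading,
                               row.names = samples$sample_id)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2abundance = values), colData = cd,
        metadata = list(effects = applied, seed = seed,
                        replicateSd = cfg$replicateSd,
                        loadingSd = cfg$loadingSd))
}

# Panel construction helper: one row per antibody.
panelRow <- function(antibody_id, antigen_class, supplier_ref,
                     gain = 1, offset = 0, noise_sd = 0.15) {
    phospho <- if (grepl("_p[STY]", antigen_class) ||
                   grepl("_pT|_pY|_pS", antigen_class))
        sub("^[^_]*_", "", antigen_class) else NA_character_
    data.frame(antibody_id = antibody_id, antigen_class = antigen_class,
               phospho_site = phospho, supplier_ref = supplier_ref,
               gain = gain, offset = offset, noise_sd = noise_sd,
               stringsAsFactors = FALSE)
}

#' Default three-platform configurations
#'
#' Three synthetic RPPA platforms ("platformA", "platformB", "platformC")
#' with partially overlapping panels of 29, 31 and 27 antibodies covering
#' the same 25 antigen classes (so 18 control samples yield 522, 558 and
#' 486 readings). Most classes are probed by one catalogue antibody shared
#' across all platforms; a subset (e.g. Her2, phospho-Erk1/2) carries
#' additional platform-specific antibodies so that cross-antibody
#' concordance is assessable. Gains, offsets, dilution depth, technical
#' replication and default normalisation strategy differ by platform,
#' emulating distinct in-house workflows.
#'
#' @param noiseSd spot-level noise sd (log2 units) applied to every
#'   antibody on every platform; 0 gives noise-free rendering.
#'
#' @return Named list of three [PlatformConfig-class] objects.
#' @export
defaultPlatformConfigs <- function(noiseSd = 0.15) {
    classes <- defaultAntigenClasses()
    # catalogue references shared by all three platforms (same physical
    # antibody, hence the same uid after integration)
    base_ref <- setNames(sprintf("AB-%03d", seq_along(classes)), classes)

    basePanel <- function(pid, gain0, offset0) {
        n <- length(classes)
        gains <- gain0 + rep(c(-0.03, 0, 0.03), length.out = n)
        offs <- offset0 + rep(c(-0.2, 0, 0.2), length.out = n)
        do.call(rbind, lapply(seq_len(n), function(i)
            panelRow(paste0(pid, ".", gsub("[^A-Za-z0-9]", "", classes[i])),
                     classes[i], base_ref[classes[i]],
                     gain = gains[i], offset = offs[i], noise_sd = noiseSd)))
    }
    extra <- function(pid, class, ref, gain, offset)
        panelRow(paste0(pid, ".", gsub("[^A-Za-z0-9]", "", class), ".x",
                        substr(ref, 4, 6)),
                 class, ref, gain = gain, offset = offset,
                 noise_sd = noiseSd)

    # Platform A: 25 base + 4 extra = 29 antibodies
    pa <- rbind(basePanel("A", 1.00, 0),
                extra("A", "Erk1/2_pT202/Y204", "AB-101", 1.02, 0.1),
                extra("A", "Her2", "AB-111", 0.98, -0.1),
                extra("A", "Akt_pS473", "AB-121", 1.04, 0.2),
                extra("A", "S6_pS235/236", "AB-131", 0.97, 0))
    # Platform B: 25 base + 6 extra = 31 antibodies
    pb <- rbind(basePanel("B", 1.06, 0.8),
                extra("B", "Erk1/2_pT202/Y204", "AB-101", 1.05, 0.6),
                extra("B", "Her2", "AB-112", 1.08, 0.9),
                extra("B", "EGFR", "AB-141", 1.03, 0.7),
                extra("B", "MEK1/2_pS217/221", "AB-151", 1.07, 0.8),
                extra("B", "STAT3_pY705", "AB-161", 1.04, 1.0),
                extra("B", "mTOR", "AB-171", 1.06, 0.8))
    # Platform C: 25 base + 2 extra = 27 antibodies
    pc <- rbind(basePanel("C", 0.94, -0.5),
                extra("C", "Erk1/2_pT202/Y204", "AB-102", 0.95, -0.4),
                extra("C", "Her2", "AB-113", 0.93, -0.6))

    list(
        platformA = PlatformConfig("platformA", pa, nDilutionSteps = 4L,
                                   nTechnicalReplicates = 3L,
                                   detectionFloor = 0.25,
                                   normalisation = "total_protein"),
        platformB = PlatformConfig("platformB", pb, nDilutionSteps = 6L,
                                   nTechnicalReplicates = 2L,
                                   detectionFloor = 0.25,
                                   normalisation = "dilution_intercept"),
        platformC = PlatformConfig("platformC", pc, nDilutionSteps = 4L,
                                   nTechnicalReplicates = 2L,
                                   detectionFloor = 0.25,
                                   normalisation = "total_protein"))
}

# log2 level of the total-protein stain before loading effects
.TOTAL_PROTEIN_LEVEL <- 12
.TOTAL_PROTEIN_ID <- "TOTAL_PROTEIN"

#' Render a platform's raw spot table from latent abundances
#'
#' Applies the platform measurement model to the latent ground truth. The
#' undiluted log2 spot signal for antibody a on sample s is
#' `gain_a * latent[class(a), s] + offset_a + loading_s + e`, with spot
#' noise `e ~ Normal(0, noise_sd_a)`; each serial two-fold dilution step
#' subtracts exactly 1.0 log2 unit; linear intensities are censored at the
#' platform detection floor. A total-protein stain spot series (antibody id
#' `"TOTAL_PROTEIN"`) tracking the loading factor is emitted alongside the
#' panel, supporting total-protein normalisation downstream.
#'
#' @param latent latent antigen [SummarizedExperiment-class] from
#'   [simulateLatentAntigens()].
#' @param pconfig a [PlatformConfig-class].
#' @param seed integer seed for spot noise.
#'
#' @return A data.frame (raw spot table) with columns `sample_id`,
#'   `antibody_id`, `dilution_step` (0-based), `technical_replicate`,
#'   `intensity` (linear units), and attributes `platform_id` and
#'   `n_floored` (count of censored spots).
#' @export
renderPlatform <- function(latent, pconfig, seed) {
    stopifnot(is(pconfig, "PlatformConfig"))
    validObject(pconfig)
    panel <- pconfig@panel
    lv <- SummarizedExperiment::assay(latent, "log2abundance")
    missing <- setdiff(panel$antigen_class, rownames(lv))
    if (length(missing))
        stop("panel references antigen class(es) absent from the latent ",
             "matrix: ", paste(missing, collapse = ", "))
    loading <- SummarizedExperiment::colData(latent)$loading
    samples <- colnames(lv)
    nS <- length(samples); nD <- pconfig@nDilutionSteps
    nT <- pconfig@nTechnicalReplicates

    grid <- expand.grid(technical_replicate = seq_len(nT),
                        dilution_step = seq_len(nD) - 1L,
                        sample_id = samples,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sIdx <- match(grid$sample_id, samples)

    oneAntibody <- function(aid, class, gain, offset, nsd) {
        log2sig <- gain * lv[class, sIdx] + offset + loading[sIdx] -
            grid$dilution_step
        if (nsd > 0) log2sig <- log2sig + rnorm(length(log2sig), 0, nsd)
        data.frame(sample_id = grid$sample_id, antibody_id = aid,
                   dilution_step = grid$dilution_step,
                   technical_replicate = grid$technical_replicate,
                   intensity = 2^log2sig, stringsAsFactors = FALSE)
    }

    spots <- withSeed(seed, {
        tabs <- lapply(seq_len(nrow(panel)), function(i)
            oneAntibody(panel$antibody_id[i], panel$antigen_class[i],
                        panel$gain[i], panel$offset[i], panel$noise_sd[i]))
        # total-protein stain: level + loading + small stain noise
        tpLog2 <- .TOTAL_PROTEIN_LEVEL + loading[sIdx] - grid$dilution_step
        tpNsd <- min(c(panel$noise_sd, 0.05))
        if (tpNsd > 0) tpLog2 <- tpLog2 + rnorm(length(tpLog2), 0, tpNsd)
        tabs$tp <- data.frame(sample_id = grid$sample_id,
                              antibody_id = .TOTAL_PROTEIN_ID,
                              dilution_step = grid$dilution_step,
                              technical_replicate = grid$technical_replicate,
                              intensity = 2^tpLog2,
                              stringsAsFactors = FALSE)
        do.call(rbind, tabs)
    })
    rownames(spots) <- NULL
    floored <- spots$intensity < pconfig@detectionFloor
    spots$intensity[floored] <- pconfig@detectionFloor
    attr(spots, "platform_id") <- pconfig@platformId
    attr(spots, "n_floored") <- sum(floored)
    spots
}

#' Simulate a complete multi-platform RPPA study
#'
#' Convenience wrapper chaining [generateDesign()],
#' [simulateLatentAntigens()] and [renderPlatform()] for every platform,
#' deriving one deterministic sub-seed per stage from a single top-level
#' seed.
#'
#' @param design a [StudyDesign-class].
#' @param antigenConfig latent configuration (see [defaultAntigenConfig()]).
#' @param platforms named list of [PlatformConfig-class] objects.
#' @param seed single top-level integer seed.
#'
#' @return List with `samples` (design table), `latent` (ground-truth
#'   SummarizedExperiment), and `spots` (named list of raw spot tables,
#'   one per platform).
#' @examples
#' sim <- simulateRppaStudy(seed = 7)
#' names(sim$spots)
#' @export
simulateRppaStudy <- function(design = defaultStudyDesign(),
                              antigenConfig = defaultAntigenConfig(),
                              platforms = defaultPlatformConfigs(),
                              seed = 1L) {
    samples <- generateDesign(design)
    latent <- simulateLatentAntigens(samples, antigenConfig,
                                     seed = deriveSeed(seed, "latent"))
    spots <- lapply(platforms, function(p)
        renderPlatform(latent, p,
                       seed = deriveSeed(seed, paste0("render.",
                                                      platformId(p)))))
    names(spots) <- vapply(platforms, platformId, "")
    list(samples = samples, latent = latent, spots = spots)
}
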