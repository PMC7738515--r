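# Synthetic multi-platform study generator: design expansion, latent
# ground truth, platform rendering.

test_that("factorial design expansion matches the product of factors", {
    des <- generateDesign(defaultStudyDesign())
    expect_equal(nrow(des), 108L)
    expect_equal(anyDuplicated(des$sample_id), 0L)
    # control subset forced by the design: 6 cell lines x 3 replicates
    expect_equal(sum(des$treatment == "DMSO" & des$timepoint_min == 20),
                 18L)
    # degenerate one-of-each design
    one <- StudyDesign("A", treatments = "x", timepointsMin = 1,
                       nReplicates = 1L)
    expect_equal(nrow(generateDesign(one)), 1L)
    # random designs: count identity
    set.seed(42)
    for (i in 1:5) {
        k <- sample(1:4, 4, replace = TRUE)
        d <- StudyDesign(paste0("c", seq_len(k[1])),
                         treatments = paste0("t", seq_len(k[2])),
                         timepointsMin = seq_len(k[3]),
                         nReplicates = k[4])
        expect_equal(nrow(generateDesign(d)), prod(k))
    }
    # deterministic order: cell line slowest, replicate fastest
    expect_equal(des$cell_line[1:6], rep("MCF7", 6))
    expect_equal(des$replicate[1:3], 1:3)
})

test_that("invalid designs are rejected", {
    expect_error(StudyDesign(character(), treatments = "t",
                             timepointsMin = 1), "cell lines")
    expect_error(StudyDesign("a", treatments = character(),
                             timepointsMin = 1), "treatments")
    expect_error(StudyDesign("a", treatments = "t", timepointsMin = 1,
                             nReplicates = 0L), "nReplicates")
})

test_that("latent abundances are baseline + gated effect + seeded noise", {
    des <- generateDesign(StudyDesign(
        c("MDA-MB-231", "MCF7"), c("TNBC", "ER+"),
        treatments = c("DMSO", "selumetinib"), timepointsMin = 20,
        nReplicates = 3L))
    cfg <- defaultAntigenConfig(replicateSd = 0, loadingSd = 0)
    lat <- simulateLatentAntigens(des, cfg, seed = 1)
    v <- SummarizedExperiment::assay(lat)

    # zero noise, no effect: replicate columns equal the cell-line baseline
    ctrl <- des$sample_id[des$treatment == "DMSO" &
                          des$cell_line == "MCF7"]
    for (s in ctrl)
        expect_equal(v[, s], cfg$baselines[, "MCF7"])

    # the configured effect is injected verbatim in the sensitive line
    dms <- des$sample_id[des$cell_line == "MDA-MB-231" &
                         des$treatment == "DMSO"][1]
    sel <- des$sample_id[des$cell_line == "MDA-MB-231" &
                         des$treatment == "selumetinib"][1]
    expect_equal(v["Erk1/2_pT202/Y204", sel] -
                 v["Erk1/2_pT202/Y204", dms], -2.0)
    # insensitive line: no effect even though the drug was applied
    mcf_sel <- des$sample_id[des$cell_line == "MCF7" &
                             des$treatment == "selumetinib"][1]
    mcf_dms <- des$sample_id[des$cell_line == "MCF7" &
                             des$treatment == "DMSO"][1]
    expect_equal(v["Erk1/2_pT202/Y204", mcf_sel],
                 v["Erk1/2_pT202/Y204", mcf_dms])

    # seeding contract
    cfgN <- defaultAntigenConfig(replicateSd = 0.5)
    a <- SummarizedExperiment::assay(simulateLatentAntigens(des, cfgN, 9))
    b <- SummarizedExperiment::assay(simulateLatentAntigens(des, cfgN, 9))
    c <- SummarizedExperiment::assay(simulateLatentAntigens(des, cfgN, 10))
    expect_identical(a, b)
    expect_false(identical(a, c))
})

test_that("latent config guards reject bad input", {
    des <- generateDesign(defaultStudyDesign())
    expect_error(defaultAntigenConfig(replicateSd = -1), ">= 0")
    cfg <- defaultAntigenConfig()
    cfg$effects <- data.frame(antigen_class = "NotAClass",
                              cell_line = "SKBR3",
                              treatment = "lapatinib",
                              timepoint_min = 20, effect = 1)
    expect_error(simulateLatentAntigens(des, cfg, 1), "NotAClass")
})

test_that("platform rendering follows the measurement model", {
    lat <- tinyLatent(c(s1 = 3, s2 = 5))
    # identity rendering: gain 1, offset 0, no noise, step 0
    sp <- renderPlatform(lat, tinyPlatform(), seed = 1)
    ab <- sp[sp$antibody_id == "ab1", ]
    expect_equal(ab$intensity[ab$sample_id == "s1"], 2^3)
    expect_equal(ab$intensity[ab$sample_id == "s2"], 2^5)

    # consecutive dilution steps halve the linear intensity
    sp4 <- renderPlatform(lat, tinyPlatform(nSteps = 4L), seed = 1)
    s1 <- sp4[sp4$antibody_id == "ab1" & sp4$sample_id == "s1", ]
    s1 <- s1[order(s1$dilution_step), ]
    expect_equal(s1$intensity, 2^3 / 2^(0:3))

    # gain and offset act on the log2 scale
    spg <- renderPlatform(lat, tinyPlatform(gain = 2, offset = 1),
                          seed = 1)
    expect_equal(spg$intensity[spg$antibody_id == "ab1" &
                               spg$sample_id == "s1"], 2^(2 * 3 + 1))

    # detection floor censors the panel spots (latent far below the
    # floor) and counts them; the bright total-protein stain is untouched
    spf <- renderPlatform(lat, tinyPlatform(floor = 1000), seed = 1)
    panelRows <- spf$antibody_id == "ab1"
    expect_true(all(spf$intensity[panelRows] == 1000))
    expect_equal(attr(spf, "n_floored"), sum(panelRows))

    # schema guard: panel class absent from latent matrix
    expect_error(renderPlatform(lat, tinyPlatform(class = "Missing"),
                                seed = 1), "Missing")
})

test_that("rendering is seed-deterministic and monotone in the latent value", {
    lat <- tinyLatent(c(s1 = 3, s2 = 5))
    p <- tinyPlatform(noiseSd = 0.3, nSteps = 3L, nTech = 2L)
    a <- renderPlatform(lat, p, seed = 4)
    b <- renderPlatform(lat, p, seed = 4)
    expect_identical(a, b)
    expect_false(identical(a, renderPlatform(lat, p, seed = 5)))

    # monotonicity under a fixed noise draw (zero noise here)
    lo <- renderPlatform(tinyLatent(c(s1 = 3, s2 = 5)),
                         tinyPlatform(nSteps = 3L), seed = 1)
    hi <- renderPlatform(tinyLatent(c(s1 = 4, s2 = 5)),
                         tinyPlatform(nSteps = 3L), seed = 1)
    expect_true(all(hi$intensity >= lo$intensity))
})

test_that("whole-study simulation is deterministic given one seed", {
    a <- simulateRppaStudy(seed = 3)
    b <- simulateRppaStudy(seed = 3)
    expect_identical(SummarizedExperiment::assay(a$latent),
                     SummarizedExperiment::assay(b$latent))
    expect_identical(a$spots, b$spots)
    # default panels: 29/31/27 antibodies (+ total protein series)
    sizes <- vapply(defaultPlatformConfigs(),
                    function(p) nrow(panelInfo(p)), 0L)
    expect_equal(unname(sizes), c(29L, 31L, 27L))
})
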