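# Clustered antibody antigen map and concordance scoring.

test_that("antigen map construction follows the indexing contract", {
    ann <- data.frame(antibody_uid = c("Akt_a", "Her2_a", "Her2_b"),
                      antigen_class = c("Akt", "Her2", "Her2"))
    map <- buildAntigenMap(c("Her2_b", "Akt_a", "Her2_a"), ann)
    expect_equal(dim(map), c(2L, 3L))
    expect_equal(rownames(map), c("Akt", "Her2"))  # alphabetical
    # one filled cell per column
    expect_equal(unname(colSums(!is.na(map))), rep(1, 3))
    # indices fixed by sorted uid, from 1: Her2_a -> 1, Her2_b -> 2
    expect_equal(unname(map["Her2", "Her2_b"]), 2L)
    expect_equal(unname(map["Her2", "Her2_a"]), 1L)
    expect_equal(unname(map["Akt", "Akt_a"]), 1L)

    # permuting the leaf order permutes columns, not cell values
    map2 <- buildAntigenMap(c("Akt_a", "Her2_a", "Her2_b"), ann)
    expect_equal(map2[, colnames(map)], map)

    expect_error(buildAntigenMap(c("Akt_a", "Unknown_x"), ann),
                 "Unknown_x")
})

test_that("sibling-rule concordance matches manual enumeration", {
    # hand-built 6-leaf tree: class X adjacent pair, class Y split apart
    dnd <- new("RppaDendrogram",
               merges = rbind(c(-1L, -2L), c(-3L, -5L), c(-4L, -6L),
                              c(2L, 3L), c(1L, 4L)),
               height = c(0.1, 0.2, 0.3, 0.5, 0.8),
               labels = paste0("l", 1:6),
               leafOrder = c(1L, 2L, 3L, 5L, 4L, 6L),
               metric = "spearman", inversions = 0L)
    ann <- data.frame(
        antibody_uid = c("X_a", "X_b", "Y_a", "Y_b", "Z1_a", "Z2_a"),
        platform_id = c("P1", "P2", "P1", "P2", "P1", "P2"),
        antigen_class = c("X", "X", "Y", "Y", "Z1", "Z2"))
    rep <- scoreConcordance(dnd, ann, rule = "sibling")
    # eligibility: X and Y only (Z1, Z2 are single-antibody, one platform)
    expect_equal(rep$summary$n_eligible, c(2L, 2L))
    # X concordant (siblings are cross-platform, cross-antibody); Y not
    pc <- rep$per_class
    expect_true(pc$clusters_cross_platform[pc$antigen_class == "X"])
    expect_true(pc$clusters_cross_antibody[pc$antigen_class == "X"])
    expect_false(pc$clusters_cross_platform[pc$antigen_class == "Y"])
    expect_false(pc$clusters_cross_antibody[pc$antigen_class == "Y"])
    expect_equal(rep$summary$fraction, c(0.5, 0.5))
    expect_error(scoreConcordance(dnd, ann, rule = "nope"))
})

test_that("cophenetic-neighbour rule finds split classes the sibling rule misses", {
    dnd <- new("RppaDendrogram",
               merges = rbind(c(-1L, -2L), c(-3L, -5L), c(-4L, -6L),
                              c(2L, 3L), c(1L, 4L)),
               height = c(0.1, 0.2, 0.3, 0.5, 0.8),
               labels = paste0("l", 1:6),
               leafOrder = c(1L, 2L, 3L, 5L, 4L, 6L),
               metric = "spearman", inversions = 0L)
    ann <- data.frame(
        antibody_uid = c("X_a", "X_b", "Y_a", "Y_b", "Z1_a", "Z2_a"),
        platform_id = c("P1", "P2", "P1", "P2", "P1", "P2"),
        antigen_class = c("X", "X", "Y", "Y", "Z1", "Z2"))
    # leaves 3 and 4 are cophenetically at 0.5; with k = 3 they see
    # each other (neighbours of 3 at heights 0.2, 0.5, 0.5)
    repK <- scoreConcordance(dnd, ann, rule = "k_cophenetic_neighbours",
                             k = 3)
    pc <- repK$per_class
    expect_true(pc$clusters_cross_platform[pc$antigen_class == "Y"])
    expect_equal(repK$summary$fraction, c(1, 1))
})

test_that("map and concordance report are mutually consistent", {
    nf <- noiseFreeProcessed()
    ia <- nf$integrated
    cl <- twoWayCluster(ia, metric = "spearman")
    rd <- as.data.frame(SummarizedExperiment::rowData(ia))
    conc <- scoreConcordance(cl$featureDendrogram, rd)
    map <- buildAntigenMap(rd$antibody_uid[leafOrder(cl$featureDendrogram)],
                           rd)
    filled <- rowSums(!is.na(map))
    for (i in seq_len(nrow(conc$per_class))) {
        cls <- conc$per_class$antigen_class[i]
        if (conc$per_class$clusters_cross_antibody[i] ||
            conc$per_class$clusters_cross_platform[i])
            expect_gte(filled[cls], 2)
    }
})

test_that("concordance does not improve with more antibody noise", {
    design <- StudyDesign(c("L1", "L2", "L3"), treatments = "DMSO",
                          timepointsMin = 20, nReplicates = 3L)
    classes <- paste0("Ag", 1:5)
    mkPlat <- function(pid, refs, noise)
        PlatformConfig(pid, do.call(rbind, lapply(seq_along(classes),
            function(i) data.frame(
                antibody_id = paste0(pid, ".", classes[i]),
                antigen_class = classes[i], phospho_site = NA_character_,
                supplier_ref = refs[i], gain = 1, offset = 0,
                noise_sd = noise))),
            nDilutionSteps = 2L, nTechnicalReplicates = 1L,
            detectionFloor = 0, normalisation = "dilution_intercept")
    fractions <- function(noise, seed) {
        plats <- list(mkPlat("p1", sprintf("R%d", 1:5), noise),
                      mkPlat("p2", sprintf("R%d", c(1, 2, 13, 14, 15)),
                             noise),
                      mkPlat("p3", sprintf("R%d", c(21, 2, 23, 14, 25)),
                             noise))
        cfg <- defaultAntigenConfig(antigenClasses = classes,
                                    cellLineNames = cellLines(design),
                                    effects = defaultEffects()[0, ],
                                    replicateSd = 0.2, loadingSd = 0)
        sim <- simulateRppaStudy(design, cfg, plats, seed = seed)
        pes <- lapply(plats, function(p)
            processPlatform(sim$spots[[platformId(p)]], p))
        ia <- integratePlatforms(pes, sampleData = sim$samples)
        dnd <- hierarchicalCluster(distanceMatrix(ia, metric = "spearman"))
        rd <- as.data.frame(SummarizedExperiment::rowData(ia))
        scoreConcordance(dnd, rd)$summary$fraction
    }
    seeds <- 1:20
    lowNoise <- rowMeans(vapply(seeds, function(s) fractions(0.1, s),
                                numeric(2)))
    highNoise <- rowMeans(vapply(seeds, function(s) fractions(3, s),
                                 numeric(2)))
    expect_gte(lowNoise[1], highNoise[1])
    expect_gte(lowNoise[2], highNoise[2])
})
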