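# Platform processing: replicate aggregation, dilution fits, total-protein
# normalisation, log2 transform, QC.

test_that("technical replicates aggregate by the median", {
    mk <- function(int, step = 0L)
        data.frame(sample_id = "s", antibody_id = "a",
                   dilution_step = step,
                   technical_replicate = seq_along(int), intensity = int)
    expect_equal(aggregateReplicates(mk(c(100, 110, 90)))$intensity, 100)
    expect_equal(aggregateReplicates(mk(42))$intensity, 42)
    expect_equal(aggregateReplicates(mk(c(100, 200)))$intensity, 150)
    expect_error(aggregateReplicates(data.frame(sample_id = "s")),
                 "lacks column")
})

test_that("dilution fits equal the independent least-squares oracle", {
    # exact two-fold series
    f <- fitDilutionSeries(0:3, c(800, 400, 200, 100))
    expect_equal(f$estimate, log2(800))
    expect_equal(f$slope, -1)
    expect_equal(f$r2, 1)
    expect_identical(f$flag, "ok")

    # saturated flat series
    expect_equal(fitDilutionSeries(0:3, rep(500, 4))$slope, 0)

    # the printed 4-point example against the closed-form solution
    y <- c(1000, 480, 260, 130)
    f2 <- fitDilutionSeries(0:3, y)
    o <- oracleOls(0:3, log2(y))
    expect_equal(f2$estimate, unname(o["intercept"]), tolerance = 1e-12)
    expect_equal(f2$slope, unname(o["slope"]), tolerance = 1e-12)

    # random series, 1e-9 agreement
    set.seed(11)
    for (i in 1:25) {
        n <- sample(3:8, 1)
        x <- 0:(n - 1)
        yy <- 2^(rnorm(1, 10, 2) - x + rnorm(n, 0, 0.3))
        f3 <- fitDilutionSeries(x, yy)
        o3 <- oracleOls(x, log2(yy))
        expect_equal(f3$estimate, unname(o3["intercept"]),
                     tolerance = 1e-9)
        expect_equal(f3$slope, unname(o3["slope"]), tolerance = 1e-9)
    }

    # all at the detection floor: unquantifiable, not an error
    expect_identical(fitDilutionSeries(0:3, rep(2, 4),
                                       detectionFloor = 2)$flag,
                     "unquantifiable")
    # single usable point: degenerate
    expect_identical(fitDilutionSeries(c(0, 1), c(100, 0))$flag,
                     "degenerate")
})

test_that("total-protein normalisation divides per sample and guards zeros", {
    m <- matrix(c(2, 4, 8, 16), nrow = 2,
                dimnames = list(c("s1", "s2"), c("a", "b")))
    expect_equal(normaliseTotalProtein(m, c(s1 = 1, s2 = 1)), m)
    half <- normaliseTotalProtein(m, c(s1 = 2, s2 = 1))
    expect_equal(half["s1", ], m["s1", ] / 2)
    expect_equal(half["s2", ], m["s2", ])
    # rank order within a sample is preserved
    set.seed(1)
    r <- matrix(rexp(40), nrow = 4,
                dimnames = list(paste0("s", 1:4), paste0("a", 1:10)))
    tp <- setNames(rexp(4) + 0.1, rownames(r))
    rn <- normaliseTotalProtein(r, tp)
    for (s in rownames(r))
        expect_equal(order(rn[s, ]), order(r[s, ]))
    expect_error(normaliseTotalProtein(m, c(s1 = 0, s2 = 1)), "s1")
})

test_that("log2 transform guards non-positive values", {
    expect_equal(log2Matrix(matrix(c(8, 1))), matrix(c(3, 0)))
    expect_warning(out <- log2Matrix(matrix(c(4, 0))), "non-positive")
    expect_true(is.na(out[2]))
    expect_true(is.na(log2Matrix(matrix(c(1, NA)))[2]))
})

test_that("dynamic-range QC summarises slopes and detection", {
    fits <- data.frame(antibody_id = rep(c("a", "b"), each = 3),
                       slope = c(-1, -1.1, -0.9, -1, 0.2, NA),
                       flag = c(rep("ok", 5), "unquantifiable"))
    qc <- qcDynamicRange(fits)
    expect_equal(qc$summary$frac_in_range, 4 / 6)
    expect_equal(qc$summary$frac_below_detection, 1 / 6)
    expect_equal(qc$per_antibody$frac_in_range,
                 c(1, 1 / 3))
    # all-ideal and all-floored corner cases
    expect_equal(qcDynamicRange(data.frame(
        antibody_id = "a", slope = rep(-1, 4),
        flag = "ok"))$summary$frac_in_range, 1)
    expect_equal(qcDynamicRange(data.frame(
        antibody_id = "a", slope = NA_real_,
        flag = "unquantifiable"))$summary$frac_below_detection, 1)
})

test_that("default synthetic study stays in the dynamic range", {
    for (pe in defaultProcessed()) {
        qc <- qcDynamicRange(S4Vectors::metadata(pe)$qc)
        expect_gt(qc$summary$frac_in_range, 0.99)
        expect_lt(qc$summary$frac_below_detection, 0.01)
    }
})

test_that("noise-free processing with unit gain recovers the latent truth", {
    lat <- tinyLatent(c(s1 = 3, s2 = 7.25, s3 = 5.5))
    p <- tinyPlatform(nSteps = 4L, nTech = 2L)
    pe <- processPlatform(renderPlatform(lat, p, seed = 1), p,
                          method = "dilution_intercept")
    expect_equal(SummarizedExperiment::assay(pe)["ab1", ],
                 SummarizedExperiment::assay(lat)["Akt", ],
                 tolerance = 1e-9)
})

test_that("total-protein processing removes the loading confounder", {
    # same latent signal, loading differs by sample
    samples <- data.frame(sample_id = c("s1", "s2"), cell_line = "L1",
                          receptor_status = "u", treatment = "DMSO",
                          timepoint_min = 20, replicate = 1:2)
    m <- matrix(c(5, 5), nrow = 1, dimnames = list("Akt", c("s1", "s2")))
    lat <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2abundance = m),
        colData = S4Vectors::DataFrame(samples, loading = c(0, 2),
                                       row.names = samples$sample_id))
    p <- PlatformConfig("tp", tinyPlatform()@panel, nDilutionSteps = 3L,
                        nTechnicalReplicates = 1L, detectionFloor = 0,
                        normalisation = "total_protein")
    raw <- processPlatform(renderPlatform(lat, p, seed = 1), p,
                           method = "dilution_intercept")
    nrm <- processPlatform(renderPlatform(lat, p, seed = 1), p,
                           method = "total_protein")
    araw <- SummarizedExperiment::assay(raw)
    anrm <- SummarizedExperiment::assay(nrm)
    # raw intercepts differ by the loading; normalised ones agree
    expect_equal(unname(araw["ab1", "s2"] - araw["ab1", "s1"]), 2,
                 tolerance = 1e-6)
    expect_equal(unname(anrm["ab1", "s2"] - anrm["ab1", "s1"]), 0,
                 tolerance = 1e-6)
})
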