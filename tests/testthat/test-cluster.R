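# Distances, average-linkage clustering, two-way clustering, PCA.

test_that("distance metrics satisfy their defining identities", {
    m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
               c = c(5, 4, 3, 2, 1))
    for (metric in c("spearman", "euclidean", "kendall")) {
        d <- distanceMatrix(m, metric = metric)
        expect_equal(unname(d["a", "b"]), 0)
        expect_equal(unname(diag(d)), rep(0, 3))
        expect_equal(d, t(d))
    }
    # exactly reversed ranks: rank-correlation distance 2
    expect_equal(unname(distanceMatrix(m, metric = "spearman")["a", "c"]),
                 2)
    expect_equal(unname(distanceMatrix(m, metric = "kendall")["a", "c"]),
                 2)
})

test_that("distances match first-principles oracles to 1e-9", {
    set.seed(7)
    for (i in 1:10) {
        m <- matrix(sample(1:4, 30, replace = TRUE) + rnorm(30, 0, 0.01),
                    nrow = 5, dimnames = list(NULL, paste0("c", 1:6)))
        if (i %% 2 == 0) m[sample(30, 3)] <- m[sample(30, 3)]  # ties
        for (metric in c("spearman", "euclidean", "kendall")) {
            d <- distanceMatrix(m, metric = metric)
            o <- oracleDistance(m, metric)
            expect_equal(unclass(d)[seq_along(o)], as.vector(o),
                         tolerance = 1e-9)
        }
    }
})

test_that("rank metrics use pairwise-complete observations", {
    m <- cbind(a = c(1, 2, 3, 4, NA, 6), b = c(2, 4, 6, 8, 10, NA))
    d <- distanceMatrix(m, metric = "spearman")
    # complete cases are rows 1-4, perfectly monotone
    expect_equal(unname(d["a", "b"]), 0)
    # fewer than 3 complete pairs: missing distance, clustering refuses
    m2 <- cbind(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2),
                c = c(1, 2, 3, 4))
    d2 <- distanceMatrix(m2, metric = "spearman")
    expect_true(is.na(d2["a", "b"]))
    expect_error(hierarchicalCluster(d2), "missing")
})

test_that("spearman distance is invariant under monotone transforms", {
    set.seed(8)
    m <- matrix(rnorm(40), nrow = 8, dimnames = list(NULL, paste0("c", 1:5)))
    d0 <- distanceMatrix(m, metric = "spearman")
    m2 <- m
    m2[, 2] <- exp(m2[, 2])        # strictly increasing transform
    m2[, 4] <- m2[, 4]^3
    expect_equal(distanceMatrix(m2, metric = "spearman"), d0,
                 tolerance = 1e-12)
})

test_that("average-linkage clustering reproduces the brute-force oracle", {
    set.seed(9)
    for (i in 1:20) {
        n <- sample(3:7, 1)
        m <- matrix(rnorm(n * 6), nrow = 6,
                    dimnames = list(NULL, paste0("it", seq_len(n))))
        metric <- sample(c("spearman", "euclidean", "kendall"), 1)
        d <- distanceMatrix(m, metric = metric)
        dnd <- hierarchicalCluster(d)
        o <- oracleAverageLinkage(unclass(d)[seq_len(n), seq_len(n)])
        expect_equal(unname(merges(dnd)), unname(o$merges))
        expect_equal(mergeHeights(dnd), o$heights, tolerance = 1e-9)
        expect_equal(leafOrder(dnd), as.integer(o$leafOrder))
    }
})

test_that("merge heights agree with hclust average linkage", {
    set.seed(10)
    for (i in 1:10) {
        n <- sample(4:12, 1)
        m <- matrix(rnorm(n * 7), nrow = 7,
                    dimnames = list(NULL, paste0("it", seq_len(n))))
        d <- distanceMatrix(m, metric = "euclidean")
        dnd <- hierarchicalCluster(d)
        hc <- hclust(as.dist(d), method = "average")
        expect_equal(sort(mergeHeights(dnd)), sort(hc$height),
                     tolerance = 1e-9)
    }
})

test_that("clustering degenerate cases behave", {
    # two identical items merge first at height zero
    m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4))
    dnd <- hierarchicalCluster(distanceMatrix(m, metric = "euclidean"))
    expect_equal(mergeHeights(dnd)[1], 0)
    expect_equal(sort(merges(dnd)[1, ]), c(-2L, -1L))
    # single leaf
    one <- matrix(1:3, ncol = 1, dimnames = list(NULL, "only"))
    d1 <- structure(matrix(0, 1, 1, dimnames = list("only", "only")),
                    metric = "euclidean")
    dnd1 <- hierarchicalCluster(d1)
    expect_equal(nLeaves(dnd1), 1L)
    expect_equal(nrow(merges(dnd1)), 0L)
    expect_equal(leafOrder(dnd1), 1L)
})

test_that("two-way clustering reorders rows and columns coherently", {
    set.seed(12)
    # block-diagonal two-group structure on both axes
    base <- rbind(matrix(rnorm(40, 10), 4), matrix(rnorm(40, -10), 4))
    m <- base + rnorm(80, 0, 0.1)
    rownames(m) <- paste0("r", 1:8); colnames(m) <- paste0("c", 1:10)
    cl <- twoWayCluster(m, metric = "euclidean")
    ro <- leafOrder(cl$featureDendrogram)
    grp <- (ro <= 4)
    expect_true(all(diff(which(grp)) == 1) || all(diff(which(!grp)) == 1))
    # conservation: reordered matrix is a permutation of the input
    expect_equal(sort(as.vector(cl$matrix)), sort(as.vector(m)))
    # transposition swaps the dendrograms
    clT <- twoWayCluster(t(m), metric = "euclidean")
    expect_equal(merges(clT$featureDendrogram),
                 merges(cl$sampleDendrogram))
    expect_equal(mergeHeights(clT$sampleDendrogram),
                 mergeHeights(cl$featureDendrogram))
})

test_that("pca is a centred svd with deterministic signs", {
    set.seed(13)
    # rank-1 matrix: first component carries all variance
    u <- rnorm(6); v <- rnorm(4)
    r1 <- outer(u, v)
    p1 <- suppressWarnings(rppaPca(r1, nComponents = 2))
    expect_equal(p1$varianceFraction[1], 1)

    m <- matrix(rnorm(24), nrow = 6)
    p <- rppaPca(m, nComponents = 4)
    # full reconstruction of the centred input
    centred <- sweep(m, 2, colMeans(m))
    expect_equal(p$scores %*% t(p$loadings), centred, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # eigen-oracle on the variance fractions
    ev <- oracleEigenvalues(m)
    expect_equal(p$varianceFraction, ev / sum(ev), tolerance = 1e-9)
    # scores are uncorrelated
    cc <- crossprod(p$scores) / (nrow(m) - 1)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
    # sign convention: max-|loading| entry positive
    for (j in seq_len(ncol(p$loadings)))
        expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
    # variance fractions are non-increasing and sum to <= 1
    expect_true(all(diff(p$varianceFraction) <= 1e-12))
    expect_lte(sum(p$varianceFraction), 1 + 1e-12)

    # missing values are median-imputed for the PCA only
    m2 <- m; m2[2, 3] <- NA
    p2 <- rppaPca(m2, nComponents = 2)
    expect_equal(p2$nImputed, 1L)
    # over-asking components truncates with a warning
    expect_warning(rppaPca(m, nComponents = 10), "reduced")
})
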