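# First-principles reference implementations used as independent oracles.
# They deliberately avoid the code paths (and, where possible, the base
# functions) used by the package implementation.

# average ranks from counting comparisons, no call to rank()
oracleRanks <- function(x) {
    vapply(seq_along(x), function(i)
        sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

# Pearson correlation from raw sum formulas
oraclePearson <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    num / den
}

oracleSpearman <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    oraclePearson(oracleRanks(x[ok]), oracleRanks(y[ok]))
}

# Kendall tau-b by explicit pair counting with tie corrections
oracleKendallTauB <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        dx <- x[j] - x[i]; dy <- y[j] - y[i]
        if (dx == 0 && dy == 0) next
        else if (dx == 0) tx <- tx + 1
        else if (dy == 0) ty <- ty + 1
        else if (sign(dx) == sign(dy)) conc <- conc + 1
        else disc <- disc + 1
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

oracleEuclidean <- function(x, y) sqrt(sum((x - y)^2))

oracleDistance <- function(m, metric) {
    p <- ncol(m)
    d <- matrix(0, p, p, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        d[i, j] <- switch(metric,
            spearman = 1 - oracleSpearman(m[, i], m[, j]),
            kendall = 1 - oracleKendallTauB(m[, i], m[, j]),
            euclidean = oracleEuclidean(m[, i], m[, j]))
    }
    d
}

# closed-form simple OLS: slope = Sxy/Sxx, intercept = ybar - slope*xbar
oracleOls <- function(x, y) {
    xb <- mean(x); yb <- mean(y)
    slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
    c(intercept = yb - slope * xb, slope = slope)
}

# textbook pooled-variance two-sample t
oraclePooledT <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Exhaustive average-linkage agglomeration: cluster distances recomputed
# each step as the direct mean of member pairwise distances from the
# original matrix (no Lance-Williams update). Same deterministic
# tie-break contract: lowest (left, right) creation-id pair; the
# earlier-created cluster is the left child.
oracleAverageLinkage <- function(dm) {
    n <- nrow(dm)
    members <- as.list(seq_len(n))        # by creation id
    alive <- seq_len(n)
    heights <- numeric(n - 1)
    mergePairs <- matrix(0L, n - 1, 2)    # creation ids merged
    for (step in seq_len(n - 1)) {
        best <- NULL; bestD <- Inf
        for (ii in seq_along(alive)) for (jj in seq_along(alive)) {
            if (ii >= jj) next
            a <- alive[ii]; b <- alive[jj]
            dAB <- mean(dm[members[[a]], members[[b]]])
            if (dAB < bestD ||
                (dAB == bestD && (a < best[1] ||
                                  (a == best[1] && b < best[2])))) {
                bestD <- dAB; best <- c(a, b)
            }
        }
        newId <- n + step
        members[[newId]] <- c(members[[best[1]]], members[[best[2]]])
        heights[step] <- bestD
        mergePairs[step, ] <- best
        alive <- c(setdiff(alive, best), newId)
    }
    # leaf order: recursive traversal, earlier-created (smaller id) left
    leaves <- function(id) {
        if (id <= n) return(id)
        step <- id - n
        c(leaves(mergePairs[step, 1]), leaves(mergePairs[step, 2]))
    }
    signed <- function(id) if (id <= n) -id else id - n
    merges <- cbind(vapply(mergePairs[, 1], signed, 0L),
                    vapply(mergePairs[, 2], signed, 0L))
    list(merges = merges, heights = heights, leafOrder = leaves(2L * n - 1L))
}

# covariance eigendecomposition oracle for PCA variance fractions
oracleEigenvalues <- function(m) {
    mc <- sweep(m, 2, colMeans(m))
    ev <- eigen(crossprod(mc) / (nrow(m) - 1), symmetric = TRUE)$values
    ev[ev < 0] <- 0
    sort(ev, decreasing = TRUE)
}
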