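# Moderated differential testing: SAM-style t-statistic with an
# artificial within-groups variance constant s0 in the denominator, and
# permutation-based FDR control over enumerated balanced label splits.

#' Moderated two-sample t-statistic
#'
#' `t_mod = (mean_a - mean_b) / (se_pooled + s0)`, where `se_pooled` is
#' the pooled-variance two-sample standard error and `s0` is a constant
#' ("artificial within-groups variance", default 1) that damps large
#' statistics arising from near-zero variance features. `s0 = 0`
#' recovers the classical pooled t-statistic.
#'
#' @param groupA,groupB numeric vectors (>= 2 non-missing values each).
#' @param s0 moderation constant, >= 0.
#'
#' @return The moderated statistic (`NA` with a flag attribute when a
#'   group has fewer than 2 values).
#' @examples
#' moderatedT(c(1, 2, 3), c(4, 5, 6), s0 = 0)  # classical pooled t
#' @export
moderatedT <- function(groupA, groupB, s0 = 1) {
    stopifnot(s0 >= 0)
    a <- groupA[!is.na(groupA)]; b <- groupB[!is.na(groupB)]
    if (length(a) < 2L || length(b) < 2L)
        return(structure(NA_real_, flag = "insufficient replicates"))
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2) * sqrt(1 / na + 1 / nb)
    (mean(a) - mean(b)) / (se + s0)
}

# vectorised column-wise moderated t for a samples x features matrix
.colModeratedT <- function(x, aIdx, bIdx, s0) {
    na <- length(aIdx); nb <- length(bIdx)
    xa <- x[aIdx, , drop = FALSE]; xb <- x[bIdx, , drop = FALSE]
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- (colSums(xa^2) - na * ma^2) / (na - 1)
    vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    sp2[sp2 < 0] <- 0  # numerical guard
    se <- sqrt(sp2) * sqrt(1 / na + 1 / nb)
    list(diff = ma - mb, t = (ma - mb) / (se + s0))
}

# all balanced reassignments of nA treated among n samples, excluding the
# observed assignment and (for equal group sizes) its mirror: those two
# reproduce every true effect exactly and would floor the estimated FDR
# of a real effect at 2/C(n, nA).
.balancedSplits <- function(n, aIdx, nPermutations, seed) {
    total <- choose(n, length(aIdx))
    all <- combn(n, length(aIdx))
    keep <- vapply(seq_len(ncol(all)), function(k) {
        s <- all[, k]
        !(setequal(s, aIdx) ||
          (length(aIdx) * 2L == n && setequal(s, setdiff(seq_len(n),
                                                         aIdx))))
    }, TRUE)
    all <- all[, keep, drop = FALSE]
    if (ncol(all) > nPermutations) {
        pick <- withSeed(seed, sample.int(ncol(all), nPermutations))
        all <- all[, pick, drop = FALSE]
    }
    if (ncol(all) < 2L)
        stop("fewer than 2 distinct balanced label splits; cannot ",
             "estimate a permutation FDR (total splits: ", total, ")")
    all
}

#' Permutation-FDR moderated differential test
#'
#' Tests every antibody column for a difference between two sample
#' groups using the moderated t-statistic, and controls the false
#' discovery rate by label permutation. All distinct balanced
#' reassignments of the group labels are enumerated (excluding the
#' observed assignment and its mirror, which reproduce true effects
#' verbatim); if more exist than `nPermutations`, a seeded random subset
#' is used. For a threshold c, `FDR(c)` is the mean permutation count of
#' `|t| >= c` divided by the observed count; the significant set is the
#' largest with `FDR <= fdrThreshold`, i.e. the smallest threshold
#' passing it.
#'
#' @param x samples x antibodies numeric matrix, or an
#'   [IntegratedRppa-class] (assay transposed internally).
#' @param groups factor/character of length `nrow(x)` with exactly two
#'   levels.
#' @param treated,control which level is the treated / control group;
#'   defaults to the second and first level. `mean_difference` is
#'   treated minus control.
#' @param s0 moderation constant (default 1).
#' @param nPermutations target permutation count (default 1000; capped
#'   at the number of distinct balanced splits, e.g. 18 informative
#'   splits for 3 vs 3).
#' @param fdrThreshold FDR level (default 0.05).
#' @param seed seed used only when splits must be subsampled.
#'
#' @return data.frame (one row per antibody): `antibody`,
#'   `mean_difference`, `t_mod`, `significant`; attributes
#'   `n_perm_used`, `cut` (selected |t| threshold, `Inf` when nothing is
#'   significant), `achieved_fdr`, `s0`, `fdr_threshold`, `perm_abs_t`
#'   (the permutation |t| matrix the FDR curve was estimated from).
#' @examples
#' x <- matrix(rnorm(60), nrow = 6,
#'             dimnames = list(NULL, paste0("ab", 1:10)))
#' x[4:6, 1] <- x[4:6, 1] + 10
#' g <- rep(c("ctrl", "drug"), each = 3)
#' res <- permutationFdr(x, g, treated = "drug", control = "ctrl")
#' @export
permutationFdr <- function(x, groups, treated = NULL, control = NULL,
                           s0 = 1, nPermutations = 1000L,
                           fdrThreshold = 0.05, seed = 1L) {
    if (is(x, "SummarizedExperiment"))
        x <- t(SummarizedExperiment::assay(x))
    x <- as.matrix(x)
    stopifnot(s0 >= 0, fdrThreshold > 0, fdrThreshold < 1,
              nPermutations >= 1L)
    groups <- as.character(groups)
    if (length(groups) != nrow(x))
        stop("need one group label per sample (row)")
    lev <- unique(groups)
    if (length(lev) != 2L) stop("exactly two groups required")
    if (is.null(control)) control <- lev[1]
    if (is.null(treated)) treated <- setdiff(lev, control)[1]
    stopifnot(treated %in% lev, control %in% lev, treated != control)
    aIdx <- which(groups == treated); bIdx <- which(groups == control)
    if (length(aIdx) < 2L || length(bIdx) < 2L)
        stop("each group needs at least 2 samples")
    if (anyNA(x))
        stop("missing values in the test matrix; complete data required")

    obs <- .colModeratedT(x, aIdx, bIdx, s0)
    n <- nrow(x)
    splits <- .balancedSplits(n, aIdx, nPermutations, seed)
    nPerm <- ncol(splits)
    permT <- matrix(0, nPerm, ncol(x))
    for (k in seq_len(nPerm)) {
        pa <- splits[, k]
        permT[k, ] <- .colModeratedT(x, pa, setdiff(seq_len(n), pa), s0)$t
    }

    absObs <- abs(obs$t)
    absPerm <- abs(permT)
    cuts <- sort(unique(absObs))
    fdrAt <- vapply(cuts, function(c)
        (sum(absPerm >= c) / nPerm) / sum(absObs >= c), 0)
    ok <- which(fdrAt <= fdrThreshold)
    if (length(ok)) {
        cut <- cuts[min(ok)]
        achieved <- fdrAt[min(ok)]
        significant <- absObs >= cut
    } else {
        cut <- Inf
        achieved <- NA_real_
        significant <- rep(FALSE, ncol(x))
    }

    res <- data.frame(
        antibody = colnames(x) %||% as.character(seq_len(ncol(x))),
        mean_difference = obs$diff, t_mod = obs$t,
        significant = significant, stringsAsFactors = FALSE)
    attr(res, "n_perm_used") <- nPerm
    attr(res, "cut") <- cut
    attr(res, "achieved_fdr") <- achieved
    attr(res, "s0") <- s0
    attr(res, "fdr_threshold") <- fdrThreshold
    attr(res, "treated") <- treated
    attr(res, "control") <- control
    attr(res, "perm_abs_t") <- absPerm
    res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Volcano-plot table of a differential result
#'
#' Orders a [permutationFdr()] result by decreasing `|t_mod|`, ready for
#' plotting mean difference against the statistic with the FDR boundary.
#'
#' @param result data.frame from [permutationFdr()].
#' @return data.frame with columns `antibody`, `mean_difference`,
#'   `abs_t_mod`, `significant`, sorted by `abs_t_mod` descending;
#'   FDR attributes carried over.
#' @export
volcanoTable <- function(result) {
    out <- data.frame(antibody = result$antibody,
                      mean_difference = result$mean_difference,
                      abs_t_mod = abs(result$t_mod),
                      significant = result$significant,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$abs_t_mod), ]
    rownames(out) <- NULL
    for (a in c("n_perm_used", "cut", "achieved_fdr", "s0",
                "fdr_threshold"))
        attr(out, a) <- attr(result, a)
    out
}

#' Run a drug-versus-vehicle contrast on an integrated matrix
#'
#' Convenience wrapper subsetting an [IntegratedRppa-class] to one cell
#' line and timepoint and testing drug against vehicle with
#' [permutationFdr()].
#'
#' @param integrated an [IntegratedRppa-class] whose `colData` carries
#'   `cell_line`, `treatment`, `timepoint_min`.
#' @param cellLine,drug,timepointMin contrast coordinates.
#' @param vehicle control treatment label (default `"DMSO"`).
#' @param ... passed to [permutationFdr()].
#'
#' @return See [permutationFdr()].
#' @export
runContrast <- function(integrated, cellLine, drug, timepointMin,
                        vehicle = "DMSO", ...) {
    cd <- SummarizedExperiment::colData(integrated)
    sel <- cd$cell_line == cellLine & cd$timepoint_min == timepointMin &
        cd$treatment %in% c(drug, vehicle)
    if (!any(sel)) stop("no samples match the contrast")
    sub <- integrated[, sel]
    permutationFdr(sub,
                   groups = SummarizedExperiment::colData(sub)$treatment,
                   treated = drug, control = vehicle, ...)
}
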