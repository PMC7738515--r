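# All-pairs antibody correlation statistics: Spearman coefficients for
# every pair of antibody-platform columns, category labels (like antigen,
# same antibody, same platform), kernel density estimates and Fisher
# z-tests comparing median correlations.

#' All-pairs Spearman correlations between antibody columns
#'
#' Computes the Spearman rank correlation over pairwise-complete samples
#' for every unordered pair of antibody-platform columns of an
#' integrated matrix, and labels each pair: `like_antigen` (same antigen
#' class), `same_antibody` (same antibody uid on different platforms)
#' and `same_platform`. Pairs with fewer than `minComplete` complete
#' observations are dropped, with the count recorded in an attribute.
#'
#' @param integrated an [IntegratedRppa-class].
#' @param minComplete minimum pairwise-complete sample count (default 3).
#'
#' @return data.frame of pairs (`uid_1`, `uid_2`, `platform_1`,
#'   `platform_2`, `r_s`, `n_complete`, `like_antigen`, `same_antibody`,
#'   `same_platform`), with attribute `n_dropped`.
#' @export
pairwiseCorrelations <- function(integrated, minComplete = 3L) {
    stopifnot(is(integrated, "IntegratedRppa"))
    a <- t(SummarizedExperiment::assay(integrated))  # samples x columns
    rd <- as.data.frame(SummarizedExperiment::rowData(integrated))
    m <- ncol(a)
    if (m < 2L) stop("need at least two antibody columns")
    r <- suppressWarnings(cor(a, method = "spearman",
                              use = "pairwise.complete.obs"))
    nC <- crossprod(!is.na(a))
    i <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    j <- unlist(lapply(seq_len(m - 1L), function(k) (k + 1L):m))
    pairs <- data.frame(
        uid_1 = rd$antibody_uid[i], uid_2 = rd$antibody_uid[j],
        platform_1 = rd$platform_id[i], platform_2 = rd$platform_id[j],
        r_s = r[cbind(i, j)], n_complete = nC[cbind(i, j)],
        like_antigen = rd$antigen_class[i] == rd$antigen_class[j],
        stringsAsFactors = FALSE)
    pairs$same_platform <- pairs$platform_1 == pairs$platform_2
    pairs$same_antibody <- pairs$uid_1 == pairs$uid_2 &
        !pairs$same_platform
    drop <- pairs$n_complete < minComplete | is.na(pairs$r_s)
    out <- pairs[!drop, ]
    rownames(out) <- NULL
    attr(out, "n_dropped") <- sum(drop)
    out
}

#' Split correlation pairs into comparison groups
#'
#' Groups the all-pairs correlation table the way the distribution
#' comparisons are made: like-antigen versus all pairs; within like
#' antigens, same versus different antibody; per platform-pair
#' distributions; or, for different antibodies recognising like
#' antigens, same- versus cross-platform.
#'
#' @param pairs pair table from [pairwiseCorrelations()].
#' @param grouping one of `"like_vs_all"`,
#'   `"same_vs_different_antibody"`, `"platform_pair"`,
#'   `"same_vs_cross_platform"`.
#' @param within for `"platform_pair"`: restrict to `"same_antibody"` or
#'   `"different_antibody"` like-antigen pairs (default
#'   `"same_antibody"`).
#'
#' @return List with `groups` (named list of `r_s` vectors; empty groups
#'   are empty vectors, not errors) and `medians` (named numeric).
#' @export
summariseCorrelations <- function(pairs,
                                  grouping = c("like_vs_all",
                                               "same_vs_different_antibody",
                                               "platform_pair",
                                               "same_vs_cross_platform"),
                                  within = c("same_antibody",
                                             "different_antibody")) {
    grouping <- match.arg(grouping)
    within <- match.arg(within)
    like <- pairs[pairs$like_antigen, , drop = FALSE]
    groups <- switch(grouping,
        like_vs_all = list(like_antigen = like$r_s, all_pairs = pairs$r_s),
        same_vs_different_antibody = list(
            same_antibody = like$r_s[like$same_antibody],
            different_antibody = like$r_s[!like$same_antibody]),
        platform_pair = {
            sel <- if (within == "same_antibody") like$same_antibody
                   else !like$same_antibody & !like$same_platform
            sub <- like[sel, , drop = FALSE]
            key <- paste(pmin(sub$platform_1, sub$platform_2),
                         pmax(sub$platform_1, sub$platform_2), sep = "|")
            split(sub$r_s, key)
        },
        same_vs_cross_platform = {
            sub <- like[!like$same_antibody, , drop = FALSE]
            list(same_platform = sub$r_s[sub$same_platform],
                 cross_platform = sub$r_s[!sub$same_platform])
        })
    medians <- vapply(groups, function(g)
        if (length(g)) median(g) else NA_real_, 0)
    list(groups = groups, medians = medians)
}

#' Gaussian kernel density estimate
#'
#' Density of a set of correlation coefficients (or any numeric values)
#' using a Gaussian kernel. The default bandwidth is Silverman's
#' rule-of-thumb; the density is evaluated on 512 grid points spanning
#' the data plus three bandwidths on either side. Zero-variance input
#' yields a degenerate spike representation with a warning.
#'
#' @param values numeric vector (length >= 2).
#' @param bandwidth `"silverman"` or a positive number.
#'
#' @return List with `x` (grid), `y` (density), `bandwidth`, and
#'   `degenerate` flag.
#' @export
correlationKde <- function(values, bandwidth = "silverman") {
    values <- values[is.finite(values)]
    if (length(values) < 2L) stop("need at least two values")
    if (var(values) == 0) {
        warning("zero-variance input: degenerate (spike) density")
        bw <- 1e-6
        d <- density(values, bw = bw, n = 512, cut = 3)
        return(list(x = d$x, y = d$y, bandwidth = bw, degenerate = TRUE))
    }
    bw <- if (identical(bandwidth, "silverman")) bw.nrd0(values)
          else as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
    d <- density(values, bw = bw, kernel = "gaussian", n = 512, cut = 3)
    list(x = d$x, y = d$y, bandwidth = bw, degenerate = FALSE)
}

#' Compare two median correlations by Fisher transformation
#'
#' Two-sided z-test on the difference of two median Spearman
#' correlations after variance-stabilising Fisher transformation:
#' `z = (atanh(m1) - atanh(m2)) / sqrt(2 / (nEff - 3))`, with the
#' p-value from the standard normal tail. `nEff` is the effective sample
#' count underlying each correlation (by default the number of samples,
#' not the number of pairs). The test treats the two medians as
#' independent single correlations, an approximation recorded in the
#' result.
#'
#' @param group1,group2 numeric vectors of correlation coefficients (or
#'   single medians).
#' @param nEff effective per-correlation sample count (> 3).
#'
#' @return List with `median_1`, `median_2`, `n_eff`, `z`, `p`, and
#'   `note` describing the approximation.
#' @examples
#' compareMedianCorrelations(0.5, 0.0, nEff = 50)
#' @export
compareMedianCorrelations <- function(group1, group2, nEff) {
    m1 <- median(group1, na.rm = TRUE)
    m2 <- median(group2, na.rm = TRUE)
    if (abs(m1) >= 1 || abs(m2) >= 1)
        stop("median correlation of +/-1: Fisher transform is infinite")
    if (nEff <= 3) stop("nEff must exceed 3")
    z <- (atanh(m1) - atanh(m2)) / sqrt(2 / (nEff - 3))
    p <- 2 * pnorm(-abs(z))
    list(median_1 = m1, median_2 = m2, n_eff = nEff, z = z, p = p,
         note = paste("medians treated as independent single",
                      "correlations at nEff samples"))
}
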