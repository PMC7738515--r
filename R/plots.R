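# Base-graphics companions to the analysis tables: correlation density +
# rug figures, volcano plots with the FDR boundary, and the antigen map
# heatmap.

#' Plot correlation-group densities with rugs
#'
#' Kernel density estimates (see [correlationKde()]) of two or more
#' groups of Spearman coefficients, with rug marks for the raw values
#' and dashed lines at the group medians.
#'
#' @param groups named list of numeric vectors (e.g.
#'   `summariseCorrelations(...)$groups`); groups with fewer than two
#'   values are skipped.
#' @param main plot title.
#' @param col line colours, recycled.
#'
#' @return Invisibly, the list of density estimates.
#' @export
plotCorrelationDensities <- function(groups, main = "",
                                     col = c("#1b7837", "#762a83",
                                             "#2166ac", "#b2182b")) {
    groups <- groups[vapply(groups, function(g)
        sum(is.finite(g)) >= 2, TRUE)]
    if (!length(groups)) stop("no plottable groups")
    col <- rep_len(col, length(groups))
    kdes <- lapply(groups, correlationKde)
    xr <- range(unlist(lapply(kdes, `[[`, "x")))
    yr <- c(0, max(unlist(lapply(kdes, `[[`, "y"))))
    graphics::plot(NA, xlim = xr, ylim = yr, main = main,
                   xlab = "Spearman rank correlation coefficient",
                   ylab = "Density")
    for (i in seq_along(kdes)) {
        graphics::lines(kdes[[i]]$x, kdes[[i]]$y, col = col[i], lwd = 2)
        graphics::rug(groups[[i]], col = col[i],
                      side = if (i %% 2) 1 else 3)
        graphics::abline(v = median(groups[[i]]), col = col[i], lty = 2)
    }
    graphics::legend("topleft", legend = names(kdes), col = col,
                     lwd = 2, bty = "n")
    invisible(kdes)
}

#' Volcano plot of a differential result
#'
#' Mean log2 difference against the moderated statistic, with
#' significant antibodies highlighted and the FDR threshold drawn.
#'
#' @param result data.frame from [permutationFdr()] /
#'   [volcanoTable()].
#' @param main plot title.
#' @param labelTop label the top n significant antibodies.
#'
#' @return Invisibly, `NULL`.
#' @export
plotVolcano <- function(result, main = "", labelTop = 5L) {
    x <- result$mean_difference
    y <- if ("abs_t_mod" %in% names(result)) result$abs_t_mod
         else abs(result$t_mod)
    sig <- result$significant
    graphics::plot(x, y, pch = 16,
                   col = ifelse(sig, "#b2182b", "grey60"), main = main,
                   xlab = "Mean difference (log2, treated - control)",
                   ylab = "|moderated t|")
    cut <- attr(result, "cut")
    if (is.finite(cut)) graphics::abline(h = cut, col = "grey40",
                                         lty = 2)
    if (labelTop > 0 && any(sig)) {
        top <- order(-y)[seq_len(min(labelTop, sum(sig)))]
        graphics::text(x[top], y[top], result$antibody[top], pos = 3,
                       cex = 0.7)
    }
    invisible(NULL)
}

#' Heatmap of a clustered antibody antigen map
#'
#' Renders the integer-indexed antigen map (see [buildAntigenMap()]) as
#' an image: one shaded cell per antibody column at its antigen-class
#' row, darker shades for higher antibody indices within a class.
#'
#' @param map integer matrix from [buildAntigenMap()].
#' @param main plot title.
#'
#' @return Invisibly, `NULL`.
#' @export
plotAntigenMap <- function(map, main = "") {
    nIdx <- max(map, na.rm = TRUE)
    shades <- grDevices::colorRampPalette(c("#c2a5cf", "#40004b"))(nIdx)
    z <- t(map)[, rev(seq_len(nrow(map))), drop = FALSE]
    graphics::image(seq_len(ncol(map)), seq_len(nrow(map)), z,
                    col = shades, zlim = c(1, nIdx), main = main,
                    xlab = "Clustered antibody columns", ylab = "",
                    axes = FALSE)
    graphics::axis(1, at = seq_len(ncol(map)), labels = colnames(map),
                   las = 2, cex.axis = 0.5)
    graphics::axis(2, at = seq_len(nrow(map)),
                   labels = rev(rownames(map)), las = 2, cex.axis = 0.6)
    graphics::box()
    invisible(NULL)
}
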