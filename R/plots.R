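#' Plot statin-use odds ratios by allele-count bin
#'
#' Dose-response display: per-bin odds ratios of regular statin use against
#' bin midpoints (reference bin at OR 1) with the fitted linear trend, over
#' bars showing the share of users per bin.
#'
#' @param x An `allele_bin_or` object from [or_by_allele_count()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.allele_bin_or <- function(x, ...) {
  b <- x$bins
  prop <- b$n_users / b$n
  graphics::barplot(stats::setNames(prop, round(b$midpoint, 1)),
                    col = "grey80", border = NA,
                    ylim = c(0, max(prop, b$or, na.rm = TRUE) * 1.2),
                    xlab = "risk alleles (bin midpoint)",
                    ylab = "OR of statin use / proportion users", ...)
  at <- seq(0.7, by = 1.2, length.out = nrow(b))
  graphics::points(at, b$or, pch = 19)
  graphics::abline(h = 1, lty = 3)
  graphics::abline(stats::lm(b$or ~ at), col = "darkgreen")
  invisible(x)
}

#' Overlayed score distributions for cases and controls
#'
#' Mirrors the usual check that case and control allele-count distributions
#' coincide under the null: relative frequency of each allele count, with
#' cases superimposed on controls.
#'
#' @param score A `lipid_score` or numeric vector.
#' @param case Binary case indicator aligned with the score.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the table of proportions plotted.
#' @export
plot_score_distribution <- function(score, case, ...) {
  s <- if (inherits(score, "lipid_score")) score$score else score
  lab <- if (inherits(score, "lipid_score")) score$trait else "score"
  brk <- seq(floor(min(s, na.rm = TRUE)), ceiling(max(s, na.rm = TRUE)))
  p0 <- table(factor(round(s[case == 0]), levels = brk)) / sum(case == 0)
  p1 <- table(factor(round(s[case == 1]), levels = brk)) / sum(case == 1)
  graphics::barplot(p0, col = "grey70", border = NA,
                    xlab = paste(lab, "risk alleles"),
                    ylab = "proportion of subjects", ...)
  graphics::barplot(p1, col = grDevices::adjustcolor("firebrick", 0.45),
                    border = NA, add = TRUE, axes = FALSE)
  invisible(list(controls = p0, cases = p1))
}
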