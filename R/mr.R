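#' Mendelian-randomization association of a lipid genetic score with
#' case-control status
#'
#' Fits the covariate-adjusted logistic model
#' `case ~ score/10 + design covariates` and reports the odds ratio per 10
#' risk alleles (OR_10) with its 95% Wald interval. Optionally repeats the
#' fit within statin-use strata and tests the score-by-statin interaction
#' with a Wald test on the product term.
#'
#' @param score A [build_lgs()] `lipid_score` (or a named numeric vector of
#'   allele counts).
#' @param cohort CohortTable data.frame with a binary `case` column; rows
#'   must align with the score's subjects.
#' @param design Design covariate matrix from [build_design_matrix()] (or
#'   `NULL` for an unadjusted fit).
#' @param strata Optional name of a binary column of `cohort` (e.g.
#'   `"statin"`) defining strata for stratified fits and an interaction
#'   test.
#' @return Object of class `lgs_mr`: list with `trait`, `overall` (the
#'   score term's `logistic_result` row), `by_group` (mean +/- sd of allele
#'   counts in cases and controls, from [compare_mean_alleles()]), `strata`
#'   (per-stratum results), `interaction_p`, `n`.
#' @export
score_crc_association <- function(score, cohort, design = NULL,
                                  strata = NULL) {
  s <- if (inherits(score, "lipid_score")) score$score else score
  trait <- if (inherits(score, "lipid_score")) score$trait else "score"
  stopifnot(length(s) == nrow(cohort))
  y <- cohort$case
  fit_one <- function(idx) {
    X <- cbind(score_10 = s[idx] / 10,
               drop_constant_cols(
                 if (!is.null(design)) design[idx, , drop = FALSE]))
    res <- fit_logistic(y[idx], X)
    res[res$term == "score_10", , drop = FALSE]
  }
  overall <- fit_one(seq_along(y))
  by_group <- compare_mean_alleles(s, y, labels = c("controls", "cases"))
  strata_res <- NULL; interaction_p <- NA_real_
  if (!is.null(strata)) {
    g <- cohort[[strata]]
    if (is.null(g)) stop2("stratum column '", strata, "' not in cohort")
    strata_res <- lapply(stats::setNames(sort(unique(g)),
                                         paste0(strata, "=", sort(unique(g)))),
                         function(v) {
      idx <- which(g == v)
      if (length(idx) == 0) stop2("empty stratum ", strata, " = ", v)
      fit_one(idx)
    })
    Xint <- cbind(score_10 = s / 10, stratum = g,
                  `score_10:stratum` = (s / 10) * g,
                  if (!is.null(design)) design)
    full <- fit_logistic(y, Xint)
    interaction_p <- full$p[full$term == "score_10:stratum"]
  }
  structure(list(trait = trait, overall = overall, by_group = by_group,
                 strata = strata_res, interaction_p = interaction_p,
                 n = overall$n), class = "lgs_mr")
}

#' @export
print.lgs_mr <- function(x, ...) {
  cat("<lgs_mr> ", x$trait,
      " genetic score vs case-control status (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  OR per 10 risk alleles: %.2f (95%% CI %.2f-%.2f), p = %s\n",
              x$overall$or, x$overall$ci_lo, x$overall$ci_hi,
              format.pval(x$overall$p, digits = 2)))
  bg <- x$by_group
  cat(sprintf("  risk alleles: %s %.2f +/- %.2f; %s %.2f +/- %.2f (t p = %s)\n",
              bg$groups$group[1], bg$groups$mean[1], bg$groups$sd[1],
              bg$groups$group[2], bg$groups$mean[2], bg$groups$sd[2],
              format.pval(bg$p, digits = 2)))
  if (!is.null(x$strata)) {
    for (nm in names(x$strata)) {
      r <- x$strata[[nm]]
      cat(sprintf("  %s: OR_10 %.2f (%.2f-%.2f), p = %s\n", nm, r$or,
                  r$ci_lo, r$ci_hi, format.pval(r$p, digits = 2)))
    }
    cat("  interaction p =", format.pval(x$interaction_p, digits = 2), "\n")
  }
  invisible(x)
}

#' @export
summary.lgs_mr <- function(object, ...) {
  rows <- list(cbind(stratum = "all", object$overall))
  for (nm in names(object$strata))
    rows[[length(rows) + 1L]] <- cbind(stratum = nm, object$strata[[nm]])
  out <- do.call(rbind, rows)
  attr(out, "interaction_p") <- object$interaction_p
  attr(out, "by_group") <- object$by_group
  out
}

#' @export
coef.lgs_mr <- function(object, ...) {
  stats::setNames(object$overall$beta, "score_10")
}

#' @export
confint.lgs_mr <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  with(object$overall,
       matrix(c(beta - z * se, beta + z * se), 1, 2,
              dimnames = list("score_10",
                              paste0(100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2), " %"))))
}

#' Compare mean allele counts (or any quantity) between two groups
#'
#' Two-sample t comparison of the score between cases and controls,
#' formatted as mean +/- sd per group. The default pooled-variance test is
#' algebraically identical to the two-sided p-value of the group indicator
#' in a single-covariate linear model; `welch = TRUE` gives the
#' unequal-variance version.
#'
#' @param x Numeric vector.
#' @param group Binary group indicator (0/1 or two-level factor).
#' @param labels Group labels in level order.
#' @param welch Use the Welch unequal-variance statistic.
#' @return List with `groups` (data.frame of group, n, mean, sd),
#'   `t`, `df`, `p`.
#' @export
compare_mean_alleles <- function(x, group, labels = NULL, welch = FALSE) {
  g <- as.integer(factor(group)) - 1L
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  if (length(unique(g)) != 2) stop2("exactly two non-empty groups required")
  if (min(table(g)) < 2) stop2("each group needs at least 2 observations")
  tt <- stats::t.test(x[g == 0], x[g == 1], var.equal = !welch)
  labels <- labels %||% levels(factor(group))
  groups <- data.frame(
    group = labels,
    n = as.vector(table(g)),
    mean = c(mean(x[g == 0]), mean(x[g == 1])),
    sd = c(stats::sd(x[g == 0]), stats::sd(x[g == 1])),
    stringsAsFactors = FALSE)
  list(groups = groups, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Per-SNP case-control scan with Bonferroni thresholds
#'
#' Fits an additive logistic model `case ~ dosage + design` for every SNP of
#' the selected sets (dosages oriented to the risk allele) and reports, per
#' trait, the Bonferroni threshold 0.05 / (number of SNPs in the score) and
#' a summary of the signed effect distribution. Monomorphic SNPs are
#' skipped with a message.
#'
#' @param G A [genotype_matrix()].
#' @param cohort CohortTable with binary `case`.
#' @param design Covariate matrix from [build_design_matrix()] or `NULL`.
#' @param sets Named list (per trait) of SNP id vectors, e.g.
#'   `selection_report$kept`.
#' @param alpha Family-wise level for the Bonferroni threshold.
#' @return List with `results` (data.frame: trait, snp_id, beta, se, or, p,
#'   `below_bonferroni`), `thresholds` (named per trait), and
#'   `effect_summary` (mean and sd of per-SNP betas per trait).
#' @export
per_snp_scan <- function(G, cohort, design = NULL, sets, alpha = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"), is.list(sets))
  y <- cohort$case
  out <- list()
  for (tr in names(sets)) {
    snps <- sets[[tr]]
    thr <- alpha / length(snps)
    for (id in snps) {
      d <- G$dosage[, id]
      if (anyNA(d)) d[is.na(d)] <- mean(d, na.rm = TRUE)
      if (stats::var(d) == 0) {
        message("skipping monomorphic SNP ", id)
        next
      }
      X <- cbind(dosage = d, design)
      res <- fit_logistic(y, X)
      row <- res[res$term == "dosage", , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, snp_id = id, beta = row$beta, se = row$se, or = row$or,
        p = row$p, below_bonferroni = !is.na(row$p) & row$p < thr,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, out)
  thresholds <- vapply(sets, function(s) alpha / length(s), 0)
  effect_summary <- do.call(rbind, lapply(split(results, results$trait),
    function(d) data.frame(trait = d$trait[1], n_snps = nrow(d),
                           mean_beta = mean(d$beta, na.rm = TRUE),
                           sd_beta = stats::sd(d$beta, na.rm = TRUE))))
  rownames(effect_summary) <- NULL
  list(results = results, thresholds = thresholds,
       effect_summary = effect_summary)
}

#' Odds ratios of statin use by allele-count bin, with per-allele trend
#'
#' Groups a genetic score into fixed-width allele-count bins anchored so the
#' bin containing the population median is the reference, fits a logistic
#' model of regular statin use on the bin indicators (plus optional design
#' covariates), and summarizes the dose-response: a continuous-score model
#' whose per-allele odds ratio is also expressed as a percent increase per
#' risk allele, and an ordinary linear fit of the per-bin ORs against bin
#' midpoints. Bins with fewer than `min_bin` subjects are merged into their
#' neighbor.
#'
#' @param score A `lipid_score` or numeric vector.
#' @param statin Binary regular-statin-use vector.
#' @param design Optional covariate matrix.
#' @param bin_width Bin width in alleles (default 3).
#' @param min_bin Minimum subjects per bin before merging (default 5).
#' @return Object of class `allele_bin_or`: list with `bins` (data.frame of
#'   bin label, midpoint, n, n_users, or, ci_lo, ci_hi; reference bin OR 1),
#'   `per_allele` (or, ci, p, percent increase), `trend` (intercept/slope of
#'   the linear fit to bin ORs), `reference`.
#' @export
or_by_allele_count <- function(score, statin, design = NULL, bin_width = 3,
                               min_bin = 5) {
  s <- if (inherits(score, "lipid_score")) score$score else score
  ok <- !is.na(s) & !is.na(statin)
  s <- s[ok]; statin <- statin[ok]
  if (!is.null(design)) design <- design[ok, , drop = FALSE]
  med <- stats::median(s)
  # anchor breaks so the median sits inside one bin
  start <- med - bin_width / 2
  lo <- start - bin_width * ceiling((start - min(s)) / bin_width)
  breaks <- seq(lo, max(s) + bin_width, by = bin_width)
  bin <- cut(s, breaks, right = FALSE, include.lowest = TRUE)
  # merge sparse bins into neighbours
  repeat {
    cnt <- table(bin)
    small <- names(cnt)[cnt > 0 & cnt < min_bin]
    if (!length(small)) break
    lv <- levels(bin)
    i <- match(small[1], lv)
    j <- if (i > 1) i - 1L else i + 1L
    message("merging sparse bin ", lv[i], " into ", lv[j])
    lv_new <- lv; lv_new[i] <- lv[j]
    levels(bin) <- lv_new
  }
  bin <- droplevels(bin)
  mids <- vapply(levels(bin), function(l) mean(s[bin == l]), 0)
  ref <- levels(bin)[which.min(abs(mids - med))]
  bin <- stats::relevel(bin, ref)
  Xb <- stats::model.matrix(~ bin)[, -1, drop = FALSE]
  fitb <- fit_logistic(statin, cbind(Xb, design))
  bres <- fitb[fitb$term %in% colnames(Xb), , drop = FALSE]
  lv_ord <- levels(bin)[order(mids[levels(bin)])]
  bins <- do.call(rbind, lapply(lv_ord, function(l) {
    if (l == ref) {
      data.frame(bin = l, midpoint = mids[[l]], n = sum(bin == l),
                 n_users = sum(statin[bin == l]), or = 1, ci_lo = NA_real_,
                 ci_hi = NA_real_, stringsAsFactors = FALSE)
    } else {
      r <- bres[bres$term == paste0("bin", l), , drop = FALSE]
      data.frame(bin = l, midpoint = mids[[l]], n = sum(bin == l),
                 n_users = sum(statin[bin == l]), or = r$or, ci_lo = r$ci_lo,
                 ci_hi = r$ci_hi, stringsAsFactors = FALSE)
    }
  }))
  rownames(bins) <- NULL
  fitc <- fit_logistic(statin, cbind(score = s, design))
  pa <- fitc[fitc$term == "score", , drop = FALSE]
  per_allele <- list(or = pa$or, ci_lo = pa$ci_lo, ci_hi = pa$ci_hi,
                     p = pa$p, percent_increase = 100 * (pa$or - 1))
  lmfit <- stats::lm(or ~ midpoint, data = bins)
  structure(list(bins = bins, per_allele = per_allele,
                 trend = stats::coef(lmfit), reference = ref),
            class = "allele_bin_or")
}

#' @export
print.allele_bin_or <- function(x, ...) {
  cat("<allele_bin_or> statin use by allele count (reference bin ",
      x$reference, ")\n", sep = "")
  df <- x$bins
  df$or <- signif(df$or, 3)
  print.data.frame(df[c("bin", "n", "n_users", "or")], row.names = FALSE)
  cat(sprintf("  per-allele OR %.3f (+%.1f%% per risk allele), trend slope %.4f/allele\n",
              x$per_allele$or, x$per_allele$percent_increase,
              x$trend[["midpoint"]]))
  invisible(x)
}
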