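#' Hardy-Weinberg equilibrium chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against the Hardy-Weinberg proportions at the allele frequency
#' estimated from the same counts.
#'
#' @param counts Numeric vector `c(n0, n1, n2)`: subjects carrying 0, 1 and
#'   2 copies of the counted allele.
#' @param flag_threshold Deviation flag threshold on the p-value (default
#'   0.001, the usual genotyping-QC level).
#' @return List with `chisq`, `p`, `df = 1`, `monomorphic` and `deviation`
#'   (`p < flag_threshold`). A monomorphic variant has an undefined test;
#'   its p is reported as 1 with `monomorphic = TRUE`.
#' @examples
#' hwe_test(c(25, 50, 25))   # exact HWE proportions: chisq 0, p 1
#' hwe_test(c(0, 100, 0))    # all heterozygous: chisq 100
#' @export
hwe_test <- function(counts, flag_threshold = 0.001) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop2("total genotype count must be positive")
  p_hat <- (2 * counts[3] + counts[2]) / (2 * n)
  if (p_hat == 0 || p_hat == 1)
    return(list(chisq = 0, p = 1, df = 1L, monomorphic = TRUE,
                deviation = FALSE))
  expected <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  chisq <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(chisq), p = unname(p), df = 1L, monomorphic = FALSE,
       deviation = p < flag_threshold)
}

#' Hardy-Weinberg scan over all variants of a genotype matrix
#'
#' @param G A [genotype_matrix()].
#' @param subset_mask Optional subject subset; conventionally the controls.
#' @param flag_threshold Passed to [hwe_test()].
#' @return Data frame with one row per variant: genotype counts, `chisq`,
#'   `p`, `monomorphic`, `deviation`.
#' @export
hwe_scan <- function(G, subset_mask = NULL, flag_threshold = 0.001) {
  stopifnot(inherits(G, "genotype_matrix"))
  D <- G$dosage
  if (!is.null(subset_mask)) D <- D[subset_mask, , drop = FALSE]
  out <- lapply(seq_len(ncol(D)), function(j) {
    cnt <- tabulate(D[, j] + 1L, nbins = 3L)
    h <- hwe_test(cnt, flag_threshold)
    data.frame(snp_id = colnames(D)[j], n0 = cnt[1], n1 = cnt[2], n2 = cnt[3],
               chisq = h$chisq, p = h$p, monomorphic = h$monomorphic,
               deviation = h$deviation, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits a binary-outcome logistic model by iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 50 iterations) and returns
#' one row per term with the log-odds coefficient, Wald standard error from
#' the observed information, odds ratio, 95% Wald confidence interval and
#' two-sided Wald p-value. An intercept is always included. Rank-deficient
#' designs raise an error naming the offending column; complete or
#' quasi-complete separation (diverging coefficients, |beta| > 15) is
#' flagged and the affected estimates withheld.
#'
#' @param y Binary outcome vector (0/1), not constant.
#' @param X Numeric matrix (or data.frame of numeric columns) of predictors,
#'   without intercept.
#' @return A data.frame of class `logistic_result` with columns `term`,
#'   `beta`, `se`, `or`, `ci_lo`, `ci_hi`, `p`, `n`, `converged`,
#'   `iterations`, `separation`.
#' @export
fit_logistic <- function(y, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(dim(X))) X <- matrix(X, ncol = 1, dimnames = list(NULL, "x"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(X) & !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  if (!all(y %in% c(0, 1))) stop2("y must be binary 0/1")
  if (length(unique(y)) < 2) stop2("y is constant")
  Xi <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_x$pivot[(qr_x$rank + 1):ncol(Xi)]]
    stop2("design matrix is rank deficient; aliased column(s): ",
          paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    Xi, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  beta <- fit$coefficients
  w <- fit$weights
  info <- crossprod(Xi * sqrt(w))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, ncol(Xi), ncol(Xi))
  })
  se <- sqrt(diag(vc))
  sep <- abs(beta) > 15
  beta[sep] <- NA_real_; se[sep] <- NA_real_
  z <- beta / se
  res <- data.frame(
    term = colnames(Xi), beta = unname(beta), se = unname(se),
    or = exp(unname(beta)),
    ci_lo = exp(unname(beta - 1.96 * se)),
    ci_hi = exp(unname(beta + 1.96 * se)),
    p = 2 * stats::pnorm(abs(unname(z)), lower.tail = FALSE),
    n = length(y), converged = fit$converged, iterations = fit$iter,
    separation = unname(sep),
    stringsAsFactors = FALSE)
  if (any(sep))
    warn2("separation detected for term(s): ",
          paste(res$term[sep], collapse = ", "), "; estimates withheld")
  class(res) <- c("logistic_result", "data.frame")
  res
}

#' @export
print.logistic_result <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  for (v in intersect(c("beta", "se", "or", "ci_lo", "ci_hi"), names(df)))
    df[[v]] <- signif(df[[v]], digits)
  if ("p" %in% names(df)) df$p <- format.pval(df$p, digits = digits)
  show <- intersect(c("term", "beta", "se", "or", "ci_lo", "ci_hi", "p"),
                    names(df))
  print.data.frame(df[show], row.names = FALSE)
  invisible(x)
}

#' Principal components of genetic ancestry
#'
#' Computes the leading principal components of the subjects from a set of
#' ancestry-informative markers. Missing dosages are mean-imputed; each
#' marker column is centered at twice its allele frequency and scaled by the
#' binomial standard deviation `sqrt(2 p (1 - p))`; monomorphic markers are
#' dropped. Subject coordinates are the unit-norm left singular vectors,
#' with each component's sign fixed so its largest-magnitude entry is
#' positive.
#'
#' @param G A [genotype_matrix()].
#' @param markers Variant ids to use (default: all).
#' @param k Number of components (default 3).
#' @return Numeric matrix subjects x k with columns `PC1` ... and attribute
#'   `"eigenvalues"` (all squared singular values / (n - 1)).
#' @export
genotype_pca <- function(G, markers = NULL, k = 3) {
  stopifnot(inherits(G, "genotype_matrix"))
  markers <- markers %||% G$snp_ids
  X <- G$dosage[, markers, drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop2("at least 3 subjects required")
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  p_hat <- colMeans(X) / 2
  poly <- p_hat > 0 & p_hat < 1
  if (sum(poly) < 3) stop2("at least 3 polymorphic markers required")
  X <- X[, poly, drop = FALSE]; p_hat <- p_hat[poly]
  Z <- sweep(X, 2, 2 * p_hat, "-")
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  sv <- svd(Z, nu = min(k, ncol(Z)), nv = 0)
  U <- sv$u[, seq_len(min(k, ncol(sv$u))), drop = FALSE]
  for (j in seq_len(ncol(U))) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) U[, j] <- -U[, j]
  }
  dimnames(U) <- list(G$subject_ids, paste0("PC", seq_len(ncol(U))))
  attr(U, "eigenvalues") <- sv$d^2 / (n - 1)
  U
}

#' Study-design adjustment covariate specification
#'
#' The covariate block adjusted for in every model: age, sex, recruiting
#' center, education, the first three ancestry principal components, and the
#' age-by-sex and region-by-sex interactions. An optional confounder block
#' (alcohol, waist-hip ratio, physical activity, red meat, ASA/NSAID use)
#' extends the multivariate statin models.
#'
#' @param covariates Main-effect covariate names present in the cohort.
#' @param pcs Use ancestry PCs when available (logical).
#' @param interactions Interaction terms, in `a:b` notation.
#' @param confounders Confounder-block column names.
#' @param region_map Optional named vector mapping center levels to region
#'   labels for the region-by-sex interaction; default: region = center.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(covariates = c("age", "sex", "center", "education"),
                        pcs = TRUE,
                        interactions = c("age:sex", "region:sex"),
                        confounders = c("alcohol", "whr_high", "phys_act",
                                        "red_meat", "asa", "nsaid"),
                        region_map = NULL) {
  structure(list(covariates = covariates, pcs = pcs,
                 interactions = interactions, confounders = confounders,
                 region_map = region_map), class = "design_spec")
}

#' Build the design-covariate matrix for a cohort
#'
#' Encodes the study-design adjustment covariates (and optionally the
#' confounder block) into a numeric model matrix without intercept.
#' Duplicate (exactly collinear) columns are removed with a message.
#'
#' @param cohort CohortTable data.frame.
#' @param spec A [design_spec()].
#' @param pcs Optional subjects x k PC matrix from [genotype_pca()], row
#'   order matching the cohort.
#' @param confounders Include the confounder block (logical, default
#'   `FALSE`).
#' @return Numeric matrix, subjects x encoded covariates.
#' @export
build_design_matrix <- function(cohort, spec = design_spec(), pcs = NULL,
                                confounders = FALSE) {
  stopifnot(inherits(spec, "design_spec"))
  dat <- cohort[, intersect(spec$covariates, names(cohort)), drop = FALSE]
  if (ncol(dat) == 0) stop2("no usable design covariates in cohort")
  if ("sex" %in% names(dat)) dat$sex <- factor(dat$sex)
  if ("center" %in% names(dat)) dat$center <- factor(dat$center)
  region <- if (!is.null(spec$region_map) && "center" %in% names(dat)) {
    factor(unname(spec$region_map[as.character(dat$center)]))
  } else if ("center" %in% names(dat)) {
    dat$center
  }
  X <- stats::model.matrix(~ ., data = dat)[, -1, drop = FALSE]
  # interactions built by hand (contrast-style: first level omitted) so the
  # encoding stays full rank whatever the region grouping
  male <- if ("sex" %in% names(dat)) as.numeric(dat$sex == levels(dat$sex)[2])
  for (term in spec$interactions) {
    vars <- sort(strsplit(term, ":", fixed = TRUE)[[1]])
    if (identical(vars, c("age", "sex")) && "age" %in% names(dat) &&
        !is.null(male)) {
      X <- cbind(X, `age:sexmale` = dat$age * male)
    } else if (identical(vars, c("region", "sex")) && !is.null(region) &&
               !is.null(male)) {
      for (r in levels(region)[-1]) {
        X <- cbind(X, as.numeric(region == r) * male)
        colnames(X)[ncol(X)] <- paste0("region", r, ":sexmale")
      }
    }
  }
  if (isTRUE(spec$pcs) && !is.null(pcs))
    X <- cbind(X, pcs[, seq_len(min(3, ncol(pcs))), drop = FALSE])
  if (confounders) {
    cf <- intersect(spec$confounders, names(cohort))
    X <- cbind(X, as.matrix(cohort[, cf, drop = FALSE]))
  }
  # drop exactly duplicated columns (e.g. degenerate region maps)
  X <- drop_duplicate_cols(X)
  X
}

# remove zero-variance columns and columns aliased with earlier ones (both
# arise when covariates or interactions collapse within a stratum), so
# stratified fits stay full rank
drop_constant_cols <- function(X) {
  if (is.null(X)) return(NULL)
  keep <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) > 1)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) return(X)
  q <- qr(cbind(1, X))
  if (q$rank < ncol(X) + 1) {
    aliased <- setdiff(q$pivot[-seq_len(q$rank)], 1L) - 1L
    X <- X[, -aliased, drop = FALSE]
  }
  X
}

drop_duplicate_cols <- function(X) {
  dup <- duplicated(t(X))
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicate design column(s): ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
  }
  X
}
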