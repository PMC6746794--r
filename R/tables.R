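#' Summary of statin exposure in a cohort
#'
#' Tabulates regular statin users overall, by case status, by molecule and
#' by pharmacologic class, with percentages over users — the arithmetic
#' behind statements such as "simvastatin, 47.5% of users".
#'
#' @param cohort CohortTable with `case`, `statin`, `statin_name` (and
#'   optionally the class columns, otherwise they are derived via
#'   [statin_classes()]).
#' @return List with `n_users`, `users_by_case` (named: controls, cases),
#'   `by_name` (data.frame name, n, pct of users), `by_lipophilicity`,
#'   `by_potency`.
#' @export
statin_use_summary <- function(cohort) {
  stopifnot(all(c("case", "statin") %in% names(cohort)))
  users <- cohort[cohort$statin == 1, , drop = FALSE]
  n_users <- nrow(users)
  by_case <- c(controls = sum(users$case == 0), cases = sum(users$case == 1))
  tab_pct <- function(x) {
    t <- table(x)
    data.frame(level = names(t), n = as.vector(t),
               pct = round(100 * as.vector(t) / n_users, 1),
               stringsAsFactors = FALSE)
  }
  cls <- statin_classes()
  lip <- users$statin_lipophilicity %||% cls[users$statin_name, "lipophilicity"]
  pot <- users$statin_potency %||% cls[users$statin_name, "potency"]
  list(n_users = n_users, users_by_case = by_case,
       by_name = tab_pct(users$statin_name),
       by_lipophilicity = tab_pct(lip),
       by_potency = tab_pct(pot))
}

#' Risk-factor association table (crude and multivariate-adjusted)
#'
#' For each binary factor, counts and percentages by case status plus two
#' covariate-adjusted logistic odds ratios: "crude" (factor + study-design
#' covariates) and "adjusted" (additionally the confounder block, excluding
#' the factor itself).
#'
#' @param cohort CohortTable with binary `case` and the factor columns.
#' @param factors Character vector of binary factor column names.
#' @param design Design covariate matrix from [build_design_matrix()].
#' @param confounder_matrix Confounder-block matrix (same rows); columns
#'   named after the factors they encode.
#' @return Data.frame, one row per factor: counts/% in controls and cases,
#'   crude and adjusted OR, 95% CI bounds and p-values. Factors constant
#'   within cases or controls are flagged (`degenerate = TRUE`, no fit).
#' @export
covariate_association_table <- function(cohort, factors, design,
                                        confounder_matrix = NULL) {
  y <- cohort$case
  rows <- lapply(factors, function(f) {
    x <- cohort[[f]]
    if (is.null(x)) stop2("factor '", f, "' not in cohort")
    n_ctl <- sum(x == 1 & y == 0, na.rm = TRUE)
    n_cas <- sum(x == 1 & y == 1, na.rm = TRUE)
    base <- data.frame(
      factor = f, n_controls = n_ctl,
      pct_controls = round(100 * n_ctl / sum(y == 0), 1),
      n_cases = n_cas, pct_cases = round(100 * n_cas / sum(y == 1), 1),
      stringsAsFactors = FALSE)
    if (length(unique(x[y == 0])) < 2 || length(unique(x[y == 1])) < 2) {
      return(cbind(base, or_crude = NA_real_, ci_lo_crude = NA_real_,
                   ci_hi_crude = NA_real_, p_crude = NA_real_,
                   or_adj = NA_real_, ci_lo_adj = NA_real_,
                   ci_hi_adj = NA_real_, p_adj = NA_real_, degenerate = TRUE))
    }
    crude <- fit_logistic(y, cbind(factor = x, design))
    cr <- crude[crude$term == "factor", ]
    cm <- confounder_matrix
    if (!is.null(cm)) cm <- cm[, setdiff(colnames(cm), f), drop = FALSE]
    adj <- fit_logistic(y, cbind(factor = x, design, cm))
    ad <- adj[adj$term == "factor", ]
    cbind(base, or_crude = cr$or, ci_lo_crude = cr$ci_lo,
          ci_hi_crude = cr$ci_hi, p_crude = cr$p,
          or_adj = ad$or, ci_lo_adj = ad$ci_lo, ci_hi_adj = ad$ci_hi,
          p_adj = ad$p, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Statin subgroup analysis: class, sex and tumour-location contrasts
#'
#' With statin non-users as the common reference, fits adjusted logistic
#' models contrasting (a) lipophilic and hydrophilic users, (b) low- and
#' high-potency users, (c) statin use within each sex, with a Wald test of
#' the statin-by-sex interaction, and (d) statin use for colon and rectal
#' cases against all controls. Classes with no users are suppressed with a
#' note.
#'
#' @param cohort CohortTable with `case`, `statin`, `statin_lipophilicity`,
#'   `statin_potency`, `sex` and optionally `location` (cases).
#' @param design Design covariate matrix.
#' @param confounder_matrix Optional confounder block appended to every
#'   model.
#' @return List of data.frames `lipophilicity`, `potency`, `by_sex` (with
#'   attribute `"interaction_p"`), `by_location`; each row: subgroup,
#'   n_controls, n_cases, or, ci_lo, ci_hi, p.
#' @export
statin_subgroup_analysis <- function(cohort, design,
                                     confounder_matrix = NULL) {
  y <- cohort$case
  adj <- function(X, idx = seq_along(y)) {
    Z <- cbind(design[idx, , drop = FALSE],
               if (!is.null(confounder_matrix))
                 confounder_matrix[idx, , drop = FALSE])
    fit_logistic(y[idx], cbind(X[idx, , drop = FALSE], drop_constant_cols(Z)))
  }
  row_of <- function(fit, term, label, idx_users) {
    r <- fit[fit$term == term, ]
    data.frame(subgroup = label,
               n_controls = sum(y == 0 & idx_users),
               n_cases = sum(y == 1 & idx_users),
               or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p,
               stringsAsFactors = FALSE)
  }
  class_table <- function(col) {
    levels_present <- sort(unique(stats::na.omit(cohort[[col]])))
    rows <- list()
    ind <- NULL
    for (lv in levels_present) {
      u <- !is.na(cohort[[col]]) & cohort[[col]] == lv & cohort$statin == 1
      if (!any(u)) { message("no users in class ", lv, "; row suppressed"); next }
      ind <- cbind(ind, as.numeric(u))
      colnames(ind)[ncol(ind)] <- lv
    }
    if (is.null(ind)) return(NULL)
    fit <- adj(ind)
    for (lv in colnames(ind))
      rows[[lv]] <- row_of(fit, lv, lv, ind[, lv] == 1)
    out <- do.call(rbind, rows); rownames(out) <- NULL
    out
  }
  lip <- class_table("statin_lipophilicity")
  pot <- class_table("statin_potency")

  # sex-stratified statin effect + interaction
  sexes <- levels(factor(cohort$sex))
  by_sex <- do.call(rbind, lapply(sexes, function(sx) {
    idx <- which(cohort$sex == sx)
    fit <- adj(cbind(statin = cohort$statin), idx)
    r <- fit[fit$term == "statin", ]
    data.frame(subgroup = sx,
               n_controls = sum(y[idx] == 0 & cohort$statin[idx] == 1),
               n_cases = sum(y[idx] == 1 & cohort$statin[idx] == 1),
               or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p,
               stringsAsFactors = FALSE)
  }))
  male <- as.numeric(cohort$sex == sexes[length(sexes)])
  fit_int <- adj(cbind(statin = cohort$statin,
                       `statin:sexmale` = cohort$statin * male))
  attr(by_sex, "interaction_p") <-
    fit_int$p[fit_int$term == "statin:sexmale"]

  by_loc <- NULL
  if ("location" %in% names(cohort)) {
    locs <- sort(unique(stats::na.omit(cohort$location)))
    by_loc <- do.call(rbind, lapply(locs, function(lc) {
      idx <- which(y == 0 | (!is.na(cohort$location) & cohort$location == lc))
      fit <- adj(cbind(statin = cohort$statin), idx)
      r <- fit[fit$term == "statin", ]
      data.frame(subgroup = lc,
                 n_controls = sum(y[idx] == 0 & cohort$statin[idx] == 1),
                 n_cases = sum(y[idx] == 1 & cohort$statin[idx] == 1),
                 or = r$or, ci_lo = r$ci_lo, ci_hi = r$ci_hi, p = r$p,
                 stringsAsFactors = FALSE)
    }))
  }
  list(lipophilicity = lip, potency = pot, by_sex = by_sex,
       by_location = by_loc)
}
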