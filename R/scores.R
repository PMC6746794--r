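#' Orient a catalog effect allele against the genotype file's counted allele
#'
#' Determines how the counted-allele dosage must be transformed so that it
#' counts copies of the effect (lipid-raising) allele, allowing for the
#' genotyping array reporting the opposite strand. `same` and `strand_flip`
#' leave the dosage unchanged; `flip` and `strand_flip_and_flip` replace it
#' by `2 - d`. Palindromic variants (A/T or C/G) cannot be oriented by
#' strand; with `palindromic = "exclude"` (default) they are declared
#' `unresolvable`, with `palindromic = "freq"` they are resolved by allele
#' frequency when the counted-allele frequency is within `freq_tol` of the
#' catalog effect-allele frequency (or of its complement).
#'
#' @param effect_allele,other_allele Catalog alleles (single bases).
#' @param counted_allele,other_counted Alleles of the genotype file, the
#'   first being the one its dosage counts.
#' @param palindromic Policy for A/T and C/G variants: `"exclude"` or
#'   `"freq"`.
#' @param counted_freq,catalog_freq Allele frequencies used by the `"freq"`
#'   policy.
#' @param freq_tol Frequency-match tolerance (default 0.2).
#' @return One of `"same"`, `"flip"`, `"strand_flip"`,
#'   `"strand_flip_and_flip"`, `"unresolvable"`.
#' @export
align_risk_allele <- function(effect_allele, other_allele, counted_allele,
                              other_counted, palindromic = c("exclude", "freq"),
                              counted_freq = NULL, catalog_freq = NULL,
                              freq_tol = 0.2) {
  palindromic <- match.arg(palindromic)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  al <- c(effect_allele, other_allele, counted_allele, other_counted)
  if (any(is.na(al)) || !all(al %in% names(comp))) return("unresolvable")
  if (effect_allele == other_allele || counted_allele == other_counted)
    return("unresolvable")
  is_palin <- effect_allele == comp[[other_allele]]
  if (is_palin) {
    if (!setequal(c(counted_allele, other_counted),
                  c(effect_allele, other_allele))) return("unresolvable")
    if (palindromic == "exclude" || is.null(counted_freq) ||
        is.null(catalog_freq)) return("unresolvable")
    # same-strand reading: counted allele's frequency should match the
    # catalog frequency of that same letter
    f_cat <- if (counted_allele == effect_allele) catalog_freq else 1 - catalog_freq
    match_same <- abs(counted_freq - f_cat) < freq_tol
    match_flip <- abs(counted_freq - (1 - f_cat)) < freq_tol
    if (match_same && match_flip) return("unresolvable")  # ambiguous (freq near 0.5)
    if (match_same)
      return(if (counted_allele == effect_allele) "same" else "flip")
    if (match_flip)
      return(if (counted_allele == effect_allele) "flip" else "same")
    return("unresolvable")
  }
  if (setequal(c(counted_allele, other_counted),
               c(effect_allele, other_allele))) {
    return(if (counted_allele == effect_allele) "same" else "flip")
  }
  if (setequal(c(counted_allele, other_counted),
               c(comp[[effect_allele]], comp[[other_allele]]))) {
    return(if (counted_allele == comp[[effect_allele]]) "strand_flip"
           else "strand_flip_and_flip")
  }
  "unresolvable"
}

#' Build an unweighted lipid genetic score
#'
#' Sums, over the selected SNPs, the number of copies of the risk
#' (lipid-raising) allele per subject, with equal weight for every SNP.
#' Each SNP's dosage is first oriented with [align_risk_allele()];
#' unresolvable SNPs are dropped with a warning. Missing genotypes are
#' either mean-imputed with twice the control risk-allele frequency
#' (`missing_policy = "mean_impute"`, the default, so every subject gets a
#' score) or propagate to `NA` (`"complete_case"`).
#'
#' @param G A [genotype_matrix()].
#' @param selected Data frame of selected SNPs with columns `snp_id`,
#'   `effect_allele`, `other_allele` and optionally `raises_trait` (when
#'   `FALSE`, the risk allele is the other allele).
#' @param trait Trait label carried on the result.
#' @param missing_policy `"mean_impute"` or `"complete_case"`.
#' @param controls Optional subject subset defining the imputation reference
#'   frequency (default all subjects).
#' @param palindromic Palindromic-SNP policy passed to
#'   [align_risk_allele()].
#' @return An object of class `lipid_score`: list with `trait`, `snp_ids`,
#'   `risk_allele`, `score` (named numeric per subject), `n_snps`,
#'   `dropped` (unresolvable SNPs).
#' @export
build_lgs <- function(G, selected, trait = "score",
                      missing_policy = c("mean_impute", "complete_case"),
                      controls = NULL, palindromic = "exclude") {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(G, "genotype_matrix"), is.data.frame(selected))
  absent <- setdiff(selected$snp_id, G$snp_ids)
  if (length(absent))
    stop2("selected SNP(s) absent from genotypes: ",
          paste(absent, collapse = ", "))
  n <- length(G$subject_ids)
  total <- rep(0, n)
  n_miss_terms <- rep(0L, n)
  used <- character(); risk_used <- character(); dropped <- character()
  for (i in seq_len(nrow(selected))) {
    id <- selected$snp_id[i]
    raises <- if ("raises_trait" %in% names(selected))
      isTRUE(selected$raises_trait[i]) else TRUE
    risk <- if (raises) selected$effect_allele[i] else selected$other_allele[i]
    oth <- if (raises) selected$other_allele[i] else selected$effect_allele[i]
    d <- G$dosage[, id]
    ctrl_d <- if (is.null(controls)) d else d[controls]
    ori <- align_risk_allele(risk, oth, G$counted_allele[[id]],
                             G$other_allele[[id]], palindromic = palindromic,
                             counted_freq = mean(ctrl_d, na.rm = TRUE) / 2,
                             catalog_freq = selected$effect_freq[i] %||% NULL)
    if (ori == "unresolvable") {
      warn2("SNP ", id, " unresolvable against array alleles; dropped from ",
            trait, " score")
      dropped <- c(dropped, id)
      next
    }
    if (ori %in% c("flip", "strand_flip_and_flip")) d <- 2 - d
    if (anyNA(d)) {
      ref <- if (is.null(controls)) d else d[controls]
      fill <- mean(ref, na.rm = TRUE)       # = 2 x control risk-allele freq
      if (missing_policy == "mean_impute") {
        d[is.na(d)] <- fill
      } else {
        n_miss_terms <- n_miss_terms + is.na(d)
        d[is.na(d)] <- 0
      }
    }
    total <- total + d
    used <- c(used, id)
    risk_used <- c(risk_used, risk)
  }
  if (missing_policy == "complete_case") total[n_miss_terms > 0] <- NA_real_
  structure(list(
    trait = trait, snp_ids = used,
    risk_allele = stats::setNames(risk_used, used),
    score = stats::setNames(total, G$subject_ids),
    n_snps = length(used), dropped = dropped,
    missing_policy = missing_policy
  ), class = "lipid_score")
}

#' @export
print.lipid_score <- function(x, ...) {
  cat("<lipid_score> ", x$trait, ": ", x$n_snps, " SNPs, ",
      length(x$score), " subjects\n", sep = "")
  s <- x$score[!is.na(x$score)]
  cat(sprintf("  range %.1f-%.1f (max possible %d), mean %.2f +/- %.2f\n",
              min(s), max(s), 2L * x$n_snps, mean(s), stats::sd(s)))
  if (length(x$dropped))
    cat("  dropped (unresolvable):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
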