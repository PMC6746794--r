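#' Simulation configuration for synthetic MR case-control cohorts
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' Defaults encode the study design the analysis targets: 1336 cases and
#' 2744 controls; trait-specific instrument sets of 22 (TG), 36 (HDL),
#' 39 (LDL) and 49 (TC) SNPs with the TC set sharing SNPs with LDL and HDL;
#' scores explaining 10% of each lipid's variance; statin prescription driven
#' by LDL (confounding by indication); and a null causal effect of lipids on
#' colorectal cancer.
#'
#' @param seed Master seed; all stage-level streams derive from it.
#' @param n_cases,n_controls Case-control sample sizes.
#' @param snp_counts Named counts of score SNPs per trait
#'   (`TG`, `HDL`, `LDL`, `TC`).
#' @param tc_overlap Named counts `c(LDL = , HDL = )` of LDL and HDL SNPs
#'   shared by the TC score (the TC score is exempt from the pleiotropy
#'   restriction between LDL and HDL); the remainder of the TC set are
#'   TC-specific SNPs.
#' @param allele_freq_range Range the counted-allele frequencies are drawn
#'   from, inside (0, 1).
#' @param ld_decoy_rho Haplotype correlation used for same-region LD decoy
#'   pairs in the instrument catalog, in `[0, 1)`.
#' @param lipid_effects mg/dL change per risk allele for `TG`, `HDL`, `LDL`
#'   (equal across a trait's SNPs, matching the unweighted score).
#' @param lipid_means Population mean lipid levels (mg/dL) for `TG`, `HDL`,
#'   `LDL`.
#' @param target_r2 Fraction of each lipid's variance explained by its
#'   genetic score, in (0, 1).
#' @param tc_formula `"ldl_hdl"` (TC = LDL + HDL, the default) or
#'   `"friedewald"` (TC = LDL + HDL + 0.2 TG).
#' @param statin_model List: `intercept` (log-odds of regular statin use at
#'   mean LDL), `beta_ldl_sd` (log-OR of statin use per LDL standard
#'   deviation), `beta_tc_sd` (optional TC term).
#' @param outcome_model List: `baseline_risk` (sampling prevalence of the
#'   outcome in the simulated source population; a case-control design
#'   identifies odds ratios only, so this is a sampling device, not an
#'   incidence), `log_or_sd` (named causal log-ORs per lipid SD for TG, HDL,
#'   LDL, TC), `log_or_statin`, `log_or_male`, `log_or_age_sd`,
#'   `log_or_center` (vector over centers, recycled).
#' @param covariate_gen List of covariate-generation settings: `age_mean`,
#'   `age_sd`, `age_range`, `p_male`, `n_centers`, `education_probs`, and
#'   control-level prevalences for the lifestyle/drug covariates.
#' @param statin_name_probs Named probabilities over statin molecules used to
#'   label users.
#' @param missing_rate Fraction of genotype entries masked missing, `[0, 1)`.
#' @param n_population Source population size to simulate before case-control
#'   sampling; `NULL` (default) uses
#'   `3 * (n_cases + n_controls)`.
#' @param n_aim Number of ancestry-informative markers simulated for the
#'   genotype PCA.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 20260924L,
                       n_cases = 1336L,
                       n_controls = 2744L,
                       snp_counts = c(TG = 22L, HDL = 36L, LDL = 39L, TC = 49L),
                       tc_overlap = c(LDL = 16L, HDL = 16L),
                       allele_freq_range = c(0.1, 0.9),
                       ld_decoy_rho = 0.9,
                       lipid_effects = c(TG = 4, HDL = 1.5, LDL = 2.5),
                       lipid_means = c(TG = 120, HDL = 50, LDL = 130),
                       target_r2 = 0.10,
                       tc_formula = c("ldl_hdl", "friedewald"),
                       statin_model = list(intercept = -1.75, beta_ldl_sd = 0.55,
                                           beta_tc_sd = 0),
                       outcome_model = list(
                         baseline_risk = 0.18,
                         log_or_sd = c(TG = 0, HDL = 0, LDL = 0, TC = 0),
                         log_or_statin = 0,
                         log_or_male = 0.4,
                         log_or_age_sd = 0.35,
                         log_or_center = 0),
                       covariate_gen = list(
                         age_mean = 65, age_sd = 10, age_range = c(30, 90),
                         p_male = 0.55, n_centers = 5L,
                         education_probs = c(0.45, 0.35, 0.20),
                         prevalence = c(smoking = 0.56, alcohol = 0.16,
                                        diabetes = 0.14, hypertension = 0.38,
                                        whr_high = 0.68, obesity = 0.07,
                                        phys_act = 0.39, vegetables = 0.31,
                                        red_meat = 0.41, asa = 0.12,
                                        nsaid = 0.15, fam_crc = 0.12)),
                       statin_name_probs = c(simvastatin = 0.475,
                                             atorvastatin = 0.353,
                                             pravastatin = 0.066,
                                             fluvastatin = 0.040,
                                             rosuvastatin = 0.040,
                                             lovastatin = 0.026),
                       missing_rate = 0.01,
                       n_population = NULL,
                       n_aim = 40L) {
  tc_formula <- match.arg(tc_formula)
  stopifnot(is_count(n_cases), is_count(n_controls))
  # canonicalize vector-valued fields (YAML configs deliver them as lists)
  snp_counts <- unlist(snp_counts); tc_overlap <- unlist(tc_overlap)
  allele_freq_range <- unlist(allele_freq_range)
  lipid_effects <- unlist(lipid_effects); lipid_means <- unlist(lipid_means)
  statin_name_probs <- unlist(statin_name_probs)
  statin_model <- lapply(statin_model, unlist)
  outcome_model <- lapply(outcome_model, unlist)
  for (v in c("age_range", "education_probs", "prevalence"))
    if (!is.null(covariate_gen[[v]])) covariate_gen[[v]] <- unlist(covariate_gen[[v]])
  traits <- c("TG", "HDL", "LDL", "TC")
  if (!all(traits %in% names(snp_counts)) || any(snp_counts[traits] < 1))
    stop2("snp_counts must give positive counts for TG, HDL, LDL, TC")
  if (!all(c("LDL", "HDL") %in% names(tc_overlap)) || any(tc_overlap < 0))
    stop2("tc_overlap must give non-negative LDL and HDL counts")
  if (sum(tc_overlap[c("LDL", "HDL")]) > snp_counts[["TC"]])
    stop2("tc_overlap exceeds the TC SNP count")
  if (tc_overlap[["LDL"]] > snp_counts[["LDL"]] ||
      tc_overlap[["HDL"]] > snp_counts[["HDL"]])
    stop2("tc_overlap exceeds the LDL/HDL SNP counts")
  if (length(allele_freq_range) != 2 || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) <= 0)
    stop2("allele_freq_range must be an increasing pair inside (0, 1)")
  if (ld_decoy_rho < 0 || ld_decoy_rho >= 1) stop2("ld_decoy_rho must be in [0, 1)")
  if (!is_prob(target_r2)) stop2("target_r2 must be in (0, 1)")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must be in [0, 1)")
  if (!is_prob(outcome_model$baseline_risk))
    stop2("outcome_model$baseline_risk must be in (0, 1)")
  stopifnot(all(is.finite(unlist(statin_model))),
            all(is.finite(unlist(outcome_model))))
  p <- statin_name_probs / sum(statin_name_probs)
  unknown <- setdiff(names(p), rownames(statin_classes()))
  if (length(unknown)) stop2("unknown statin name(s): ", paste(unknown, collapse = ", "))
  structure(list(
    seed = as.integer(seed), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    snp_counts = snp_counts[traits], tc_overlap = tc_overlap[c("LDL", "HDL")],
    allele_freq_range = allele_freq_range, ld_decoy_rho = ld_decoy_rho,
    lipid_effects = lipid_effects, lipid_means = lipid_means,
    target_r2 = target_r2, tc_formula = tc_formula,
    statin_model = statin_model, outcome_model = outcome_model,
    covariate_gen = covariate_gen, statin_name_probs = p,
    missing_rate = missing_rate,
    n_population = if (!is.null(n_population)) as.integer(n_population),
    n_aim = as.integer(n_aim)
  ), class = "sim_config")
}

#' Pharmacologic classification of statins
#'
#' @return A data.frame keyed by molecule with columns `lipophilicity`
#'   (`lipophilic`: atorvastatin, fluvastatin, lovastatin, simvastatin;
#'   `hydrophilic`: pravastatin, rosuvastatin) and `potency` (`high`:
#'   atorvastatin, rosuvastatin; `low`: the rest).
#' @export
statin_classes <- function() {
  data.frame(
    lipophilicity = c(atorvastatin = "lipophilic", fluvastatin = "lipophilic",
                      lovastatin = "lipophilic", simvastatin = "lipophilic",
                      pravastatin = "hydrophilic", rosuvastatin = "hydrophilic"),
    potency = c(atorvastatin = "high", fluvastatin = "low", lovastatin = "low",
                simvastatin = "low", pravastatin = "low", rosuvastatin = "high"),
    stringsAsFactors = FALSE
  )
}
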