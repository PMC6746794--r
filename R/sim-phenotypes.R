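#' Simulate a lipid phenotype from genotypes at a fixed explained variance
#'
#' The genetic component is the sum of per-allele effects times risk-allele
#' dosage; Gaussian noise is then added with variance solved so that the
#' genetic component explains exactly `target_r2` of the total variance:
#' \eqn{\sigma^2 = Var(g)(1 - R^2)/R^2}. Because all SNPs of a trait carry
#' the same per-allele effect, the genetic component is proportional to the
#' unweighted allele score, so the regression R-squared of the lipid on the
#' score converges to `target_r2`; rescaling all effects leaves it unchanged.
#'
#' @param G A [genotype_matrix()].
#' @param config A [sim_config()] (provides `lipid_effects`, `lipid_means`
#'   and `target_r2`).
#' @param trait One of `"TG"`, `"HDL"`, `"LDL"` (TC is derived; see
#'   [compute_tc()]).
#' @param snp_ids Variants driving the trait (default: all variants of `G`).
#' @param flip Logical per selected variant: `TRUE` where the risk
#'   (lipid-raising) allele is the one *not* counted by `G`, so its dosage
#'   enters as `2 - d`.
#' @param null_sd Noise standard deviation used when all effects are zero
#'   (mg/dL).
#' @return Numeric vector of lipid values (mg/dL), named by subject.
#' @export
simulate_lipids <- function(G, config, trait = c("TG", "HDL", "LDL"),
                            snp_ids = NULL, flip = NULL, null_sd = 25) {
  trait <- match.arg(trait)
  stopifnot(inherits(G, "genotype_matrix"))
  if (!is_prob(config$target_r2)) stop2("target_r2 must be in (0, 1)")
  snp_ids <- snp_ids %||% G$snp_ids
  D <- G$dosage[, snp_ids, drop = FALSE]
  # mean-impute missing dosages for generation
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0)) D[is.na(D[, j]), j] <- mu[j]
  }
  if (!is.null(flip)) {
    flip <- rep_len(flip, ncol(D))
    D[, flip] <- 2 - D[, flip]
  }
  eff <- config$lipid_effects[[trait]]
  if (!is.finite(eff)) stop2("lipid effect for ", trait, " must be finite")
  g <- as.vector(D %*% rep(eff, ncol(D)))
  vg <- stats::var(g)
  n <- nrow(D)
  if (vg == 0) {
    lipid <- config$lipid_means[[trait]] + stats::rnorm(n, 0, null_sd)
  } else {
    sigma <- sqrt(vg * (1 - config$target_r2) / config$target_r2)
    lipid <- config$lipid_means[[trait]] + (g - mean(g)) + stats::rnorm(n, 0, sigma)
  }
  stats::setNames(lipid, G$subject_ids)
}

#' Derive total cholesterol from the simulated lipid fractions
#'
#' @param lipids Data frame or list with components `TG`, `HDL`, `LDL`.
#' @param config A [sim_config()]; `tc_formula = "ldl_hdl"` gives
#'   TC = LDL + HDL, `"friedewald"` gives TC = LDL + HDL + 0.2 TG.
#' @return Numeric vector of TC values.
#' @export
compute_tc <- function(lipids, config) {
  if (config$tc_formula == "friedewald")
    lipids$LDL + lipids$HDL + 0.2 * lipids$TG
  else
    lipids$LDL + lipids$HDL
}

#' Simulate study-design and lifestyle covariates
#'
#' @param n Number of subjects.
#' @param config A [sim_config()] (uses its `covariate_gen` block).
#' @return A data.frame with `age`, `sex`, `center`, `education` and the
#'   binary lifestyle/drug covariates, one row per subject.
#' @export
simulate_covariates <- function(n, config) {
  cg <- config$covariate_gen
  age <- round(stats::rnorm(n, cg$age_mean, cg$age_sd))
  age <- pmin(pmax(age, cg$age_range[1]), cg$age_range[2])
  out <- data.frame(
    age = age,
    sex = factor(ifelse(stats::runif(n) < cg$p_male, "male", "female"),
                 levels = c("female", "male")),
    center = factor(sample.int(cg$n_centers, n, replace = TRUE),
                    levels = seq_len(cg$n_centers),
                    labels = paste0("C", seq_len(cg$n_centers))),
    education = factor(sample(c("primary", "secondary", "university"), n,
                              replace = TRUE, prob = cg$education_probs),
                       levels = c("primary", "secondary", "university"))
  )
  for (v in names(cg$prevalence))
    out[[v]] <- as.integer(stats::runif(n) < cg$prevalence[[v]])
  out
}

#' Simulate statin exposure and case-control outcome with confounding by
#' indication
#'
#' Regular statin use is a Bernoulli draw whose log-odds increase with
#' standardized LDL (and optionally TC): the drug's indication. The outcome
#' is a Bernoulli draw from a logistic model in the standardized lipids,
#' statin use and design covariates. Because high LDL both triggers statin
#' prescription and (when its causal log-OR is non-zero) raises outcome
#' risk, a crude statin-outcome contrast is confounded by indication even
#' when the statin's own effect is zero. Subjects are then sampled without
#' replacement to exactly `n_cases` cases and `n_controls` controls.
#'
#' @param lipids Data frame with columns `TG`, `HDL`, `LDL`, `TC` for the
#'   source population.
#' @param covariates Data frame from [simulate_covariates()], same subjects.
#' @param config A [sim_config()].
#' @return A `CohortTable` data.frame with `subject_id`, `case`, the
#'   covariates, `statin` (regular use 0/1), `statin_name`,
#'   `statin_lipophilicity`, `statin_potency` and `location` (colon/rectum,
#'   cases only); attribute `"subject_index"` gives the sampled rows of the
#'   source population (cases first), attribute `"lipids"` their latent
#'   lipid values.
#' @export
simulate_statin_and_outcome <- function(lipids, covariates, config) {
  n <- nrow(covariates)
  stopifnot(length(lipids$LDL) == n)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  sm <- config$statin_model
  eta_statin <- sm$intercept + sm$beta_ldl_sd * z(lipids$LDL) +
    (sm$beta_tc_sd %||% 0) * z(lipids$TC)
  statin <- stats::rbinom(n, 1L, stats::plogis(eta_statin))

  om <- config$outcome_model
  lor <- om$log_or_sd[c("TG", "HDL", "LDL", "TC")]
  lor[is.na(lor)] <- 0
  centers <- rep_len(om$log_or_center, nlevels(covariates$center))
  eta <- stats::qlogis(om$baseline_risk) +
    lor[["TG"]] * z(lipids$TG) + lor[["HDL"]] * z(lipids$HDL) +
    lor[["LDL"]] * z(lipids$LDL) + lor[["TC"]] * z(lipids$TC) +
    om$log_or_statin * statin +
    om$log_or_male * (covariates$sex == "male") +
    om$log_or_age_sd * z(covariates$age) +
    centers[as.integer(covariates$center)]
  y <- stats::rbinom(n, 1L, stats::plogis(eta))

  cases <- which(y == 1L); controls <- which(y == 0L)
  if (length(cases) < config$n_cases) {
    need <- ceiling(1.1 * config$n_cases * n / max(length(cases), 1L))
    stop2("only ", length(cases), " cases simulated but ", config$n_cases,
          " requested; increase the source population to about ", need,
          " subjects")
  }
  if (length(controls) < config$n_controls)
    stop2("only ", length(controls), " controls simulated but ",
          config$n_controls, " requested; increase the source population")
  idx <- c(sample(cases, config$n_cases), sample(controls, config$n_controls))

  users <- which(statin[idx] == 1L)
  statin_name <- rep(NA_character_, length(idx))
  statin_name[users] <- sample(names(config$statin_name_probs), length(users),
                               replace = TRUE, prob = config$statin_name_probs)
  cls <- statin_classes()
  location <- rep(NA_character_, length(idx))
  is_case <- seq_along(idx) <= config$n_cases
  location[is_case] <- sample(c("colon", "rectum"), sum(is_case),
                              replace = TRUE, prob = c(0.78, 0.22))
  cohort <- data.frame(
    subject_id = rownames(covariates)[idx] %||% paste0("S", idx),
    case = as.integer(is_case),
    covariates[idx, , drop = FALSE],
    statin = statin[idx],
    statin_name = statin_name,
    statin_lipophilicity = ifelse(is.na(statin_name), NA_character_,
                                  cls[statin_name, "lipophilicity"]),
    statin_potency = ifelse(is.na(statin_name), NA_character_,
                            cls[statin_name, "potency"]),
    location = location,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(cohort, "subject_index") <- idx
  attr(cohort, "lipids") <- as.data.frame(lipids)[idx, , drop = FALSE]
  cohort
}

#' Simulate a complete synthetic MR case-control study
#'
#' Runs the full generator: instrument catalog with labeled decoys,
#' HWE-consistent genotypes with LD blocks for the catalog panel plus
#' ancestry-informative markers, lipid phenotypes at the configured explained
#' variance, statin exposure driven by LDL, outcome draw, and case-control
#' sampling to the configured sizes. Each stage uses its own random
#' sub-stream derived from `config$seed`, so the whole object is a
#' deterministic function of the configuration.
#'
#' @param config A [sim_config()].
#' @param decoys A [decoy_spec()] for the instrument catalog.
#' @return A list of class `lgs_sim` with elements `catalog`, `genotypes`
#'   (sampled subjects only), `cohort`, `lipids`, `aim_ids`, `truth` (per-
#'   trait risk-aligned instrument tables and stage seeds) and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), decoys = decoy_spec()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 5L)
  n_pop <- config$n_population %||% (3L * (config$n_cases + config$n_controls))

  set.seed(seeds[1])
  catalog <- make_instrument_catalog(config, decoys)
  panel <- attr(catalog, "panel")

  set.seed(seeds[2])
  G <- simulate_genotypes(
    n_pop, panel$freq, ld_blocks = panel_ld_blocks(panel),
    missing_rate = config$missing_rate, snp_ids = panel$snp_id,
    counted_allele = panel$counted_allele, other_allele = panel$other_allele,
    chrom = panel$chrom, pos = panel$pos)
  aim_ids <- character()
  if (config$n_aim > 0) {
    aim <- simulate_genotypes(n_pop, stats::runif(config$n_aim, 0.2, 0.8),
                              missing_rate = config$missing_rate,
                              snp_ids = paste0("aim", seq_len(config$n_aim)),
                              chrom = 23L, pos = seq_len(config$n_aim) * 10000L)
    aim_ids <- aim$snp_ids
    G <- genotype_matrix(cbind(G$dosage, aim$dosage),
                         c(G$counted_allele, aim$counted_allele),
                         c(G$other_allele, aim$other_allele),
                         chrom = c(G$chrom, aim$chrom), pos = c(G$pos, aim$pos))
  }

  # risk-aligned true instrument sets drive the lipid phenotypes
  truth_sets <- lapply(c(TG = "TG", HDL = "HDL", LDL = "LDL"), function(tr) {
    rows <- catalog[catalog$trait == tr & catalog$keep_truth, , drop = FALSE]
    risk <- ifelse(rows$raises_trait, rows$effect_allele, rows$other_allele)
    ori <- mapply(align_risk_allele, risk, rows$other_allele,
                  G$counted_allele[rows$snp_id], G$other_allele[rows$snp_id])
    data.frame(snp_id = rows$snp_id, risk_allele = risk,
               flip = ori %in% c("flip", "strand_flip_and_flip"),
               stringsAsFactors = FALSE)
  })

  set.seed(seeds[3])
  lipids <- list()
  for (tr in c("TG", "HDL", "LDL"))
    lipids[[tr]] <- simulate_lipids(G, config, tr,
                                    snp_ids = truth_sets[[tr]]$snp_id,
                                    flip = truth_sets[[tr]]$flip)
  lipids$TC <- compute_tc(lipids, config)
  lipids <- as.data.frame(lipids)
  rownames(lipids) <- G$subject_ids

  set.seed(seeds[4])
  covars <- simulate_covariates(n_pop, config)
  rownames(covars) <- G$subject_ids

  set.seed(seeds[5])
  cohort <- simulate_statin_and_outcome(lipids, covars, config)
  idx <- attr(cohort, "subject_index")

  structure(list(
    catalog = catalog,
    genotypes = G[idx, ],
    cohort = cohort,
    lipids = attr(cohort, "lipids"),
    aim_ids = aim_ids,
    truth = list(seeds = seeds, sets = truth_sets, n_population = n_pop),
    config = config
  ), class = "lgs_sim")
}

#' @export
print.lgs_sim <- function(x, ...) {
  cat("<lgs_sim> synthetic MR case-control study\n")
  cat("  ", sum(x$cohort$case), " cases / ", sum(1 - x$cohort$case),
      " controls; ", length(x$genotypes$snp_ids), " variants (",
      length(x$aim_ids), " AIM)\n", sep = "")
  cat("  catalog: ", nrow(x$catalog), " rows, ",
      sum(x$catalog$keep_truth), " true instrument entries\n", sep = "")
  invisible(x)
}
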