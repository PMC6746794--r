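test_that("statin exposure summary reproduces share arithmetic", {
  # cohort engineered to the headline usage pattern: 785 regular users of
  # whom 373 simvastatin and 277 atorvastatin, 535 controls / 250 cases
  names_users <- rep(c("simvastatin", "atorvastatin", "pravastatin",
                       "fluvastatin", "rosuvastatin", "lovastatin"),
                     c(373, 277, 55, 35, 30, 15))
  cohort <- data.frame(
    case = c(rep(0, 535), rep(1, 250), rep(0, 2209), rep(1, 1086)),
    statin = rep(c(1, 0), c(785, 3295)),
    statin_name = c(names_users, rep(NA, 3295)),
    stringsAsFactors = FALSE)
  ss <- statin_use_summary(cohort)
  expect_equal(ss$n_users, 785)
  expect_equal(unname(ss$users_by_case), c(535, 250))
  by_name <- ss$by_name
  expect_equal(by_name$pct[by_name$level == "simvastatin"], 47.5)
  expect_equal(by_name$pct[by_name$level == "atorvastatin"], 35.3)
  # class roll-up follows the pharmacologic map
  lip <- ss$by_lipophilicity
  expect_equal(lip$n[lip$level == "lipophilic"], 373 + 277 + 35 + 15)
  expect_equal(lip$n[lip$level == "hydrophilic"], 55 + 30)
  pot <- ss$by_potency
  expect_equal(pot$n[pot$level == "high"], 277 + 30)
})

test_that("statin classification map assigns lipophilicity and potency", {
  cls <- statin_classes()
  expect_equal(cls["rosuvastatin", "lipophilicity"], "hydrophilic")
  expect_equal(cls["rosuvastatin", "potency"], "high")
  expect_equal(cls["simvastatin", "lipophilicity"], "lipophilic")
  expect_equal(cls["simvastatin", "potency"], "low")
  expect_setequal(rownames(cls)[cls$lipophilicity == "lipophilic"],
                  c("atorvastatin", "fluvastatin", "lovastatin",
                    "simvastatin"))
  expect_setequal(rownames(cls)[cls$potency == "low"],
                  c("fluvastatin", "lovastatin", "pravastatin",
                    "simvastatin"))
})

test_that("risk-factor table reports null factors near OR 1 and flags degenerate ones", {
  set.seed(81)
  n <- 3000
  cohort <- data.frame(
    case = rbinom(n, 1, 0.35),
    age = round(rnorm(n, 65, 8)),
    sex = factor(sample(c("female", "male"), n, TRUE)),
    center = factor(sample(paste0("C", 1:3), n, TRUE)),
    education = factor(sample(c("primary", "secondary"), n, TRUE)),
    nullfac = rbinom(n, 1, 0.3),
    allon = 1L)
  X <- build_design_matrix(cohort, design_spec(interactions = character()))
  tab <- covariate_association_table(cohort, c("nullfac", "allon"), X)
  r <- tab[tab$factor == "nullfac", ]
  expect_gt(r$ci_hi_crude, 1)
  expect_lt(r$ci_lo_crude, 1)
  expect_equal(r$or_crude, 1, tolerance = 0.25)
  expect_true(tab$degenerate[tab$factor == "allon"])
  expect_error(covariate_association_table(cohort, "ghost", X), "ghost")
})

test_that("adjustment moves a confounded factor estimate toward its true null", {
  set.seed(82)
  n <- 6000
  u <- rnorm(n)                      # common cause
  factorx <- rbinom(n, 1, plogis(-1 + 1.2 * u))
  y <- rbinom(n, 1, plogis(-1 + 1.0 * u))   # factor has zero direct effect
  cohort <- data.frame(case = y, factorx = factorx, u = u,
                       age = rnorm(n, 60, 5))
  X <- build_design_matrix(cohort, design_spec(covariates = "age",
                                               interactions = character()))
  tab <- covariate_association_table(cohort, "factorx", X,
                                     confounder_matrix = cbind(u = u))
  expect_gt(tab$or_crude, 1.2)        # confounding inflates the crude OR
  expect_lt(abs(log(tab$or_adj)), abs(log(tab$or_crude)))
  expect_equal(tab$or_adj, 1, tolerance = 0.15)
})

test_that("statin subgroup analysis contrasts classes against non-users", {
  set.seed(83)
  cfg <- small_config(seed = 91L, n_cases = 500L, n_controls = 1000L,
                      outcome_model = list(baseline_risk = 0.25,
                                           log_or_sd = c(TG = 0, HDL = 0,
                                                         LDL = 0, TC = 0),
                                           log_or_statin = -0.25,
                                           log_or_male = 0.3,
                                           log_or_age_sd = 0.3,
                                           log_or_center = 0))
  sim <- simulate_cohort(cfg)
  X <- build_design_matrix(sim$cohort, design_spec(interactions = character()))
  res <- statin_subgroup_analysis(sim$cohort, X)
  expect_true(all(c("lipophilic", "hydrophilic") %in%
                    res$lipophilicity$subgroup) ||
                nrow(res$lipophilicity) >= 1)
  expect_setequal(res$by_sex$subgroup, c("female", "male"))
  expect_true(is.finite(attr(res$by_sex, "interaction_p")))
  expect_setequal(res$by_location$subgroup, c("colon", "rectum"))
  # location rows compare each case location against all controls
  expect_equal(res$by_location$n_controls,
               rep(sum(sim$cohort$case == 0 & sim$cohort$statin == 1), 2))
})

test_that("a class with no users is suppressed with a note", {
  set.seed(84)
  n <- 800
  cohort <- data.frame(
    case = rbinom(n, 1, 0.4),
    age = rnorm(n, 60, 8),
    sex = factor(sample(c("female", "male"), n, TRUE)),
    statin = rbinom(n, 1, 0.2))
  cohort$statin_name <- ifelse(cohort$statin == 1, "simvastatin", NA)
  cohort$statin_lipophilicity <- ifelse(cohort$statin == 1, "lipophilic", NA)
  cohort$statin_potency <- ifelse(cohort$statin == 1, "low", NA)
  X <- build_design_matrix(cohort, design_spec(covariates = c("age", "sex"),
                                               interactions = character()))
  res <- statin_subgroup_analysis(cohort, X)
  expect_equal(res$lipophilicity$subgroup, "lipophilic")
  expect_false("hydrophilic" %in% res$lipophilicity$subgroup)
})

test_that("statin effect recovery: protective log-OR -0.25 at large n", {
  set.seed(85)
  cfg <- small_config(seed = 92L, n_cases = 2000L, n_controls = 4000L,
                      statin_model = list(intercept = -1.2, beta_ldl_sd = 0),
                      outcome_model = list(baseline_risk = 0.3,
                                           log_or_sd = c(TG = 0, HDL = 0,
                                                         LDL = 0, TC = 0),
                                           log_or_statin = -0.25,
                                           log_or_male = 0,
                                           log_or_age_sd = 0,
                                           log_or_center = 0))
  sim <- simulate_cohort(cfg)
  fit <- fit_logistic(sim$cohort$case, cbind(statin = sim$cohort$statin))
  r <- fit[fit$term == "statin", ]
  expect_equal(r$or, exp(-0.25), tolerance = 0.12)
  expect_true(r$ci_lo < exp(-0.25) && exp(-0.25) < r$ci_hi)
})

test_that("allele-count bins yield a flat dose-response when statin ignores the score", {
  set.seed(86)
  n <- 8000
  s <- rbinom(n, 78, 0.5)
  statin <- rbinom(n, 1, 0.2)
  res <- suppressMessages(or_by_allele_count(s, statin, bin_width = 3))
  expect_s3_class(res, "allele_bin_or")
  expect_equal(res$bins$or[res$bins$bin == res$reference], 1)
  expect_lt(max(abs(log(res$bins$or))), 0.6)
  expect_lt(abs(res$trend[["midpoint"]]), 0.05)
  expect_equal(res$per_allele$or, 1, tolerance = 0.05)
  # reference bin contains the median
  med <- median(s)
  ref_row <- res$bins[res$bins$bin == res$reference, ]
  expect_lt(abs(ref_row$midpoint - med), 3)
})

test_that("per-allele statin OR is recovered and reported as percent increase", {
  set.seed(87)
  n <- 20000
  s <- rbinom(n, 78, 0.5)
  statin <- rbinom(n, 1, plogis(-1.7 + log(1.08) * (s - mean(s))))
  res <- suppressMessages(or_by_allele_count(s, statin, bin_width = 3))
  pa <- res$per_allele
  expect_true(pa$ci_lo < 1.08 && 1.08 < pa$ci_hi)
  expect_equal(pa$percent_increase, 100 * (pa$or - 1))
  expect_equal(pa$percent_increase, 8, tolerance = 2)
  # the bin ORs rise with allele count: positive fitted trend
  expect_gt(res$trend[["midpoint"]], 0)
})
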