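test_that("independent genotypes at freq 0.5 sit at Hardy-Weinberg proportions", {
  set.seed(11)
  G <- simulate_genotypes(10000, rep(0.5, 3))
  for (j in 1:3) {
    cnt <- tabulate(G$dosage[, j] + 1L, nbins = 3L)
    h <- hwe_test(cnt)
    expect_gt(h$p, 1e-3)
    expect_equal(cnt / 10000, c(0.25, 0.5, 0.25), tolerance = 0.03)
  }
})

test_that("LD blocks produce prunable dosage correlation and HWE margins", {
  set.seed(12)
  G <- simulate_genotypes(10000, c(0.4, 0.4),
                          ld_blocks = list(list(size = 2, rho = 0.9)))
  r2 <- compute_ld_r2(G, "rs1", "rs2")
  expect_gt(r2, 0.2)
  expect_equal(r2, 0.81, tolerance = 0.08)
  for (j in 1:2) expect_gt(hwe_test(tabulate(G$dosage[, j] + 1L, 3L))$p, 1e-3)
  # blocks with rho 0 leave variants uncorrelated
  G0 <- simulate_genotypes(10000, c(0.4, 0.4),
                           ld_blocks = list(list(size = 2, rho = 0)))
  expect_lt(compute_ld_r2(G0, "rs1", "rs2"), 0.01)
})

test_that("genotype simulator validates its block specification", {
  expect_error(simulate_genotypes(10, c(0.5, 0.5),
                                  ld_blocks = list(list(size = 0, rho = 0))),
               "positive")
  expect_error(simulate_genotypes(10, c(0.5, 0.5),
                                  ld_blocks = list(list(size = 2, rho = 1))),
               "\\[0, 1\\)")
  expect_error(simulate_genotypes(10, c(0.5, 0.5),
                                  ld_blocks = list(list(size = 1, rho = 0))),
               "sum")
  expect_error(simulate_genotypes(10, 0.5, missing_rate = 1), "missing_rate")
})

test_that("missingness mask hits the requested rate", {
  set.seed(13)
  G <- simulate_genotypes(5000, rep(0.3, 10), missing_rate = 0.02)
  frac <- mean(is.na(G$dosage))
  se <- sqrt(0.02 * 0.98 / 50000)
  expect_lt(abs(frac - 0.02), 4 * se)
})

test_that("lipid generator hits the target explained variance", {
  set.seed(14)
  cfg <- small_config()
  G <- simulate_genotypes(20000, runif(12, 0.1, 0.9))
  lip <- simulate_lipids(G, cfg, "LDL")
  score <- rowSums(G$dosage)
  r2 <- summary(lm(lip ~ score))$r.squared
  expect_lt(abs(r2 - 0.10), 0.01)
  # scaling equivariance: doubling per-allele effects changes nothing
  cfg2 <- small_config()
  cfg2$lipid_effects["LDL"] <- 2 * cfg$lipid_effects["LDL"]
  set.seed(14)
  G2 <- simulate_genotypes(20000, runif(12, 0.1, 0.9))
  lip2 <- simulate_lipids(G2, cfg2, "LDL")
  r2b <- summary(lm(lip2 ~ rowSums(G2$dosage)))$r.squared
  expect_lt(abs(r2b - r2), 0.01)
})

test_that("zero lipid effects give pure noise and TC follows its formula", {
  set.seed(15)
  cfg <- small_config()
  cfg$lipid_effects["TG"] <- 0
  G <- simulate_genotypes(5000, rep(0.5, 6))
  lip <- simulate_lipids(G, cfg, "TG")
  expect_lt(summary(lm(lip ~ rowSums(G$dosage)))$r.squared, 0.005)
  lips <- list(TG = c(100, 200), HDL = c(50, 60), LDL = c(120, 130))
  expect_equal(compute_tc(lips, cfg), c(170, 190))
  cfg_f <- small_config(tc_formula = "friedewald")
  expect_equal(compute_tc(lips, cfg_f), c(170 + 20, 190 + 40))
})

test_that("statin use is independent of lipids when its indication term is zero", {
  set.seed(16)
  cfg <- small_config(n_cases = 400L, n_controls = 800L,
                      statin_model = list(intercept = -1.5, beta_ldl_sd = 0))
  sim <- simulate_cohort(cfg)
  ldl_q <- cut(sim$lipids$LDL, stats::quantile(sim$lipids$LDL, 0:4 / 4),
               include.lowest = TRUE)
  p <- suppressWarnings(chisq.test(table(ldl_q, sim$cohort$statin))$p.value)
  expect_gt(p, 0.001)
})

test_that("case-control sampling returns the exact configured sizes", {
  set.seed(17)
  sim <- simulate_cohort(small_config())
  expect_equal(sum(sim$cohort$case), 150)
  expect_equal(sum(1 - sim$cohort$case), 300)
  expect_equal(nrow(sim$genotypes$dosage), 450)
  # statin class defined only for users
  users <- sim$cohort$statin == 1
  expect_true(all(!is.na(sim$cohort$statin_name[users])))
  expect_true(all(is.na(sim$cohort$statin_name[!users])))
})

test_that("an undersized source population is reported with the size needed", {
  cfg <- small_config(n_cases = 400L, n_controls = 100L, n_population = 500L)
  expect_error(simulate_cohort(cfg), "population")
})

test_that("the full simulation is a deterministic function of its seed", {
  a <- simulate_cohort(small_config(seed = 123L))
  b <- simulate_cohort(small_config(seed = 123L))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$lipids, b$lipids)
  c <- simulate_cohort(small_config(seed = 124L))
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})

test_that("catalog decoys carry construction-time ground-truth labels", {
  set.seed(18)
  cfg <- small_config()
  # no decoys: every row is a keeper
  cat0 <- make_instrument_catalog(cfg, decoy_spec(0L, 0L, 0L, 0L, 0L, 0L,
                                                  tri_trait = FALSE))
  expect_true(all(cat0$keep_truth))
  expect_equal(sum(cat0$trait == "TC"), 8)
  # with decoys: one labelled row per violation class
  cat1 <- make_instrument_catalog(cfg, decoy_spec(2L, 2L, 2L, 2L, 2L, 2L,
                                                  tri_trait = TRUE))
  reasons <- table(cat1$drop_reason_truth)
  expect_equal(unname(reasons["subthreshold_p"]), 2)
  expect_equal(unname(reasons["population"]), 2)
  expect_equal(unname(reasons["no_effect_allele"]), 2)
  expect_equal(unname(reasons["ld_pruned"]), 2)
  expect_equal(unname(reasons["excluded_trait"]), 2)
  # pleiotropic decoys contribute two rows each, the tri-trait SNP three
  expect_equal(unname(reasons["pleiotropic"]), 2 * 2 + 3)
  tri <- cat1[!cat1$keep_truth & cat1$drop_reason_truth == "pleiotropic", ]
  tri_id <- names(which(table(tri$snp_id) == 3))
  expect_length(tri_id, 1)
  expect_setequal(tri$trait[tri$snp_id == tri_id], c("TG", "HDL", "LDL"))
  expect_error(decoy_spec(subthreshold_p = -1), "non-negative")
})
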