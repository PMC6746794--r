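test_that("HWE chi-square matches hand-computed values", {
  h0 <- hwe_test(c(25, 50, 25))
  expect_equal(h0$chisq, 0)
  expect_equal(h0$p, 1)
  # all heterozygous: expected (25, 50, 25) per 100, chi2 = 25 + 50 + 25
  h1 <- hwe_test(c(0, 100, 0))
  expect_equal(h1$chisq, 100)
  expect_true(h1$deviation)
  # hand-computed general case
  cnt <- c(30, 40, 30)
  p_hat <- (2 * 30 + 40) / 200
  e <- 100 * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  expect_equal(hwe_test(cnt)$chisq, sum((cnt - e)^2 / e))
  mono <- hwe_test(c(50, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)
  expect_error(hwe_test(c(0, 0, 0)), "positive")
})

test_that("HWE p-values are uniform under the null", {
  set.seed(61)
  ps <- replicate(300, {
    p <- runif(1, 0.2, 0.8)
    g <- stats::rbinom(500, 2, p)
    hwe_test(tabulate(g + 1L, 3L))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("logistic ML reproduces the 2x2 cross-product odds ratio", {
  # 20 exposed cases, 10 unexposed cases, 10 exposed controls, 20 unexposed
  y <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  x <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  fit <- fit_logistic(y, cbind(exposure = x))
  or <- fit$or[fit$term == "exposure"]
  expect_equal(or, 4.0, tolerance = 1e-6)
  # invariant on random tables
  set.seed(62)
  for (i in 1:10) {
    n <- matrix(sample(5:50, 4), 2)
    y2 <- rep(c(1, 1, 0, 0), n)
    x2 <- rep(c(1, 0, 1, 0), n)
    f2 <- fit_logistic(y2, cbind(x = x2))
    expect_equal(f2$or[f2$term == "x"], (n[1] * n[4]) / (n[2] * n[3]),
                 tolerance = 1e-6)
  }
})

test_that("logistic estimates and Wald errors agree with stats::glm", {
  set.seed(63)
  n <- 500
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, "a"] - 0.4 * X[, "b"]))
  mine <- fit_logistic(y, X)
  ref <- glm(y ~ a + b, data = data.frame(y, X), family = binomial())
  expect_equal(mine$beta, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(mine$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(mine$or, exp(mine$beta))
  expect_true(all(mine$ci_lo < mine$or & mine$or < mine$ci_hi))
})

test_that("degenerate designs are reported: rank deficiency and separation", {
  set.seed(64)
  x <- rnorm(100)
  y <- rbinom(100, 1, 0.5)
  expect_error(fit_logistic(y, cbind(a = x, b = x)), "rank deficient")
  expect_error(fit_logistic(rep(1, 50), cbind(x = rnorm(50))), "constant")
  ysep <- as.numeric(x > 0)
  expect_warning(fsep <- fit_logistic(ysep, cbind(x = x)), "separation")
  expect_true(any(fsep$separation))
  expect_true(all(is.na(fsep$beta[fsep$separation])))
})

test_that("large-sample null odds ratio converges to 1", {
  set.seed(65)
  x <- rnorm(20000)
  y <- rbinom(20000, 1, 0.3)
  fit <- fit_logistic(y, cbind(x = x))
  expect_equal(fit$or[fit$term == "x"], 1, tolerance = 0.05)
})

test_that("genotype PCs separate structured populations and respect symmetry", {
  set.seed(66)
  n <- 200; m <- 60
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.2, 0.7)
  d <- sapply(seq_len(m), function(j)
    rbinom(n, 2, ifelse(pop == 1, pmin(p1[j] + 0.2, 0.95), p1[j])))
  G <- toy_genotypes(d)
  pcs <- genotype_pca(G)
  expect_equal(dim(pcs), c(n, 3))
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  expect_equal(sum(pcs[, 1]^2), 1, tolerance = 1e-8)
  # duplicated subjects get identical coordinates
  d2 <- rbind(d[1:50, ], d[1:50, ])
  pcs2 <- genotype_pca(toy_genotypes(d2))
  expect_equal(unname(pcs2[1:50, ]), unname(pcs2[51:100, ]), tolerance = 1e-8)
  # homogeneous population: leading eigenvalue close to the bulk
  dh <- sapply(runif(40, 0.2, 0.8), function(p) rbinom(500, 2, p))
  ev <- attr(genotype_pca(toy_genotypes(dh)), "eigenvalues")
  expect_lt(ev[1] / mean(ev), 2)
  expect_error(genotype_pca(toy_genotypes(d[1:2, ])), "3 subjects")
})

test_that("OR_10 scaling, location invariance and orientation antisymmetry hold", {
  set.seed(67)
  n <- 2000
  s <- rbinom(n, 44, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.03 * s))
  f10 <- fit_logistic(y, cbind(x = s / 10))
  f1 <- fit_logistic(y, cbind(x = s))
  expect_equal(f10$beta[f10$term == "x"], 10 * f1$beta[f1$term == "x"],
               tolerance = 1e-8)
  # shifting the score leaves the slope untouched
  fsh <- fit_logistic(y, cbind(x = (s + 7) / 10))
  expect_equal(fsh$beta[fsh$term == "x"], f10$beta[f10$term == "x"],
               tolerance = 1e-8)
  # reversing risk-allele orientation (score -> 2m - score) negates beta
  frev <- fit_logistic(y, cbind(x = (88 - s) / 10))
  expect_equal(frev$beta[frev$term == "x"], -f10$beta[f10$term == "x"],
               tolerance = 1e-8)
})

test_that("the MR fit returns OR_10 with strata and a Wald interaction test", {
  set.seed(68)
  sim <- simulate_cohort(small_config(seed = 71L, n_cases = 400L,
                                      n_controls = 800L))
  controls <- which(sim$cohort$case == 0)
  rep_ <- filter_catalog(sim$catalog, sim$genotypes, controls_mask = controls)
  sel <- sim$catalog[sim$catalog$trait == "LDL" &
                       sim$catalog$snp_id %in% rep_$kept$LDL, ]
  s <- build_lgs(sim$genotypes, sel, trait = "LDL", controls = controls)
  X <- build_design_matrix(sim$cohort, design_spec(interactions = character()))
  mr <- score_crc_association(s, sim$cohort, design = X, strata = "statin")
  expect_s3_class(mr, "lgs_mr")
  expect_equal(mr$overall$or, exp(mr$overall$beta))
  expect_named(mr$strata, c("statin=0", "statin=1"))
  expect_true(is.finite(mr$interaction_p))
  expect_equal(unname(coef(mr)), mr$overall$beta)
  ci <- confint(mr)
  expect_lt(ci[1], mr$overall$beta)
  expect_gt(ci[2], mr$overall$beta)
  expect_error(score_crc_association(s, sim$cohort, X, strata = "nope"),
               "nope")
  expect_output(print(mr), "OR per 10 risk alleles")
})

test_that("group comparison matches the linear-model p-value and t.test forms", {
  set.seed(69)
  x <- rnorm(100)
  g <- rep(0:1, 50)
  cmp <- compare_mean_alleles(x, g)
  lmp <- summary(lm(x ~ g))$coefficients["g", 4]
  expect_equal(cmp$p, lmp, tolerance = 1e-12)
  wt <- t.test(x[g == 0], x[g == 1])
  expect_equal(compare_mean_alleles(x, g, welch = TRUE)$p, wt$p.value)
  same <- compare_mean_alleles(c(x, x), rep(0:1, each = 100))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_error(compare_mean_alleles(x, rep(0, 100)), "two")
  # a half-sd shift at n = 200 per arm is reliably detected
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(200); b <- rnorm(200, 0.5)
    expect_lt(compare_mean_alleles(c(a, b), rep(0:1, each = 200))$p, 0.01)
  }
})

test_that("per-SNP scan applies trait-wise Bonferroni thresholds", {
  set.seed(70)
  sim <- simulate_cohort(small_config(seed = 72L, n_cases = 300L,
                                      n_controls = 600L))
  controls <- which(sim$cohort$case == 0)
  rep_ <- filter_catalog(sim$catalog, sim$genotypes, controls_mask = controls)
  scan <- per_snp_scan(sim$genotypes, sim$cohort, NULL, rep_$kept)
  expect_equal(unname(scan$thresholds["LDL"]), 0.05 / length(rep_$kept$LDL))
  expect_equal(unname(scan$thresholds), 0.05 / lengths(rep_$kept),
               ignore_attr = TRUE)
  # a 22-SNP score gives the conventional threshold
  expect_equal(0.05 / 22, per_snp_scan(sim$genotypes, sim$cohort, NULL,
    list(TG = rep(rep_$kept$LDL, length.out = 22)))$thresholds[["TG"]],
    tolerance = 1e-12)
  # null simulation: no SNP should clear its Bonferroni bar
  expect_equal(sum(scan$results$below_bonferroni), 0)
  expect_lt(abs(scan$effect_summary$mean_beta[
    scan$effect_summary$trait == "LDL"]), 0.5)
})

test_that("a monomorphic SNP is skipped in the scan with a message", {
  d <- cbind(rs1 = rbinom(200, 2, 0.5), rs2 = rep(2L, 200))
  G <- toy_genotypes(d)
  cohort <- data.frame(case = rbinom(200, 1, 0.4))
  expect_message(scan <- per_snp_scan(G, cohort, NULL,
                                      list(X = c("rs1", "rs2"))),
                 "monomorphic")
  expect_equal(scan$results$snp_id, "rs1")
})
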