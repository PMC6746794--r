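# Shared fixtures and independent oracles used across the suite.

# small, fast simulation configuration (same structure as the full study,
# scaled down)
small_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_cases = 150L, n_controls = 300L,
         snp_counts = c(TG = 5L, HDL = 6L, LDL = 7L, TC = 8L),
         tc_overlap = c(LDL = 3L, HDL = 3L), n_aim = 10L,
         missing_rate = 0.01),
    list(...))
  do.call(sim_config, args)
}

# hand-built genotype matrix from explicit dosages
toy_genotypes <- function(dosage, counted = "A", other = "G", ...) {
  genotype_matrix(as.matrix(dosage), counted, other, ...)
}

# independent LD-pruning oracle: repeatedly keep the globally most
# significant remaining candidate and delete every same-region candidate in
# LD with it (removal formulation, distinct from the package's keep-check
# formulation)
prune_oracle <- function(cand, r2mat, r2_threshold = 0.2, region_mb = 1) {
  remaining <- order(cand$pvalue, cand$pos, cand$snp_id)
  kept <- integer()
  while (length(remaining)) {
    i <- remaining[1]
    kept <- c(kept, i)
    remaining <- remaining[-1]
    drop <- vapply(remaining, function(j) {
      same_region <- cand$chrom[j] == cand$chrom[i] &&
        abs(cand$pos[j] - cand$pos[i]) <= region_mb * 1e6
      same_region && !is.na(r2mat[i, j]) && r2mat[i, j] > r2_threshold
    }, TRUE)
    remaining <- remaining[!drop]
  }
  sort(cand$snp_id[kept])
}

# Monte-Carlo oracle for binary-outcome allele-score MR power: simulate the
# model the analytic formula assumes — a standardized score explaining R2xz
# of a normal exposure and a binary outcome whose probability is linear in
# the exposure with attenuated risk difference b = K(OR/(1+K(OR-1))-1) per
# exposure SD — estimate the causal effect by the instrumental-variable
# (Wald ratio) estimator, and count rejections of the 1-df test at the
# formula's sampling variance v = (K(1-K)-b^2)/(N R2xz). This verifies the
# formula against its own generative model and test; robustness to a
# logistic data-generating process is a separate question (see the methods
# vignette).
mc_power <- function(N, K, R2xz, OR, alpha = 0.05, reps = 4000) {
  b <- K * (OR / (1 + K * (OR - 1)) - 1)
  v <- (K * (1 - K) - b^2) / (N * R2xz)
  crit <- stats::qnorm(1 - alpha / 2)
  hits <- 0L
  for (r in seq_len(reps)) {
    z <- stats::rnorm(N)
    x <- sqrt(R2xz) * z + sqrt(1 - R2xz) * stats::rnorm(N)
    p <- pmin(pmax(K + b * x, 1e-6), 1 - 1e-6)
    y <- stats::rbinom(N, 1L, p)
    zc <- z - mean(z); xc <- x - mean(x); yc <- y - mean(y)
    bhat <- sum(zc * yc) / sum(zc * xc)
    if (abs(bhat) / sqrt(v) > crit) hits <- hits + 1L
  }
  hits / reps
}

# one full null-pipeline replicate at reduced SNP counts: simulate the
# study, select instruments, build the LDL score and return the Wald p of
# the OR_10 test (no PCs, main-effect design only, for speed)
null_pipeline_pvalue <- function(seed, n_cases = 1336L, n_controls = 2744L,
                                 trait = "LDL") {
  cfg <- sim_config(seed = seed, n_cases = n_cases, n_controls = n_controls,
                    snp_counts = c(TG = 6L, HDL = 6L, LDL = 6L, TC = 8L),
                    tc_overlap = c(LDL = 2L, HDL = 2L), n_aim = 0L,
                    missing_rate = 0)
  sim <- simulate_cohort(cfg, decoy_spec(0L, 0L, 0L, 0L, 0L, 0L,
                                         tri_trait = FALSE))
  controls <- which(sim$cohort$case == 0)
  rep_ <- filter_catalog(sim$catalog, sim$genotypes, controls_mask = controls)
  sel <- sim$catalog[sim$catalog$trait == trait &
                       sim$catalog$snp_id %in% rep_$kept[[trait]], ]
  s <- build_lgs(sim$genotypes, sel, trait = trait, controls = controls)
  X <- build_design_matrix(sim$cohort,
                           design_spec(interactions = character()))
  mr <- score_crc_association(s, sim$cohort, design = X)
  mr$overall$p
}
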