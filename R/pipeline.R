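#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()] with blocks `simulation`
#' (arguments of [sim_config()] plus `decoys`), `selection` (arguments of
#' [filter_catalog()]), `association` (design/confounder options) and
#' `power` (arguments of [mrnd_binary_power()] / [min_detectable_or()]).
#' Any block can be overridden by a user list or a YAML file.
#'
#' @param seed Master seed stored in the simulation block.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 20260924L) {
  list(
    simulation = list(seed = seed, decoys = list()),
    selection = list(p_threshold = 5e-8, population = "Caucasian",
                     r2_threshold = 0.2, region_mb = 1,
                     excluded_traits = c("alcohol", "BMI", "diabetes",
                                         "inflammation")),
    association = list(use_pcs = TRUE, missing_policy = "mean_impute",
                       strata = "statin"),
    power = list(alpha = 0.05, target_power = 0.80, or = 1.33, r2 = 0.10)
  )
}

validate_config <- function(config) {
  need <- c("simulation", "selection", "association", "power")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop2("configuration lacks block(s): ", paste(missing, collapse = ", "))
  config
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes simulate -> select -> score -> associate -> power in order and
#' writes every result to `out_dir`: catalog and genotypes (additive text
#' and VCF), cohort CSV, selection report, score CSV, risk-factor and statin
#' tables, per-trait MR association table, power JSON, and a run manifest
#' with the configuration, seeds and MD5 hash of every output file. The
#' same configuration and seed reproduce byte-identical outputs.
#'
#' @param config Nested configuration list (see [default_config()]) or path
#'   to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return The manifest list, invisibly. Results are also returned in the
#'   `"results"` attribute.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$simulation$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("stage '", name, "' failed: ", conditionMessage(e)))
  }

  sim_args <- config$simulation
  decoys <- do.call(decoy_spec, sim_args$decoys %||% list())
  sim_args$decoys <- NULL
  cfg <- do.call(sim_config, sim_args)
  sim <- stage("simulate", simulate_cohort(cfg, decoys))

  write_catalog(sim$catalog, file.path(out_dir, "catalog.tsv"))
  write_genotypes_additive(sim$genotypes, file.path(out_dir, "genotypes.txt"))
  write_genotypes_vcf(sim$genotypes, file.path(out_dir, "genotypes.vcf"))
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)

  sel_args <- config$selection
  controls <- which(sim$cohort$case == 0)
  report <- stage("select", do.call(filter_catalog, c(
    list(catalog = sim$catalog, genotypes = sim$genotypes,
         controls_mask = controls), sel_args)))
  write_selection_report(report, out_dir)

  hwe <- stage("hwe", hwe_scan(sim$genotypes, subset_mask = controls))
  write_result_tsv(hwe, file.path(out_dir, "hwe_controls.tsv"))

  scores <- stage("score", {
    out <- list()
    for (tr in names(report$kept)) {
      sel <- sim$catalog[sim$catalog$trait == tr &
                           sim$catalog$snp_id %in% report$kept[[tr]], ,
                         drop = FALSE]
      out[[tr]] <- build_lgs(sim$genotypes, sel, trait = tr,
                             missing_policy = config$association$missing_policy,
                             controls = controls)
    }
    out
  })
  score_df <- data.frame(subject_id = sim$genotypes$subject_ids,
                         lapply(scores, function(s) unname(s$score)))
  utils::write.csv(score_df, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)

  assoc <- stage("associate", {
    pcs <- if (isTRUE(config$association$use_pcs) && length(sim$aim_ids) >= 3)
      genotype_pca(sim$genotypes, markers = sim$aim_ids)
    spec <- design_spec()
    X <- build_design_matrix(sim$cohort, spec, pcs = pcs)
    conf <- as.matrix(sim$cohort[, intersect(spec$confounders,
                                             names(sim$cohort)),
                                 drop = FALSE])
    mr <- lapply(scores, function(s)
      score_crc_association(s, sim$cohort, design = X,
                            strata = config$association$strata))
    tab3 <- do.call(rbind, lapply(names(mr), function(tr) {
      m <- mr[[tr]]
      data.frame(trait = tr,
                 mean_controls = m$by_group$groups$mean[1],
                 sd_controls = m$by_group$groups$sd[1],
                 mean_cases = m$by_group$groups$mean[2],
                 sd_cases = m$by_group$groups$sd[2],
                 or_10 = m$overall$or, ci_lo = m$overall$ci_lo,
                 ci_hi = m$overall$ci_hi, p = m$overall$p,
                 interaction_p = m$interaction_p, stringsAsFactors = FALSE)
    }))
    factors <- intersect(c("fam_crc", "smoking", "alcohol", "diabetes",
                           "hypertension", "whr_high", "obesity", "phys_act",
                           "vegetables", "red_meat", "asa", "nsaid",
                           "statin"), names(sim$cohort))
    tab1 <- covariate_association_table(sim$cohort, factors, X,
                                        confounder_matrix = conf)
    tab2 <- statin_subgroup_analysis(sim$cohort, X, confounder_matrix = conf)
    scan <- per_snp_scan(sim$genotypes, sim$cohort, X, report$kept)
    list(mr = mr, tab1 = tab1, tab2 = tab2, tab3 = tab3, scan = scan,
         statins = statin_use_summary(sim$cohort))
  })
  write_result_tsv(assoc$tab3, file.path(out_dir, "table3_mr.tsv"))
  write_result_tsv(assoc$tab1, file.path(out_dir, "table1_risk_factors.tsv"))
  if (!is.null(assoc$tab2$lipophilicity))
    write_result_tsv(assoc$tab2$lipophilicity,
                     file.path(out_dir, "table2_statin_class.tsv"))
  write_result_tsv(assoc$scan$results, file.path(out_dir, "per_snp_scan.tsv"))

  pw <- config$power
  N <- cfg$n_cases + cfg$n_controls
  K <- cfg$n_cases / N
  power_out <- stage("power", list(
    n = N, cases = cfg$n_cases, k = K, r2 = pw$r2, alpha = pw$alpha,
    or = pw$or,
    power = unclass(mrnd_binary_power(N, K, pw$r2, pw$alpha, pw$or))[1],
    min_detectable_or = min_detectable_or(N, K, pw$r2, pw$alpha,
                                          pw$target_power)))
  jsonlite::write_json(power_out, file.path(out_dir, "power.json"),
                       auto_unbox = TRUE, digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("lgsmr")),
    master_seed = cfg$seed,
    stage_seeds = as.list(sim$truth$seeds),
    config = config,
    timestamp = format(Sys.time(), tz = "UTC"),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(manifest, "results") <- list(sim = sim, selection = report,
                                    scores = scores, association = assoc,
                                    power = power_out)
  invisible(manifest)
}
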