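#' Decoy specification for synthetic instrument catalogs
#'
#' Counts of catalog entries that violate each selection rule, used by
#' [make_instrument_catalog()] to seed the catalog with known-bad candidates.
#'
#' @param subthreshold_p SNPs whose GWAS p-value misses genome-wide
#'   significance (p between 1e-7 and 1e-6).
#' @param population SNPs reported in a non-Caucasian population.
#' @param no_effect_allele SNPs whose lipid-raising allele is not reported.
#' @param ld_dup Same-region duplicates in high LD (r2 > 0.2) with a true
#'   instrument but with a larger p-value, so region pruning must drop them.
#' @param pleiotropic SNPs associated at genome-wide significance with two
#'   lipid traits among TG/HDL/LDL.
#' @param excluded_trait SNPs additionally tagged to a trait on the exclusion
#'   list (alcohol, BMI, diabetes, inflammation).
#' @param tri_trait Add one rs174546-like SNP associated with all three of
#'   TG, HDL and LDL (raising LDL and HDL, lowering TG).
#' @return A named list of class `decoy_spec`.
#' @export
decoy_spec <- function(subthreshold_p = 3L, population = 3L,
                       no_effect_allele = 3L, ld_dup = 3L, pleiotropic = 3L,
                       excluded_trait = 3L, tri_trait = TRUE) {
  counts <- c(subthreshold_p = subthreshold_p, population = population,
              no_effect_allele = no_effect_allele, ld_dup = ld_dup,
              pleiotropic = pleiotropic, excluded_trait = excluded_trait)
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("decoy counts must be non-negative integers")
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(c(as.list(counts), list(tri_trait = isTRUE(tri_trait))),
            class = "decoy_spec")
}

# allele pairs that are unambiguous under strand flips (no A/T or C/G)
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                        ncol = 2, byrow = TRUE)

#' Build a synthetic GWAS-catalog-style instrument table with labeled decoys
#'
#' Emulates a filtered GWAS-catalog extract: one row per SNP-trait
#' association with id, coordinates, effect (lipid-raising) and other
#' alleles, trait label, GWAS p-value and population. True instruments are
#' placed in distinct chromosomal regions (> 1 Mb apart); decoys violating
#' each selection rule are added per `decoys`, including same-region LD
#' duplicates that the region-pruning step must remove. Ground-truth
#' keep/drop labels (`keep_truth`, `drop_reason_truth`) are attached for
#' testing the selection pipeline; they are derived from the construction,
#' not from running the filter.
#'
#' The TC score set is built as `tc_overlap` SNPs shared with the LDL and
#' HDL sets plus TC-specific SNPs, so TC rows duplicate some LDL/HDL SNP
#' ids (the TC score is exempt from the LDL/HDL pleiotropy restriction).
#'
#' @param config A [sim_config()].
#' @param decoys A [decoy_spec()].
#' @return A data.frame catalog (columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `trait`, `pvalue`, `population`,
#'   `raises_trait`, `keep_truth`, `drop_reason_truth`) with attribute
#'   `"panel"`: one row per unique SNP (`snp_id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`, `freq`, `block`, `rho`) describing the
#'   genotyping panel, ordered so that LD-block members are adjacent.
#' @export
make_instrument_catalog <- function(config, decoys = decoy_spec()) {
  stopifnot(inherits(config, "sim_config"), inherits(decoys, "decoy_spec"))
  locus <- 0L
  next_locus <- function() {
    locus <<- locus + 1L
    list(chrom = ((locus - 1L) %% 22L) + 1L,
         pos = 1000000L + ((locus - 1L) %/% 22L) * 3000000L)
  }
  rows <- list()
  panel <- list()
  snp_i <- 0L
  add_snp <- function(chrom, pos, freq = NULL) {
    snp_i <<- snp_i + 1L
    id <- sprintf("rs%05d", snp_i)
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), 1L), ]
    # the array may count either allele, sometimes on the opposite strand
    counted_first <- stats::runif(1) < 0.5
    counted <- if (counted_first) pair[1] else pair[2]
    other <- if (counted_first) pair[2] else pair[1]
    if (stats::runif(1) < 0.3) {
      comp <- c(A = "T", T = "A", C = "G", G = "C")
      counted <- comp[[counted]]; other <- comp[[other]]
    }
    panel[[length(panel) + 1L]] <<- data.frame(
      snp_id = id, chrom = chrom, pos = pos,
      counted_allele = counted, other_allele = other,
      freq = freq %||% stats::runif(1, config$allele_freq_range[1],
                                    config$allele_freq_range[2]),
      block = length(panel) + 1L, rho = 0,
      stringsAsFactors = FALSE)
    list(id = id, effect = pair[1], other = pair[2])
  }
  add_row <- function(snp, trait, pvalue, population = "Caucasian",
                      keep = FALSE, reason = NA_character_, raises = TRUE,
                      effect_allele = NULL, chrom, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      snp_id = snp$id, chrom = chrom, pos = pos,
      effect_allele = effect_allele %||% snp$effect,
      other_allele = snp$other, trait = trait, pvalue = pvalue,
      population = population, raises_trait = raises, keep_truth = keep,
      drop_reason_truth = reason, stringsAsFactors = FALSE)
  }
  gwas_p <- function(n = 1L) 10^stats::runif(n, -20, -9)

  # --- true instruments ----------------------------------------------------
  true_ids <- list(TG = character(), HDL = character(), LDL = character())
  true_info <- list()
  for (trait in c("TG", "HDL", "LDL")) {
    for (k in seq_len(config$snp_counts[[trait]])) {
      loc <- next_locus()
      snp <- add_snp(loc$chrom, loc$pos)
      add_row(snp, trait, gwas_p(), keep = TRUE, chrom = loc$chrom, pos = loc$pos)
      true_ids[[trait]] <- c(true_ids[[trait]], snp$id)
      true_info[[snp$id]] <- list(snp = snp, chrom = loc$chrom, pos = loc$pos,
                                  p = rows[[length(rows)]]$pvalue)
    }
  }
  # TC set: shared LDL + shared HDL + TC-only
  tc_shared <- c(utils::head(true_ids$LDL, config$tc_overlap[["LDL"]]),
                 utils::head(true_ids$HDL, config$tc_overlap[["HDL"]]))
  for (id in tc_shared) {
    info <- true_info[[id]]
    add_row(info$snp, "TC", gwas_p(), keep = TRUE,
            chrom = info$chrom, pos = info$pos)
  }
  n_tc_only <- config$snp_counts[["TC"]] - length(tc_shared)
  for (k in seq_len(n_tc_only)) {
    loc <- next_locus()
    snp <- add_snp(loc$chrom, loc$pos)
    add_row(snp, "TC", gwas_p(), keep = TRUE, chrom = loc$chrom, pos = loc$pos)
  }

  # --- decoys --------------------------------------------------------------
  lipids <- c("TG", "HDL", "LDL")
  for (k in seq_len(decoys$subthreshold_p)) {
    loc <- next_locus(); snp <- add_snp(loc$chrom, loc$pos)
    add_row(snp, lipids[(k - 1L) %% 3L + 1L], 10^stats::runif(1, -7, -6.05),
            reason = "subthreshold_p", chrom = loc$chrom, pos = loc$pos)
  }
  for (k in seq_len(decoys$population)) {
    loc <- next_locus(); snp <- add_snp(loc$chrom, loc$pos)
    add_row(snp, lipids[(k - 1L) %% 3L + 1L], gwas_p(),
            population = "East Asian", reason = "population",
            chrom = loc$chrom, pos = loc$pos)
  }
  for (k in seq_len(decoys$no_effect_allele)) {
    loc <- next_locus(); snp <- add_snp(loc$chrom, loc$pos)
    add_row(snp, lipids[(k - 1L) %% 3L + 1L], gwas_p(),
            reason = "no_effect_allele", effect_allele = NA_character_,
            chrom = loc$chrom, pos = loc$pos)
  }
  if (decoys$ld_dup > 0) {
    partners <- sample(names(true_info), decoys$ld_dup)
    for (id in partners) {
      info <- true_info[[id]]
      pos <- info$pos + 50000L
      snp <- add_snp(info$chrom, pos)
      # place in the partner's LD block so dosage r2 >> 0.2
      pi <- match(id, vapply(panel, function(x) x$snp_id, ""))
      panel[[length(panel)]]$block <- panel[[pi]]$block
      panel[[length(panel)]]$rho <- config$ld_decoy_rho
      trait <- rows[[which(vapply(rows, function(r)
        r$snp_id == id & r$trait %in% lipids, TRUE))[1]]]$trait
      add_row(snp, trait, min(info$p * 100, 4.9e-8), reason = "ld_pruned",
              chrom = info$chrom, pos = pos)
    }
  }
  for (k in seq_len(decoys$pleiotropic)) {
    loc <- next_locus(); snp <- add_snp(loc$chrom, loc$pos)
    pair <- lipids[c((k - 1L) %% 3L + 1L, k %% 3L + 1L)]
    for (tr in pair)
      add_row(snp, tr, gwas_p(), reason = "pleiotropic",
              chrom = loc$chrom, pos = loc$pos)
  }
  excluded <- c("alcohol", "BMI", "diabetes", "inflammation")
  for (k in seq_len(decoys$excluded_trait)) {
    loc <- next_locus(); snp <- add_snp(loc$chrom, loc$pos)
    add_row(snp, lipids[(k - 1L) %% 3L + 1L], gwas_p(),
            reason = "excluded_trait", chrom = loc$chrom, pos = loc$pos)
    add_row(snp, paste0("other:", excluded[(k - 1L) %% 4L + 1L]), gwas_p(),
            reason = "not_score_candidate", chrom = loc$chrom, pos = loc$pos)
  }
  if (decoys$tri_trait) {
    loc <- next_locus(); snp <- add_snp(loc$chrom, loc$pos)
    for (tr in lipids)
      add_row(snp, tr, gwas_p(), reason = "pleiotropic", raises = tr != "TG",
              chrom = loc$chrom, pos = loc$pos)
  }

  catalog <- do.call(rbind, rows)
  panel <- do.call(rbind, panel)
  # order so LD-block members are adjacent (simulate_genotypes needs runs)
  panel <- panel[order(panel$block, panel$pos), , drop = FALSE]
  rownames(panel) <- NULL
  attr(catalog, "panel") <- panel
  catalog
}

# translate a panel into simulate_genotypes() arguments
panel_ld_blocks <- function(panel) {
  r <- rle(panel$block)
  lapply(seq_along(r$lengths), function(i) {
    idx <- sum(r$lengths[seq_len(i - 1L)]) + 1L
    list(size = r$lengths[i], rho = panel$rho[idx + r$lengths[i] - 1L])
  })
}
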