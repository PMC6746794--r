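#' Composite LD r-squared between two variants
#'
#' Squared Pearson correlation of additive dosages over pairwise-complete
#' subjects (the phase-free composite-LD convention, appropriate for
#' unphased genotype data). Symmetric in its arguments.
#'
#' @param G A [genotype_matrix()].
#' @param snp_a,snp_b Variant ids.
#' @param subset_mask Optional logical/integer subject subset (typically the
#'   controls, the LD reference of the selection pipeline).
#' @return r-squared in `[0, 1]`, or `NA` (with a warning) when either
#'   variant has zero dosage variance in the subset.
#' @export
compute_ld_r2 <- function(G, snp_a, snp_b, subset_mask = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  miss <- setdiff(c(snp_a, snp_b), G$snp_ids)
  if (length(miss))
    stop2("variant(s) absent from genotypes: ", paste(miss, collapse = ", "))
  a <- G$dosage[, snp_a]
  b <- G$dosage[, snp_b]
  if (!is.null(subset_mask)) { a <- a[subset_mask]; b <- b[subset_mask] }
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) stop2("fewer than 2 pairwise-complete subjects")
  if (identical(snp_a, snp_b)) return(1)
  if (stats::var(a[ok]) == 0 || stats::var(b[ok]) == 0) {
    warn2("zero dosage variance for ", snp_a, " or ", snp_b,
          "; LD undefined, treated as not in LD")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])^2
}

#' Greedy region-wise LD pruning keeping the most significant SNP
#'
#' Candidates are visited in order of ascending GWAS p-value (ties: lower
#' position, then id). A candidate is kept iff its LD with every already-kept
#' candidate of the same chromosomal region is r-squared <= `r2_threshold`.
#' Two candidates share a region when they lie on the same chromosome within
#' `region_mb` megabases. Undefined LD (`NA`) is treated as not in LD.
#'
#' @param candidates Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `pvalue`.
#' @param ld Function `(snp_a, snp_b) -> r2`, e.g. a closure over
#'   [compute_ld_r2()].
#' @param r2_threshold Pruning threshold (default 0.2).
#' @param region_mb Region half-width in Mb (default 1).
#' @return The kept rows, ordered by chromosome and position, with an
#'   attribute `"ld_pairs"`: the evaluated pairs and their r-squared.
#' @export
prune_by_region <- function(candidates, ld, r2_threshold = 0.2, region_mb = 1) {
  stopifnot(is.data.frame(candidates),
            all(c("snp_id", "chrom", "pos", "pvalue") %in% names(candidates)))
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$pvalue, candidates$pos, candidates$snp_id)
  kept <- integer()
  pairs <- list()
  for (i in ord) {
    in_region <- kept[candidates$chrom[kept] == candidates$chrom[i] &
                        abs(candidates$pos[kept] - candidates$pos[i]) <=
                        region_mb * 1e6]
    ok <- TRUE
    for (k in in_region) {
      r2 <- ld(candidates$snp_id[i], candidates$snp_id[k])
      pairs[[length(pairs) + 1L]] <- data.frame(
        snp_a = candidates$snp_id[i], snp_b = candidates$snp_id[k],
        r2 = r2, stringsAsFactors = FALSE)
      if (!is.na(r2) && r2 > r2_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- candidates[sort(kept), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  attr(out, "ld_pairs") <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snp_a = character(), snp_b = character(), r2 = numeric())
  out
}

#' Apply the full instrument-selection pipeline to a catalog
#'
#' Filters a GWAS-catalog-style table into the four trait-specific
#' instrument sets, applying, in fixed precedence order: (1) genome-wide
#' significance `pvalue <= p_threshold`; (2) population restriction;
#' (3) reported effect (lipid-raising) allele; (4) region-wise LD pruning at
#' r-squared > `r2_threshold` keeping the most significant SNP; (5) for the
#' TG/HDL/LDL scores, exclusion of SNPs associated at genome-wide
#' significance with more than one of TG/HDL/LDL (the TC score is exempt, so
#' it may share SNPs with LDL and HDL); (6) exclusion of SNPs tagged to
#' traits on `excluded_traits`. Every lipid-trait catalog row receives
#' either kept status or exactly one primary drop reason.
#'
#' @param catalog Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `trait`, `pvalue`, `population`. Rows
#'   with `trait` of the form `other:<name>` are not score candidates but
#'   drive rule (6).
#' @param genotypes A [genotype_matrix()] used for LD computation (rule 4).
#' @param controls_mask Optional subject subset (logical or indices) used as
#'   the LD reference; default all subjects.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param population Population label retained (default `"Caucasian"`).
#' @param r2_threshold,region_mb LD-pruning parameters (defaults 0.2, 1 Mb).
#' @param excluded_traits Trait names whose SNPs are excluded from every
#'   score (default alcohol, BMI, diabetes, inflammation).
#' @return An object of class `selection_report`: list with `kept` (named
#'   list of per-trait kept snp_id vectors), `table` (per-row status and
#'   primary drop reason), `ld_pairs`, and the parameters used.
#' @export
filter_catalog <- function(catalog, genotypes, controls_mask = NULL,
                           p_threshold = 5e-8, population = "Caucasian",
                           r2_threshold = 0.2, region_mb = 1,
                           excluded_traits = c("alcohol", "BMI", "diabetes",
                                               "inflammation")) {
  stopifnot(is.data.frame(catalog), nrow(catalog) > 0)
  lipid_traits <- c("TG", "HDL", "LDL", "TC")
  cat_l <- catalog[catalog$trait %in% lipid_traits, , drop = FALSE]
  # SNPs tagged to excluded traits (via other:<name> rows)
  other <- catalog[startsWith(catalog$trait, "other:"), , drop = FALSE]
  excluded_snps <- unique(other$snp_id[sub("^other:", "", other$trait) %in%
                                         excluded_traits])
  # genome-wide-significant lipid-trait multiplicity among TG/HDL/LDL
  sig3 <- cat_l[cat_l$trait %in% c("TG", "HDL", "LDL") &
                  cat_l$pvalue <= p_threshold, , drop = FALSE]
  multi <- table(unique(sig3[c("snp_id", "trait")])$snp_id)
  pleio_snps <- names(multi)[multi > 1]

  ld_cache <- new.env(parent = emptyenv())
  ld_fun <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(ld_cache[[key]])) return(ld_cache[[key]])
    r2 <- compute_ld_r2(genotypes, a, b, subset_mask = controls_mask)
    ld_cache[[key]] <- r2
    r2
  }

  res <- list(); ld_pairs <- list()
  for (tr in lipid_traits) {
    rows <- cat_l[cat_l$trait == tr, , drop = FALSE]
    if (nrow(rows) == 0) { res[[tr]] <- NULL; next }
    reason <- rep(NA_character_, nrow(rows))
    reason[is.na(reason) & rows$pvalue > p_threshold] <- "subthreshold_p"
    reason[is.na(reason) & rows$population != population] <- "population"
    reason[is.na(reason) & (is.na(rows$effect_allele) |
                              !rows$effect_allele %in% c("A", "C", "G", "T"))] <-
      "no_effect_allele"
    surv <- rows[is.na(reason), , drop = FALSE]
    if (nrow(surv)) {
      absent <- setdiff(surv$snp_id, genotypes$snp_ids)
      if (length(absent))
        stop2("catalog SNP(s) absent from genotypes, LD pruning impossible: ",
              paste(absent, collapse = ", "))
      pruned <- prune_by_region(surv, ld_fun, r2_threshold, region_mb)
      ld_pairs[[tr]] <- attr(pruned, "ld_pairs")
      reason[is.na(reason) & !(rows$snp_id %in% pruned$snp_id)] <- "ld_pruned"
    }
    if (tr != "TC")
      reason[is.na(reason) & rows$snp_id %in% pleio_snps] <- "pleiotropic"
    reason[is.na(reason) & rows$snp_id %in% excluded_snps] <- "excluded_trait"
    rows$status <- ifelse(is.na(reason), "kept", "dropped")
    rows$drop_reason <- reason
    res[[tr]] <- rows
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  kept <- lapply(res, function(r) r$snp_id[r$status == "kept"])
  lp <- do.call(rbind, ld_pairs)
  structure(list(
    kept = kept, table = tab,
    ld_pairs = if (!is.null(lp)) unique(lp) else
      data.frame(snp_a = character(), snp_b = character(), r2 = numeric()),
    params = list(p_threshold = p_threshold, population = population,
                  r2_threshold = r2_threshold, region_mb = region_mb,
                  excluded_traits = excluded_traits)
  ), class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  for (tr in names(x$kept))
    cat(sprintf("  %-4s kept %3d of %3d candidates\n", tr,
                length(x$kept[[tr]]), sum(x$table$trait == tr)))
  drops <- table(x$table$drop_reason)
  if (length(drops))
    cat("  drop reasons:",
        paste(names(drops), drops, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
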