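#' Write genotypes as additive-dosage tab-separated text
#'
#' Header row of SNP ids preceded by a `subject_id` column; one subject per
#' line; missing genotypes written as `NA`. Two comment lines (`##counted=`,
#' `##other=`) preserve the allele labels so the matrix round-trips.
#'
#' @param G A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_additive <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("##counted=", paste(G$counted_allele, collapse = "\t")),
               paste0("##other=", paste(G$other_allele, collapse = "\t"))), con)
  df <- data.frame(subject_id = G$subject_ids, G$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Emits VCFv4.2 with one biallelic record per variant; REF is the variant's
#' other allele and ALT the counted allele, so the ALT dosage equals the
#' stored counted-allele dosage. Genotypes are unphased (`0/0`, `0/1`,
#' `1/1`, missing `./.`).
#'
#' @param G A [genotype_matrix()] (needs `chrom`/`pos`; defaults of chrom 1
#'   and consecutive positions are used when absent).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- length(G$snp_ids)
  chrom <- G$chrom %||% rep(1L, m)
  pos <- G$pos %||% seq_len(m)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$subject_ids), collapse = "\t"))
  body <- vapply(seq_len(m), function(j) {
    d <- G$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(chrom[j], pos[j], G$snp_ids[j], G$other_allele[[j]],
            G$counted_allele[[j]], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from VCF or additive-dosage text
#'
#' For VCF input (parsed with the vcfR package) the returned dosage counts
#' copies of the ALT allele; `./.` genotypes become missing; multi-allelic
#' records are rejected with their data-line number. Additive text written
#' by [write_genotypes_additive()] round-trips exactly.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"additive"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "additive")) {
  format <- match.arg(format)
  if (format == "additive") {
    hdr <- readLines(path, n = 2L)
    counted <- other <- NULL
    skip <- 0L
    if (startsWith(hdr[1], "##counted=")) {
      counted <- strsplit(sub("^##counted=", "", hdr[1]), "\t")[[1]]
      other <- strsplit(sub("^##other=", "", hdr[2]), "\t")[[1]]
      skip <- 2L
    }
    df <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                            check.names = FALSE, stringsAsFactors = FALSE)
    d <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(d) <- "integer"
    rownames(d) <- df[[1]]
    return(genotype_matrix(d, counted %||% "A", other %||% "G"))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop2("multi-allelic record(s) rejected at data line(s): ",
          paste(which(multi), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- sub("|", "/", x, fixed = TRUE)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           (substr(x, 1, 1) == "1") + (substr(x, 3, 3) == "1"))
  }
  d <- t(apply(gt, 1, count_alt))
  if (ncol(gt) == 1) d <- t(d)
  dimnames(d) <- list(rownames(gt), colnames(gt))
  d <- t(d)  # subjects x variants
  storage.mode(d) <- "integer"
  genotype_matrix(d, counted_allele = fix[, "ALT"], other_allele = fix[, "REF"],
                  chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]))
}

#' Write the instrument catalog as TSV
#'
#' @param catalog Catalog data.frame from [make_instrument_catalog()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog
  out$pvalue <- fmt_num(out$pvalue)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an instrument catalog TSV
#'
#' @param path Input file.
#' @return Catalog data.frame.
#' @export
read_catalog <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(pvalue = "numeric"))
}

#' Write a selection report as TSV plus JSON summary
#'
#' @param report A `selection_report` from [filter_catalog()].
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_selection_report <- function(report, dir) {
  stopifnot(inherits(report, "selection_report"))
  tsv <- file.path(dir, "selection_report.tsv")
  utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, "selection_summary.json")
  jsonlite::write_json(list(kept = report$kept, params = report$params),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

# TSV writer with fixed 6-significant-digit float formatting so output
# hashes are reproducible across platforms
write_result_tsv <- function(df, path) {
  out <- df
  for (v in names(out)) if (is.numeric(out[[v]])) out[[v]] <- fmt_num(out[[v]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
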