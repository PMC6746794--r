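#' Genotype dosage matrix
#'
#' Container for subjects-by-variants additive dosages of a counted allele.
#' Each non-missing entry is the number of copies (0, 1 or 2) of the counted
#' allele carried by the subject; missing genotypes are `NA`.
#'
#' @param dosage Integer matrix, subjects in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names are subject ids, column names
#'   variant ids (generated when absent).
#' @param counted_allele Character vector, one single base per variant: the
#'   allele whose copies the dosage counts.
#' @param other_allele Character vector, the variant's other allele.
#' @param chrom,pos Optional chromosome labels and 1-based positions per
#'   variant (used when writing VCF).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `subject_ids`, `snp_ids`, `counted_allele`, `other_allele`,
#'   `chrom`, `pos`.
#' @export
genotype_matrix <- function(dosage, counted_allele, other_allele,
                            chrom = NULL, pos = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad))
    stop2("dosage entries must be 0, 1, 2 or NA; found ",
          paste(utils::head(unique(dosage[bad]), 3), collapse = ", "))
  m <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("rs", seq_len(m))
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  counted_allele <- rep_len(as.character(counted_allele), m)
  other_allele <- rep_len(as.character(other_allele), m)
  ok <- counted_allele %in% c("A", "C", "G", "T") &
    other_allele %in% c("A", "C", "G", "T") & counted_allele != other_allele
  if (!all(ok))
    stop2("alleles must be distinct single bases in {A,C,G,T} (variant ",
          colnames(dosage)[which(!ok)[1]], ")")
  structure(list(
    dosage = dosage,
    subject_ids = rownames(dosage),
    snp_ids = colnames(dosage),
    counted_allele = stats::setNames(counted_allele, colnames(dosage)),
    other_allele = stats::setNames(other_allele, colnames(dosage)),
    chrom = if (!is.null(chrom)) stats::setNames(rep_len(chrom, m), colnames(dosage)),
    pos = if (!is.null(pos)) stats::setNames(rep_len(as.integer(pos), m), colnames(dosage))
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$subject_ids), " subjects x ",
      length(x$snp_ids), " variants\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat("  missing entries: ", format(100 * miss, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i,j Subject / variant indices (any form accepted by matrix
#'   subsetting).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selected subjects/variants.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$subject_ids)
  if (missing(j)) j <- seq_along(x$snp_ids)
  d <- x$dosage[i, j, drop = FALSE]
  genotype_matrix(d, x$counted_allele[colnames(d)], x$other_allele[colnames(d)],
                  chrom = if (!is.null(x$chrom)) x$chrom[colnames(d)],
                  pos = if (!is.null(x$pos)) x$pos[colnames(d)])
}
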