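#' Simulate genotype dosages under Hardy-Weinberg equilibrium with optional
#' LD blocks
#'
#' Genotypes are generated as the sum of two independent haplotypes, so the
#' marginal genotype frequencies at every variant are exactly the
#' Hardy-Weinberg proportions for its allele frequency. Within an LD block,
#' each haplotype is a Markov chain over the block's variants: adjacent
#' alleles have the configured correlation, so adjacent dosages have
#' (expected) correlation equal to the haplotype correlation and
#' \eqn{r^2 \approx \rho^2}. Variants in different blocks are independent.
#'
#' @param n Number of subjects.
#' @param freqs Numeric vector of counted-allele frequencies, one per
#'   variant, each in (0, 1).
#' @param ld_blocks Optional list describing LD blocks, each element
#'   `list(size = , rho = )` with `size` a positive integer and `rho` a
#'   haplotype allele correlation in `[0, 1)`. Block sizes must sum to the
#'   number of variants (they partition the variant list in order). `NULL`
#'   makes all variants independent.
#' @param missing_rate Fraction of entries masked as missing, in `[0, 1)`.
#' @param snp_ids Optional variant ids (default `rs1 ...`).
#' @param counted_allele,other_allele Optional allele labels per variant
#'   (defaults `"A"` / `"G"`).
#' @param chrom,pos Optional variant coordinates, carried through to the
#'   returned object.
#' @return A [genotype_matrix()] with attribute `"freqs"` (the allele
#'   frequencies used).
#' @export
simulate_genotypes <- function(n, freqs, ld_blocks = NULL, missing_rate = 0,
                               snp_ids = NULL, counted_allele = "A",
                               other_allele = "G", chrom = NULL, pos = NULL) {
  stopifnot(is_count(n), is.numeric(freqs), all(freqs > 0 & freqs < 1))
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop2("missing_rate must be in [0, 1)")
  m <- length(freqs)
  if (is.null(ld_blocks)) ld_blocks <- list(list(size = m, rho = 0))
  sizes <- vapply(ld_blocks, function(b) as.numeric(b$size), 0)
  rhos <- vapply(ld_blocks, function(b) as.numeric(b$rho), 0)
  if (any(sizes < 1 | sizes != round(sizes))) stop2("block sizes must be positive integers")
  if (any(rhos < 0 | rhos >= 1)) stop2("haplotype correlations must be in [0, 1)")
  if (sum(sizes) != m) stop2("block sizes must sum to the number of variants (", m, ")")

  dosage <- matrix(0L, n, m)
  start <- 1L
  for (b in seq_along(sizes)) {
    idx <- seq.int(start, length.out = sizes[b])
    h1 <- sim_haplotypes(n, freqs[idx], rhos[b])
    h2 <- sim_haplotypes(n, freqs[idx], rhos[b])
    dosage[, idx] <- h1 + h2
    start <- start + as.integer(sizes[b])
  }
  if (missing_rate > 0) {
    mask <- stats::runif(n * m) < missing_rate
    dosage[mask] <- NA_integer_
  }
  colnames(dosage) <- snp_ids %||% paste0("rs", seq_len(m))
  rownames(dosage) <- paste0("S", seq_len(n))
  g <- genotype_matrix(dosage, counted_allele, other_allele, chrom = chrom, pos = pos)
  attr(g, "freqs") <- stats::setNames(freqs, colnames(dosage))
  g
}

# One haplotype per subject over a block: first-order Markov chain of
# Bernoulli alleles with pairwise correlation rho between neighbours.
# Conditional probabilities follow from Cov(X, Y) = rho * sqrt(p1 q1 p2 q2);
# they are clipped into [0, 1] (only binding for extreme frequency contrasts).
sim_haplotypes <- function(n, p, rho) {
  k <- length(p)
  H <- matrix(0L, n, k)
  H[, 1] <- stats::rbinom(n, 1L, p[1])
  if (k > 1) for (j in 2:k) {
    p1 <- p[j - 1]; p2 <- p[j]
    cov <- rho * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    p_on <- min(1, max(0, p2 + cov / p1))
    p_off <- min(1, max(0, p2 - cov / (1 - p1)))
    pr <- ifelse(H[, j - 1] == 1L, p_on, p_off)
    H[, j] <- stats::rbinom(n, 1L, pr)
  }
  H
}
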