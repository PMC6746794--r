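# Internal helpers shared across modules.

#' Derive reproducible sub-stream seeds from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed, so stages can be re-run (or reordered in tests) without perturbing
#' each other's random streams. Seeds are kept below 2^31 so they are valid R
#' integers.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-stream seeds to derive.
#' @return Integer vector of length `n`, named `stream1` ... `streamn`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  names(seeds) <- paste0("stream", seq_len(n))
  seeds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x < 1

# format numbers with 6 significant digits for reproducible text output
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
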