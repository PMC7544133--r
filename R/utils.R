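# Internal helpers shared across modules.

# 95% normal quantile used for all reported confidence intervals.
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

NUCLEOTIDES <- c("A", "C", "G", "T")

complement_allele <- function(a) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[a])
}

is_palindromic <- function(a1, a2) {
  a1 == complement_allele(a2)
}

#' @keywords internal
two_sided_p <- function(z) {
  2 * stats::pnorm(-abs(z))
}

# Deterministic integer sub-seed derived from a master seed and a label,
# kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289) %% 2147483587)
}
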