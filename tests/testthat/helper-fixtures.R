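# Fixture builders shared across the suite. Everything is generated in
# code; no stored data.

# A small well-formed summary-statistic tibble with deterministic values.
make_sumstats <- function(n = 5, seed = 42, chrom = NULL, pos = NULL) {
  withr::with_seed(seed, {
    beta <- round(stats::rnorm(n, 0, 0.05), 4)
    se <- round(stats::runif(n, 0.004, 0.01), 4)
    tibble::tibble(
      variant_id = sprintf("rs%04d", seq_len(n)),
      chrom = chrom %||% as.character(rep_len(1:2, n)),
      pos = pos %||% as.integer(seq_len(n) * 1e6),
      effect_allele = rep_len(c("A", "C", "G", "T", "A"), n),
      other_allele = rep_len(c("G", "T", "A", "C", "C"), n),
      eaf = round(stats::runif(n, 0.05, 0.95), 3),
      beta = beta,
      se = se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)),
      n = rep(10000L, n)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An LD panel where every listed pair has the given r2 and all variants sit
# on one chromosome within one window.
make_dense_ld <- function(ids, r2, chrom = "1", pos = NULL) {
  pos <- pos %||% as.integer(seq_along(ids) * 1e5)
  pairs <- expand.grid(id1 = ids, id2 = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$id1 < pairs$id2, , drop = FALSE]
  pairs$r2 <- rep_len(r2, nrow(pairs))
  ld_panel_from_pairs(pairs,
                      tibble::tibble(variant_id = ids, chrom = chrom, pos = pos))
}

# Independent reference implementation of greedy clumping, written as a
# direct transcription of the selection rule, used as an oracle.
reference_clump <- function(records, ld, window_kb, r2_threshold, p_threshold) {
  x <- records[records$pvalue < p_threshold, , drop = FALSE]
  x <- x[order(x$pvalue, x$chrom, x$pos, x$variant_id), , drop = FALSE]
  kept <- x[0, ]
  while (nrow(x) > 0) {
    top <- x[1, ]
    kept <- rbind(kept, top)
    conflict <- x$chrom == top$chrom &
      abs(x$pos - top$pos) <= window_kb * 1000 &
      ld_r2(ld, x$variant_id, top$variant_id) > r2_threshold
    x <- x[!conflict & x$variant_id != top$variant_id, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$pos, kept$variant_id), , drop = FALSE]
}

# Exhaustive palindrome-orientation oracle: enumerate the four possible
# reported configurations of a palindromic outcome record (allele order x
# strand) and return the frequency-consistent aligned (beta, eaf), or NULL
# when ambiguous.
palindrome_oracle <- function(eaf_exposure, beta_outcome, eaf_outcome,
                              outcome_effect_first, limit) {
  # the two candidate alignments of the outcome effect allele to the
  # exposure effect allele
  cand <- list(
    list(beta = if (outcome_effect_first) beta_outcome else -beta_outcome,
         eaf = if (outcome_effect_first) eaf_outcome else 1 - eaf_outcome),
    list(beta = if (outcome_effect_first) -beta_outcome else beta_outcome,
         eaf = if (outcome_effect_first) 1 - eaf_outcome else eaf_outcome)
  )
  ambiguous <- function(f) f >= limit & f <= 1 - limit
  if (ambiguous(eaf_exposure) || ambiguous(cand[[1]]$eaf)) return(NULL)
  ok <- vapply(cand, function(cc) (cc$eaf < 0.5) == (eaf_exposure < 0.5),
               logical(1))
  if (sum(ok) != 1) return(NULL)
  cand[[which(ok)]]
}

# Minimal cohort for individual-level unit tests.
make_mini_cohort <- function(n = 800, seed = 7, causal = log(1.75)) {
  cfg <- sim_config(n_variants = 40, instrument_r2 = 0.2,
                    causal_logor_per_sd = causal, pleiotropy = "none",
                    n_cohort = n, seed = seed)
  simulate_cohort(cfg)
}
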