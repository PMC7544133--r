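#' Align exposure and outcome effects to a shared effect allele
#'
#' Joins two summary-statistic sets on `variant_id` and orients every outcome
#' record to the exposure's effect allele. Outcome records whose allele pair
#' is reversed have their beta negated and allele frequency complemented.
#' Records reported on the opposite strand are recognised by complementing
#' the outcome alleles (non-palindromic variants only). Palindromic variants
#' (A/T or C/G) are strand-ambiguous: the orientation is inferred from allele
#' frequency when both studies' frequencies are clearly away from 0.5
#' (outside `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`), otherwise
#' the variant is dropped. Irreconcilable allele pairs are dropped with a
#' warning.
#'
#' @param exposure,outcome Canonical summary-statistic tibbles (see
#'   [read_summary_stats()]); each must have unique `variant_id`s.
#' @param palindrome_eaf_limit Ambiguity limit for palindromic frequency
#'   inference, in (0, 0.5); default 0.42.
#' @return A tibble of class `mr_harmonized` with one row per retained
#'   variant: `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `pvalue_exposure`, `n_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`, `action`.
#'   `action` is one of `unchanged`, `flipped`, `inferred_palindromic`;
#'   dropped variants are reported in the `dropped` attribute with reasons.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  assert_that(palindrome_eaf_limit > 0 && palindrome_eaf_limit < 0.5,
              "palindrome_eaf_limit must be in (0, 0.5)")
  if (anyDuplicated(exposure$variant_id) > 0L)
    stop("duplicate variant_id in exposure study", call. = FALSE)
  if (anyDuplicated(outcome$variant_id) > 0L)
    stop("duplicate variant_id in outcome study", call. = FALSE)

  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L)
    stop("zero overlapping variants between exposure and outcome", call. = FALSE)

  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  amb_lo <- palindrome_eaf_limit
  amb_hi <- 1 - palindrome_eaf_limit

  k <- length(shared)
  beta_o <- rep(NA_real_, k)
  eaf_o <- rep(NA_real_, k)
  se_o <- ou$se
  action <- rep(NA_character_, k)

  for (i in seq_len(k)) {
    a1 <- ex$effect_allele[i]; a2 <- ex$other_allele[i]
    b1 <- ou$effect_allele[i]; b2 <- ou$other_allele[i]
    pal <- is_palindromic(a1, a2)

    # orientation implied by the allele labels themselves
    label_dir <- if (b1 == a1 && b2 == a2) {
      1L
    } else if (b1 == a2 && b2 == a1) {
      -1L
    } else if (!pal && complement_allele(b1) == a1 && complement_allele(b2) == a2) {
      1L  # other strand, same orientation
    } else if (!pal && complement_allele(b1) == a2 && complement_allele(b2) == a1) {
      -1L
    } else {
      0L  # irreconcilable
    }

    if (label_dir == 0L) {
      action[i] <- "incompatible_alleles"
      next
    }

    if (!pal) {
      if (label_dir == 1L) {
        beta_o[i] <- ou$beta[i]; eaf_o[i] <- ou$eaf[i]; action[i] <- "unchanged"
      } else {
        beta_o[i] <- -ou$beta[i]; eaf_o[i] <- 1 - ou$eaf[i]; action[i] <- "flipped"
      }
      next
    }

    # Palindromic: allele labels cannot distinguish strand; use frequency.
    eaf_x <- ex$eaf[i]
    eaf_label <- if (label_dir == 1L) ou$eaf[i] else 1 - ou$eaf[i]
    ambiguous <- (eaf_x >= amb_lo && eaf_x <= amb_hi) ||
      (eaf_label >= amb_lo && eaf_label <= amb_hi)
    if (ambiguous) {
      action[i] <- "dropped_palindromic"
      next
    }
    if ((eaf_x < 0.5) == (eaf_label < 0.5)) {
      # label-implied orientation is frequency-consistent
      beta_o[i] <- label_dir * ou$beta[i]
      eaf_o[i] <- eaf_label
      action[i] <- if (label_dir == 1L) "unchanged" else "flipped"
    } else {
      # labels were reported on the other strand: take the complement
      beta_o[i] <- -label_dir * ou$beta[i]
      eaf_o[i] <- 1 - eaf_label
      action[i] <- "inferred_palindromic"
    }
  }

  keep <- action %in% c("unchanged", "flipped", "inferred_palindromic")
  dropped <- tibble::tibble(variant_id = shared[!keep], reason = action[!keep])
  if (any(action == "incompatible_alleles", na.rm = TRUE)) {
    warning(sum(action == "incompatible_alleles"),
            " variant(s) dropped: irreconcilable allele pairs", call. = FALSE)
  }

  out <- tibble::tibble(
    variant_id = shared[keep],
    chrom = ex$chrom[keep],
    pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    pvalue_exposure = ex$pvalue[keep],
    n_exposure = ex$n[keep],
    eaf_exposure = ex$eaf[keep],
    beta_outcome = beta_o[keep],
    se_outcome = se_o[keep],
    eaf_outcome = eaf_o[keep],
    action = action[keep]
  )
  bad <- !is.finite(out$beta_exposure) | !is.finite(out$se_exposure) |
    !is.finite(out$beta_outcome) | !is.finite(out$se_outcome)
  out <- out[!bad, , drop = FALSE]
  structure(out, class = c("mr_harmonized", class(tibble::tibble()))) |>
    set_attr("dropped", dropped)
}

set_attr <- function(x, name, value) {
  attr(x, name) <- value
  x
}

#' Convert a harmonized instrument back to outcome summary-statistic form
#'
#' Utility used for idempotence checks and for feeding a harmonized outcome
#' back through [harmonize()].
#'
#' @param h An `mr_harmonized` tibble.
#' @return A canonical summary-statistic tibble of the outcome effects.
#' @export
harmonized_outcome_records <- function(h) {
  tibble::tibble(
    variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    eaf = h$eaf_outcome, beta = h$beta_outcome, se = h$se_outcome,
    pvalue = two_sided_p(h$beta_outcome / h$se_outcome),
    n = h$n_exposure
  )
}
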