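#' Variance in the exposure explained by one variant
#'
#' Computes `2 * maf * (1 - maf) * beta^2` with `maf = min(eaf, 1 - eaf)`,
#' the variance share of a standardized exposure attributable to a variant
#' under Hardy-Weinberg equilibrium. `beta` must be on the per-standard-
#' deviation exposure scale.
#'
#' @param eaf Effect-allele frequency in \[0,1\] (vectorised).
#' @param beta Per-allele effect on the standardized exposure (vectorised).
#' @return Variance explained, same length as the inputs.
#' @export
variance_explained <- function(eaf, beta) {
  assert_that(all(eaf >= 0 & eaf <= 1), "eaf must lie in [0,1]")
  maf <- pmin(eaf, 1 - eaf)
  2 * maf * (1 - maf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)`: the single-degree-of-freedom F-statistic
#' of a per-variant regression explaining a share `r2` of the exposure
#' variance in a sample of size `n`. Values below ~10 conventionally signal
#' weak-instrument bias.
#'
#' @param r2 Variance explained, in \[0,1) (vectorised).
#' @param n Exposure GWAS sample size, `> 2`.
#' @return F-statistic, same length as `r2`.
#' @export
f_statistic <- function(r2, n) {
  assert_that(all(r2 >= 0 & r2 < 1), "r2 must lie in [0,1)")
  assert_that(all(n > 2), "n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Build a genetic instrument from two GWAS
#'
#' Composes the instrument-construction pipeline: filter the exposure study
#' to `p < p_threshold`, LD-clump to an independent set, harmonize with the
#' outcome study, and attach per-variant strength metrics (R-squared and F
#' computed from the exposure allele frequency, effect size and sample
#' size). The result is an `mr_instrument`: the harmonized tibble plus
#' columns `r2_explained` and `f_stat`, with summary strength statistics in
#' attributes retrievable via [glance()].
#'
#' @param exposure,outcome Canonical summary-statistic tibbles.
#' @param ld An `ld_panel`.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param window_kb,r2_threshold Clumping parameters (defaults 10,000 kb and
#'   0.001).
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @param trait_sd Exposure SD in the units of the exposure betas, used to
#'   rescale them to the standardized scale for the strength metrics;
#'   `NULL` (default) when betas are already per-SD.
#' @return An `mr_instrument` tibble.
#' @export
build_instrument <- function(exposure, outcome, ld, p_threshold = 5e-8,
                             window_kb = 10000, r2_threshold = 0.001,
                             palindrome_eaf_limit = 0.42, trait_sd = NULL) {
  clumped <- clump(exposure, ld, window_kb = window_kb,
                   r2_threshold = r2_threshold, p_threshold = p_threshold)
  h <- harmonize(clumped, outcome, palindrome_eaf_limit = palindrome_eaf_limit)
  as_mr_instrument(h, trait_sd = trait_sd)
}

#' Attach strength metrics to a harmonized instrument
#'
#' @param h An `mr_harmonized` tibble.
#' @param trait_sd Exposure SD used to rescale raw-unit exposure betas to
#'   per-SD before computing R-squared; `NULL` when already per-SD.
#' @return An `mr_instrument` tibble.
#' @export
as_mr_instrument <- function(h, trait_sd = NULL) {
  beta_std <- if (is.null(trait_sd)) h$beta_exposure else h$beta_exposure / trait_sd
  h$r2_explained <- variance_explained(h$eaf_exposure, beta_std)
  h$f_stat <- f_statistic(h$r2_explained, h$n_exposure)
  structure(h, class = unique(c("mr_instrument", class(h))))
}

#' @export
glance.mr_instrument <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x),
    total_r2 = sum(x$r2_explained),
    mean_f = mean(x$f_stat),
    min_f = min(x$f_stat),
    max_f = max(x$f_stat),
    n_exposure = max(x$n_exposure)
  )
}

#' Restrict an instrument by confounder associations
#'
#' Removes every instrument variant nominally associated (`p < nominal_p`)
#' with any of the supplied confounder GWASs, recomputing strength metrics.
#' Variants absent from a confounder study are retained for that trait. The
#' exclusion log (variant, trait, p) is attached as the `exclusions`
#' attribute.
#'
#' @param inst An `mr_instrument`.
#' @param confounder_studies Named list of canonical summary-statistic
#'   tibbles, one per confounder trait.
#' @param nominal_p Exclusion threshold (default 0.05).
#' @return The restricted `mr_instrument`.
#' @export
restrict_instrument <- function(inst, confounder_studies, nominal_p = 0.05) {
  if (is.null(names(confounder_studies)) || any(names(confounder_studies) == "")) {
    names(confounder_studies) <- paste0("trait_", seq_along(confounder_studies))
  }
  logs <- purrr::imap(confounder_studies, function(study, trait) {
    hit <- match(inst$variant_id, study$variant_id)
    p <- study$pvalue[hit]
    excl <- !is.na(p) & p < nominal_p
    tibble::tibble(variant_id = inst$variant_id[excl], trait = trait, p = p[excl])
  })
  exclusions <- dplyr::bind_rows(logs)
  keep <- !(inst$variant_id %in% exclusions$variant_id)
  out <- inst[keep, , drop = FALSE]
  out <- as_mr_instrument(out)
  set_attr(out, "exclusions", exclusions)
}

#' First-order approximation of sample-overlap bias
#'
#' When the exposure and outcome GWASs share participants, the two-sample MR
#' estimate is pulled toward the confounded observational association in
#' proportion to the overlap fraction and in inverse proportion to
#' instrument strength: `expected_bias = overlap_fraction *
#' assumed_confounded_effect / mean_f`. The expected type-I error at nominal
#' alpha = 0.05 under a true null is computed from the normal approximation
#' of the bias-shifted estimator given the estimator's standard error.
#'
#' @param overlap_fraction Share of outcome-sample participants also in the
#'   exposure sample, in \[0,1\].
#' @param mean_f Mean instrument F-statistic (must be positive).
#' @param assumed_confounded_effect The confounded observational association
#'   on the estimate's scale (default 0.2).
#' @param se Standard error of the MR estimate used for the type-I-error
#'   approximation (default 0.05 on the log-odds scale).
#' @return A one-row tibble: `overlap_fraction`, `assumed_confounded_effect`,
#'   `mean_f`, `expected_bias`, `expected_type1_error`.
#' @export
overlap_bias <- function(overlap_fraction, mean_f,
                         assumed_confounded_effect = 0.2, se = 0.05) {
  assert_that(overlap_fraction >= 0 && overlap_fraction <= 1,
              "overlap_fraction must lie in [0,1]")
  assert_that(mean_f > 0, "mean_f must be positive")
  assert_that(se > 0, "se must be positive")
  bias <- overlap_fraction * assumed_confounded_effect / mean_f
  shift <- bias / se
  type1 <- stats::pnorm(-Z95 - shift) + stats::pnorm(-Z95 + shift)
  tibble::tibble(
    overlap_fraction = overlap_fraction,
    assumed_confounded_effect = assumed_confounded_effect,
    mean_f = mean_f,
    expected_bias = bias,
    expected_type1_error = type1
  )
}
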