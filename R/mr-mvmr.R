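#' Multivariable MR
#'
#' Estimates the direct effect of several exposures on the outcome jointly:
#' weighted multivariable least squares of the outcome effects on the matrix
#' of exposure effects, no intercept, weights `1 / se_y^2`. Standard errors
#' carry the same multiplicative overdispersion floor as the univariable
#' estimators. Only variants present in every exposure and in the outcome
#' enter (the intersection is taken and its size reported).
#'
#' @param exposures Named list of tibbles, one per exposure, each with
#'   columns `variant_id`, `beta`, `se` (exposure association estimates
#'   already aligned to a shared effect allele per variant).
#' @param outcome Tibble with columns `variant_id`, `beta`, `se` for the
#'   outcome, aligned to the same alleles.
#' @return A tibble of class `mr_mvmr`: one row per exposure with
#'   `exposure`, `beta`, `se`, `ci_low`, `ci_high`, `or`, `pvalue`,
#'   `n_snps`.
#' @export
mr_mvmr <- function(exposures, outcome) {
  assert_that(length(exposures) >= 1, "need at least one exposure")
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- paste0("exposure_", seq_along(exposures))
  }
  ids <- Reduce(intersect, c(lapply(exposures, function(e) e$variant_id),
                             list(outcome$variant_id)))
  p <- length(exposures)
  assert_that(length(ids) >= p + 1,
              "need more shared variants than exposures")
  X <- vapply(exposures, function(e) e$beta[match(ids, e$variant_id)],
              numeric(length(ids)))
  X <- matrix(X, ncol = p, dimnames = list(NULL, names(exposures)))
  oy <- outcome[match(ids, outcome$variant_id), ]
  w <- 1 / oy$se^2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient exposure matrix; collinear exposure(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(oy$beta ~ 0 + X, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(sm$cov.unscaled))) * disp
  out <- tibble::tibble(
    exposure = names(exposures),
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    or = exp(beta),
    pvalue = two_sided_p(beta / se),
    n_snps = length(ids)
  )
  structure(out, class = c("mr_mvmr", class(out)))
}

#' Bidirectional MR
#'
#' Runs the full two-sample analysis in both directions: A -> B using
#' variants genome-wide significant for A, and B -> A using variants
#' genome-wide significant for B, each direction with IVW, weighted median
#' and MR-Egger.
#'
#' @param study_a,study_b Canonical summary-statistic tibbles.
#' @param ld An `ld_panel` covering both studies' variants.
#' @param p_threshold,window_kb,r2_threshold Instrument-construction
#'   parameters (see [build_instrument()]).
#' @param n_boot,seed Weighted-median settings.
#' @return A list with elements `forward` and `reverse`, each a list of
#'   `instrument` (the `mr_instrument` used) and `estimates` (stacked
#'   `mr_estimate` rows).
#' @export
mr_bidirectional <- function(study_a, study_b, ld, p_threshold = 5e-8,
                             window_kb = 10000, r2_threshold = 0.001,
                             n_boot = 1000, seed = 1L) {
  run_dir <- function(expo, outc, s) {
    inst <- build_instrument(expo, outc, ld, p_threshold = p_threshold,
                             window_kb = window_kb, r2_threshold = r2_threshold)
    list(instrument = inst,
         estimates = mr_all_methods(inst, n_boot = n_boot, seed = s))
  }
  list(
    forward = run_dir(study_a, study_b, derive_seed(seed, 1L)),
    reverse = run_dir(study_b, study_a, derive_seed(seed, 2L))
  )
}
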