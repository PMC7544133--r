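# Two-sample MR estimators. Estimates are carried on the log-odds scale;
# odds ratios are attached as derived columns at the reporting boundary.

new_mr_estimate <- function(method, beta, se, pvalue, n_snps,
                            q_stat = NA_real_, egger_intercept = NA_real_,
                            egger_intercept_p = NA_real_) {
  out <- tibble::tibble(
    method = method,
    n_snps = as.integer(n_snps),
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    or = exp(beta),
    or_ci_low = exp(beta - Z95 * se),
    or_ci_high = exp(beta + Z95 * se),
    pvalue = pvalue,
    q_stat = q_stat,
    egger_intercept = egger_intercept,
    egger_intercept_p = egger_intercept_p
  )
  structure(out, class = c("mr_estimate", class(out)))
}

#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::as_tibble(x)[c("method", "n_snps", "beta", "se", "ci_low", "ci_high",
                         "or", "or_ci_low", "or_ci_high", "pvalue")]
}

#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::as_tibble(x)[c("method", "n_snps", "q_stat", "egger_intercept",
                         "egger_intercept_p")]
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNP(s)\n", x$method[1], x$n_snps[1]))
  cat(sprintf("  log-OR %.4f (SE %.4f); OR %.3f (95%% CI %.3f-%.3f); p = %.3g\n",
              x$beta[1], x$se[1], x$or[1], x$or_ci_low[1], x$or_ci_high[1],
              x$pvalue[1]))
  if (is.finite(x$q_stat[1]))
    cat(sprintf("  Cochran's Q = %.2f on %d df\n", x$q_stat[1], x$n_snps[1] - 1L))
  if (is.finite(x$egger_intercept[1]))
    cat(sprintf("  Egger intercept %.4f (p = %.3g)\n",
                x$egger_intercept[1], x$egger_intercept_p[1]))
  invisible(x)
}

#' Single-variant Wald ratio
#'
#' The causal estimate from one variant: the outcome effect divided by the
#' exposure effect, with the first-order delta-method standard error
#' `|se_y / beta_x|` (exposure uncertainty ignored, appropriate for strong
#' instruments).
#'
#' @param beta_x,se_x Exposure effect and its SE.
#' @param beta_y,se_y Outcome effect and its SE.
#' @return An `mr_estimate` tibble (one row).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  assert_that(beta_x != 0, "beta_x must be nonzero")
  beta <- beta_y / beta_x
  se <- abs(se_y / beta_x)
  new_mr_estimate("wald", beta, se, two_sided_p(beta / se), 1L)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta)^2` with first-order weights
#' `w_j = (beta_x_j / se_y_j)^2`, measuring heterogeneity of the per-variant
#' Wald ratios around a pooled estimate. Under homogeneity Q is approximately
#' chi-squared with `k - 1` degrees of freedom.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble (>= 2 variants).
#' @param beta Pooled causal estimate the ratios are compared against;
#'   default the fixed-effect IVW estimate.
#' @return The Q statistic (scalar).
#' @export
cochran_q <- function(inst, beta = NULL) {
  assert_that(nrow(inst) >= 2, "need at least 2 variants")
  w <- (inst$beta_exposure / inst$se_outcome)^2
  ratio <- inst$beta_outcome / inst$beta_exposure
  if (is.null(beta)) beta <- sum(w * ratio) / sum(w)
  sum(w * (ratio - beta)^2)
}

#' Inverse-variance-weighted MR estimate
#'
#' The primary two-sample MR estimator: the precision-weighted average of
#' per-variant Wald ratios, `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`.
#' The fixed-effect SE is `sqrt(1 / sum(bx^2 / sy^2))`; under the
#' multiplicative random-effects model (the default) it is inflated by
#' `max(1, sqrt(Q / (k - 1)))` to account for heterogeneity. A single
#' variant reduces to the Wald ratio with a warning.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` tibble (one row) with `q_stat` populated.
#' @export
mr_ivw <- function(inst, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  k <- nrow(inst)
  assert_that(k >= 1, "empty instrument")
  if (k == 1L) {
    warning("single-variant instrument: IVW reduces to the Wald ratio", call. = FALSE)
    est <- wald_ratio(inst$beta_exposure, inst$se_exposure,
                      inst$beta_outcome, inst$se_outcome)
    est$method <- "ivw"
    return(est)
  }
  w <- (inst$beta_exposure / inst$se_outcome)^2
  ratio <- inst$beta_outcome / inst$beta_exposure
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  if (model == "multiplicative_random") {
    se <- se * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate("ivw", beta, se, two_sided_p(beta / se), k, q_stat = q)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept, each variant first oriented so its exposure
#' effect is non-negative, weights `1 / se_y^2`. The slope estimates the
#' causal effect allowing directional pleiotropy; the intercept estimates
#' the average directional pleiotropic effect and its two-sided test is the
#' Egger pleiotropy test. Standard errors carry a multiplicative
#' overdispersion factor bounded below by 1; p-values use t with `k - 2`
#' degrees of freedom.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble with >= 3
#'   variants.
#' @return An `mr_estimate` tibble (one row) with `egger_intercept` and
#'   `egger_intercept_p` populated.
#' @export
mr_egger <- function(inst) {
  k <- nrow(inst)
  assert_that(k >= 3, "MR-Egger needs at least 3 variants")
  flip <- sign(inst$beta_exposure)
  flip[flip == 0] <- 1
  bx <- inst$beta_exposure * flip
  by <- inst$beta_outcome * flip
  w <- 1 / inst$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma                      # sqrt(weighted RSS / (k - 2))
  disp <- max(1, sigma)                  # floor the dispersion at 1
  se_u <- sqrt(diag(sm$cov.unscaled))    # SEs at unit dispersion
  slope <- stats::coef(fit)[["bx"]]
  slope_se <- se_u[["bx"]] * disp
  icpt <- stats::coef(fit)[["(Intercept)"]]
  icpt_se <- se_u[["(Intercept)"]] * disp
  pt2 <- function(z) 2 * stats::pt(-abs(z), df = k - 2)
  new_mr_estimate("egger", slope, slope_se, pt2(slope / slope_se), k,
                  q_stat = cochran_q(inst),
                  egger_intercept = icpt,
                  egger_intercept_p = pt2(icpt / icpt_se))
}

#' Weighted-median MR estimate
#'
#' The weighted median of per-variant Wald ratios, consistent when variants
#' contributing at least half of the total weight are valid instruments.
#' Ratios are sorted and the estimate is the linear interpolation of the
#' weighted empirical CDF at 0.5, with normalized first-order weights
#' `(beta_x / se_y)^2`. The SE is the standard deviation of the estimate
#' over `n_boot` parametric bootstrap draws of the per-variant effects from
#' their stated standard errors.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble with >= 3
#'   variants.
#' @param n_boot Bootstrap replicates (default 1000, minimum 100).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` tibble (one row).
#' @export
mr_weighted_median <- function(inst, n_boot = 1000, seed = 1L) {
  k <- nrow(inst)
  assert_that(k >= 3, "weighted median needs at least 3 variants")
  assert_that(n_boot >= 100, "n_boot must be at least 100")
  w <- (inst$beta_exposure / inst$se_outcome)^2
  assert_that(any(w > 0), "all weights are zero")
  est <- weighted_median_point(inst$beta_outcome / inst$beta_exposure, w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, inst$beta_exposure, inst$se_exposure)
      by <- stats::rnorm(k, inst$beta_outcome, inst$se_outcome)
      wb <- (bx / inst$se_outcome)^2
      weighted_median_point(by / bx, wb)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_estimate("weighted_median", est, se, two_sided_p(est / se), k)
}

# Linear interpolation of the weighted empirical CDF at probability 0.5.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(r[1])
  if (0.5 >= cw[length(cw)]) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, ties = "ordered")$y
}

#' Rescale an MR estimate to different exposure units
#'
#' Converts a per-1-SD estimate to a per-`target_units` estimate (or any
#' linear rescaling of the exposure): the log-odds effect, its SE and CI
#' bounds are multiplied by `target_units / sd_units` and the odds-ratio
#' columns re-exponentiated. For example, a per-SD odds ratio with SD 9.28
#' cm rescaled to 10 cm raises every log-scale quantity to the power
#' 10/9.28.
#'
#' @param estimate An `mr_estimate` tibble.
#' @param sd_units The exposure SD in natural units (e.g. cm), `> 0`.
#' @param target_units The target increment in the same units, `> 0`.
#' @return The rescaled `mr_estimate`.
#' @export
scale_per_unit <- function(estimate, sd_units, target_units) {
  assert_that(sd_units > 0 && target_units > 0, "scales must be positive")
  f <- target_units / sd_units
  out <- estimate
  out$beta <- estimate$beta * f
  out$se <- estimate$se * f
  out$ci_low <- estimate$ci_low * f
  out$ci_high <- estimate$ci_high * f
  out$or <- exp(out$beta)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  out
}

#' Run the standard estimator battery on one instrument
#'
#' Convenience wrapper returning IVW, MR-Egger, weighted-median and (when
#' requested) MR-PRESSO results stacked in one tibble.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO simulations; `0` skips MR-PRESSO.
#' @param seed Integer seed for the stochastic estimators.
#' @param ivw_model Passed to [mr_ivw()].
#' @return An `mr_estimate` tibble with one row per method.
#' @export
mr_all_methods <- function(inst, n_boot = 1000, n_sim = 0, seed = 1L,
                           ivw_model = "multiplicative_random") {
  out <- list(
    mr_ivw(inst, model = ivw_model),
    mr_egger(inst),
    mr_weighted_median(inst, n_boot = n_boot, seed = seed)
  )
  if (n_sim > 0 && nrow(inst) >= 4) {
    pr <- mr_presso(inst, n_sim = n_sim, seed = derive_seed(seed, 7L))
    out <- c(out, list(pr$raw), if (!is.null(pr$corrected)) list(pr$corrected))
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("mr_estimate", class(tibble::tibble())))
}
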