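# Estimator-recovery benchmarks. Each function runs a replicate grid on
# the parametric summary-level simulator (or the individual-level cohort
# simulator where the estimator is individual-level) and reports recovery
# metrics against the planted truth. These back the package's validation
# suite and the reproducibility script.

#' IVW recovery benchmark
#'
#' Replicates a two-sample design with no pleiotropy at published-GWAS
#' scale and measures the mean bias of the IVW estimate on the log-odds
#' scale and the empirical coverage of its 95% CI.
#'
#' @param true_or True causal odds ratios per exposure SD (vector; one grid
#'   cell each).
#' @param n_reps Replicates per cell.
#' @param k Instrument variants per replicate.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_mr_summary()].
#' @return A tibble with one row per cell: `true_or`, `mean_est`,
#'   `mean_bias`, `coverage`, `mc_se`.
#' @export
benchmark_ivw_recovery <- function(true_or = c(1.0, 1.34, 2.0), n_reps = 200,
                                   k = 200, seed = 1L, ...) {
  purrr::map_dfr(true_or, function(or) {
    b0 <- log(or)
    res <- purrr::map_dfr(seq_len(n_reps), function(r) {
      inst <- simulate_mr_summary(k = k, causal_logor = b0, pleiotropy = "none",
                                  seed = derive_seed(seed, r * 17 + round(100 * or)),
                                  ...)
      est <- mr_ivw(inst)
      tibble::tibble(beta = est$beta,
                     covered = est$ci_low <= b0 & b0 <= est$ci_high)
    })
    tibble::tibble(true_or = or,
                   mean_est = mean(res$beta),
                   mean_bias = mean(res$beta) - b0,
                   coverage = mean(res$covered),
                   mc_se = stats::sd(res$beta) / sqrt(n_reps))
  })
}

#' MR-Egger pleiotropy-recovery benchmark
#'
#' Under balanced pleiotropy the mean Egger intercept should be about zero;
#' under directional pleiotropy with mean per-variant direct effect
#' `pleiotropy_mean` the mean intercept should recover that value and the
#' slope the true causal effect.
#'
#' @param pleiotropy `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect distribution.
#' @param true_or True causal OR per SD.
#' @param n_reps,k,seed Grid settings.
#' @return One-row tibble: `mean_intercept`, `intercept_mc_se`,
#'   `mean_slope`, `slope_mc_se`, `true_intercept`, `true_slope`.
#' @export
benchmark_egger <- function(pleiotropy = "directional", pleiotropy_mean = 0.02,
                            pleiotropy_sd = 0.01, true_or = 1.34,
                            n_reps = 200, k = 200, seed = 1L) {
  b0 <- log(true_or)
  res <- purrr::map_dfr(seq_len(n_reps), function(r) {
    inst <- simulate_mr_summary(k = k, causal_logor = b0,
                                pleiotropy = pleiotropy,
                                pleiotropy_mean = pleiotropy_mean,
                                pleiotropy_sd = pleiotropy_sd,
                                seed = derive_seed(seed, r * 23))
    est <- mr_egger(inst)
    tibble::tibble(intercept = est$egger_intercept, slope = est$beta)
  })
  tibble::tibble(
    mean_intercept = mean(res$intercept),
    intercept_mc_se = stats::sd(res$intercept) / sqrt(n_reps),
    mean_slope = mean(res$slope),
    slope_mc_se = stats::sd(res$slope) / sqrt(n_reps),
    true_intercept = if (pleiotropy == "directional") pleiotropy_mean else 0,
    true_slope = b0
  )
}

#' Weighted-median robustness benchmark
#'
#' A contaminated design: `prop_invalid` of the variants carry large
#' directional pleiotropy, so IVW is materially biased while the weighted
#' median (valid variants holding most of the weight) stays near the truth.
#' Instruments are strong (few variants, high variance explained) so the
#' per-variant ratio noise does not dominate the median.
#'
#' @param true_beta True causal log-odds per SD (default 0.3).
#' @param prop_invalid Fraction of invalid variants (default 0.4, planted
#'   exactly).
#' @param pleio_mean Mean direct effect of invalid variants (default 0.05).
#' @param n_cases,n_controls Outcome GWAS counts; the cell uses a large
#'   outcome study so per-variant ratio noise stays small relative to the
#'   contamination.
#' @param n_reps,k,total_r2,seed Grid settings.
#' @return One-row tibble with mean bias of the weighted median and of IVW.
#' @export
benchmark_weighted_median <- function(true_beta = 0.3, prop_invalid = 0.4,
                                      pleio_mean = 0.05, n_reps = 100,
                                      k = 50, total_r2 = 0.3,
                                      n_cases = 200000, n_controls = 800000,
                                      seed = 1L) {
  res <- purrr::map_dfr(seq_len(n_reps), function(r) {
    inst <- simulate_mr_summary(k = k, total_r2 = total_r2,
                                n_cases = n_cases, n_controls = n_controls,
                                causal_logor = true_beta,
                                pleiotropy = "directional",
                                pleiotropy_mean = pleio_mean,
                                pleiotropy_sd = pleio_mean / 5,
                                pleiotropy_prop = prop_invalid,
                                seed = derive_seed(seed, r * 29))
    wm <- mr_weighted_median(inst, n_boot = 200, seed = derive_seed(seed, r * 31))
    tibble::tibble(wm = wm$beta, ivw = mr_ivw(inst)$beta)
  })
  tibble::tibble(
    true_beta = true_beta,
    wm_bias = mean(res$wm) - true_beta,
    ivw_bias = mean(res$ivw) - true_beta,
    wm_mc_se = stats::sd(res$wm) / sqrt(n_reps)
  )
}

#' MR-PRESSO detection benchmark
#'
#' Clean cells (no pleiotropy) measure the fraction of replicates with no
#' outlier flagged; planted cells add one variant with a direct outcome
#' effect of `outlier_size` times its outcome SE and measure the fraction
#' of replicates in which that variant is flagged and the fraction in
#' which the outlier-corrected estimate is closer to the truth than the
#' raw one.
#'
#' @param n_reps Replicates per cell.
#' @param k Variants per replicate.
#' @param n_sim MR-PRESSO simulations per replicate.
#' @param outlier_size Planted direct effect in units of the outcome SE.
#' @param true_or True causal OR per SD.
#' @param seed Integer seed.
#' @return One-row tibble: `clean_no_outlier_rate`, `planted_detection_rate`,
#'   `corrected_closer_rate`.
#' @export
benchmark_presso <- function(n_reps = 100, k = 50, n_sim = 2000,
                             outlier_size = 10, true_or = 1.34, seed = 1L) {
  b0 <- log(true_or)
  clean <- vapply(seq_len(n_reps), function(r) {
    inst <- simulate_mr_summary(k = k, causal_logor = b0, pleiotropy = "none",
                                seed = derive_seed(seed, r * 37))
    pr <- mr_presso(inst, n_sim = n_sim, seed = derive_seed(seed, r * 41))
    length(pr$outlier_indices) == 0
  }, logical(1))
  planted <- purrr::map_dfr(seq_len(n_reps), function(r) {
    inst <- simulate_mr_summary(k = k, causal_logor = b0, pleiotropy = "none",
                                seed = derive_seed(seed, r * 43))
    j <- 1L + (r %% k)
    inst$beta_outcome[j] <- inst$beta_outcome[j] + outlier_size * inst$se_outcome[j]
    pr <- mr_presso(inst, n_sim = n_sim, seed = derive_seed(seed, r * 47))
    hit <- j %in% pr$outlier_indices
    closer <- if (!is.null(pr$corrected)) {
      abs(pr$corrected$beta - b0) < abs(pr$raw$beta - b0)
    } else NA
    tibble::tibble(hit = hit, closer = closer)
  })
  tibble::tibble(
    clean_no_outlier_rate = mean(clean),
    planted_detection_rate = mean(planted$hit),
    corrected_closer_rate = mean(planted$closer, na.rm = TRUE)
  )
}

#' Multivariable-MR recovery benchmark
#'
#' Two correlated exposures with planted direct effects on the outcome;
#' measures mean recovery of both direct effects.
#'
#' @param true_effects Planted direct effects (length 2, default
#'   `c(0.29, 0.10)`).
#' @param exposure_cor Correlation of the two exposures' variant effects.
#' @param n_reps,k,seed Grid settings.
#' @return A tibble with one row per exposure: `true`, `mean_est`, `mc_se`.
#' @export
benchmark_mvmr <- function(true_effects = c(0.29, 0.10), exposure_cor = 0.3,
                           n_reps = 200, k = 150, seed = 1L) {
  n_exposure <- 693529
  n_cases <- 65446; n_controls <- 522744
  res <- purrr::map_dfr(seq_len(n_reps), function(r) {
    withr::with_seed(derive_seed(seed, r * 53), {
      maf <- stats::runif(k, 0.05, 0.5)
      het <- 2 * maf * (1 - maf)
      z1 <- stats::rnorm(k); z2 <- exposure_cor * z1 +
        sqrt(1 - exposure_cor^2) * stats::rnorm(k)
      bx1 <- z1 * sqrt(0.112 / sum(het * z1^2))
      bx2 <- z2 * sqrt(0.08 / sum(het * z2^2))
      se_x1 <- sqrt(1 / (n_exposure * het))
      se_y <- sqrt((1 / n_cases + 1 / n_controls) / het)
      by <- true_effects[1] * bx1 + true_effects[2] * bx2
      ids <- sprintf("rs%06d", seq_len(k))
      fit <- mr_mvmr(
        list(exp1 = tibble::tibble(variant_id = ids,
                                   beta = stats::rnorm(k, bx1, se_x1), se = se_x1),
             exp2 = tibble::tibble(variant_id = ids,
                                   beta = stats::rnorm(k, bx2, se_x1), se = se_x1)),
        tibble::tibble(variant_id = ids,
                       beta = stats::rnorm(k, by, se_y), se = se_y)
      )
      tibble::tibble(exposure = fit$exposure, est = fit$beta)
    })
  })
  out <- dplyr::summarise(dplyr::group_by(res, .data$exposure),
                          mean_est = mean(.data$est),
                          mc_se = stats::sd(.data$est) / sqrt(n_reps),
                          .groups = "drop")
  out$true <- true_effects[match(out$exposure, c("exp1", "exp2"))]
  out
}

#' Two-stage individual-level MR recovery benchmark
#'
#' Simulates cohorts with a planted causal odds ratio per exposure SD and
#' runs the full GRS + two-stage pipeline on each.
#'
#' @param true_or Planted causal OR per SD (default 1.75).
#' @param n_reps Replicates.
#' @param n_cohort Cohort size per replicate.
#' @param seed Integer seed.
#' @param ... Additional [sim_config()] overrides.
#' @return One-row tibble: `true_or`, `mean_or`, `mean_beta`, `mc_se`
#'   (log scale).
#' @export
benchmark_two_stage <- function(true_or = 1.75, n_reps = 100, n_cohort = 6000,
                                seed = 1L, ...) {
  betas <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(causal_logor_per_sd = log(true_or),
                      pleiotropy = "none", n_cohort = n_cohort,
                      seed = derive_seed(seed, r * 59), ...)
    sim <- simulate_cohort(cfg)
    grs <- compute_grs(sim$dosages,
                       stats::setNames(sim$truth$beta_exposure,
                                       sim$variants$variant_id))
    two_stage_mr(sim$cohort, grs)$beta_per_sd
  }, numeric(1))
  tibble::tibble(true_or = true_or, mean_or = exp(mean(betas)),
                 mean_beta = mean(betas),
                 mc_se = stats::sd(betas) / sqrt(n_reps))
}

#' PheWAS error-control and power benchmark
#'
#' Null cells: `n_null` phenotypes independent of the predictor per
#' replicate; the family-wise error is the fraction of replicates with any
#' Bonferroni-significant null phenotype. Power cell: one phenotype
#' generated with odds ratio `power_or` per SD of the predictor; power is
#' the fraction of replicates where its p-value falls below the
#' study-scale Bonferroni threshold `0.05 / 1816`.
#'
#' @param n_reps_null,n_null,n_null_sample Null-grid settings.
#' @param n_reps_power,power_or,power_n,power_prev Power-grid settings.
#' @param seed Integer seed.
#' @return One-row tibble: `fwer`, `power`, `n_reps_null`, `n_reps_power`.
#' @export
benchmark_phewas <- function(n_reps_null = 50, n_null = 100,
                             n_null_sample = 2000, n_reps_power = 20,
                             power_or = 1.5, power_n = 6000,
                             power_prev = 0.3, seed = 1L) {
  make_base <- function(n, s) {
    withr::with_seed(s, {
      tibble::tibble(
        id = sprintf("i%05d", seq_len(n)),
        age = round(stats::runif(n, 30, 85)),
        sex = stats::rbinom(n, 1, 0.5),
        PC1 = stats::rnorm(n), PC2 = stats::rnorm(n),
        pred = as.numeric(scale(stats::rnorm(n)))
      )
    })
  }
  null_hits <- vapply(seq_len(n_reps_null), function(r) {
    base <- make_base(n_null_sample, derive_seed(seed, r * 61))
    asg <- withr::with_seed(derive_seed(seed, r * 67), {
      purrr::map_dfr(seq_len(n_null), function(ph) {
        tibble::tibble(phecode = sprintf("%03d", ph),
                       label = sprintf("null phenotype %d", ph),
                       id = base$id,
                       status = ifelse(stats::rbinom(n_null_sample, 1, 0.3) == 1,
                                       "case", "control"))
      })
    })
    res <- run_phewas(base, base$pred, asg, n_pcs = 2)
    any(res$significant_bonferroni)
  }, logical(1))

  bonf <- bonferroni_threshold(0.05, 1816)
  power_hits <- vapply(seq_len(n_reps_power), function(r) {
    base <- make_base(power_n, derive_seed(seed, r * 71))
    asg <- withr::with_seed(derive_seed(seed, r * 73), {
      alpha0 <- stats::qlogis(power_prev)
      y <- stats::rbinom(power_n, 1, stats::plogis(alpha0 + log(power_or) * base$pred))
      planted <- tibble::tibble(phecode = "427", label = "planted phenotype",
                                id = base$id,
                                status = ifelse(y == 1, "case", "control"))
      nulls <- purrr::map_dfr(1:5, function(ph) {
        tibble::tibble(phecode = sprintf("n%02d", ph),
                       label = sprintf("null phenotype %d", ph),
                       id = base$id,
                       status = ifelse(stats::rbinom(power_n, 1, 0.3) == 1,
                                       "case", "control"))
      })
      dplyr::bind_rows(planted, nulls)
    })
    res <- run_phewas(base, base$pred, asg, n_pcs = 2)
    res$pvalue[res$phecode == "427"] < bonf
  }, logical(1))

  tibble::tibble(fwer = mean(null_hits), power = mean(power_hits),
                 n_reps_null = n_reps_null, n_reps_power = n_reps_power)
}
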