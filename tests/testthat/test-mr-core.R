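# Shared fixture: a moderate clean instrument at published-GWAS scale.
clean_inst <- simulate_mr_summary(k = 60, causal_logor = 0.3,
                                  pleiotropy = "none", seed = 101)

test_that("wald ratio arithmetic and delta-method SE", {
  est <- wald_ratio(0.1, 0.005, 0.05, 0.01)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.005, 0, 0.01)$beta, 0)
  expect_error(wald_ratio(0, 0.005, 0.05, 0.01), "nonzero")

  # Monte-Carlo oracle for the ratio SE at strong instrument strength
  mc <- withr::with_seed(77, {
    bx <- stats::rnorm(1e5, 0.1, 0.005)
    by <- stats::rnorm(1e5, 0.05, 0.01)
    stats::sd(by / bx)
  })
  expect_equal(est$se, mc, tolerance = 0.1)
})

test_that("IVW reduces to the Wald ratio and pools replicated variants", {
  one <- clean_inst[1, ]
  expect_warning(est1 <- mr_ivw(one), "single-variant")
  w <- wald_ratio(one$beta_exposure, one$se_exposure,
                  one$beta_outcome, one$se_outcome)
  expect_equal(est1$beta, w$beta)
  expect_equal(est1$se, w$se)

  k <- 9
  rep_inst <- clean_inst[rep(1, k), ]
  estk <- mr_ivw(rep_inst, model = "fixed")
  expect_equal(estk$beta, w$beta)
  expect_equal(estk$se, w$se / sqrt(k))
})

test_that("IVW matches its closed form and the fixed SE never exceeds random", {
  w <- (clean_inst$beta_exposure / clean_inst$se_outcome)^2
  ratio <- clean_inst$beta_outcome / clean_inst$beta_exposure
  expect_equal(mr_ivw(clean_inst, model = "fixed")$beta,
               sum(w * ratio) / sum(w))
  expect_lte(mr_ivw(clean_inst, model = "fixed")$se,
             mr_ivw(clean_inst, model = "multiplicative_random")$se)
})

test_that("estimators are invariant to ordering and per-variant sign flips", {
  withr::with_seed(13, {
    perm <- sample(nrow(clean_inst))
    flip <- stats::runif(nrow(clean_inst)) < 0.5
  })
  flipped <- clean_inst
  flipped$beta_exposure[flip] <- -flipped$beta_exposure[flip]
  flipped$beta_outcome[flip] <- -flipped$beta_outcome[flip]
  variants <- list(clean_inst[perm, ], flipped)
  for (v in variants) {
    expect_equal(mr_ivw(v)$beta, mr_ivw(clean_inst)$beta)
    expect_equal(mr_egger(v)$beta, mr_egger(clean_inst)$beta)
    expect_equal(mr_weighted_median(v, n_boot = 100, seed = 5)$beta,
                 mr_weighted_median(clean_inst, n_boot = 100, seed = 5)$beta,
                 tolerance = 1e-8)
  }
})

test_that("Egger recovers a perfect line exactly and needs 3 variants", {
  inst <- clean_inst[1:6, ]
  inst$beta_exposure <- c(0.02, 0.02, 0.04, 0.04, 0.06, 0.06)
  inst$beta_outcome <- 0.01 + 0.5 * inst$beta_exposure
  est <- mr_egger(inst)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-10)
  expect_error(mr_egger(clean_inst[1:2, ]), "3 variants")
})

test_that("weighted median handles its degenerate weight configurations", {
  inst <- clean_inst[1:3, ]
  inst$beta_exposure <- c(0.1, 0.1, 0.1)
  inst$se_outcome <- c(0.01, 0.01, 0.01)
  inst$beta_outcome <- c(0.02, 0.05, 0.09)      # ratios 0.2, 0.5, 0.9
  est <- mr_weighted_median(inst, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.5)

  dom <- inst
  dom$se_outcome <- c(1000, 1000, 0.001)        # one dominant weight
  expect_equal(mr_weighted_median(dom, n_boot = 100, seed = 1)$beta, 0.9)
  expect_error(mr_weighted_median(inst[1:2, ], n_boot = 100, seed = 1),
               "3 variants")
})

test_that("Cochran's Q is zero under homogeneity, chi-square distributed, and outlier-sensitive", {
  inst <- clean_inst[1:5, ]
  inst$beta_outcome <- 0.4 * inst$beta_exposure  # identical ratios
  expect_equal(cochran_q(inst), 0, tolerance = 1e-20)

  withr::with_seed(21, {
    k <- 15
    qs <- vapply(1:300, function(r) {
      i2 <- simulate_mr_summary(k = k, causal_logor = 0.3, pleiotropy = "none",
                                seed = 7000 + r)
      cochran_q(i2)
    }, numeric(1))
  })
  expect_equal(mean(qs), k - 1, tolerance = 0.1)

  outlier <- clean_inst
  outlier$beta_outcome[1] <- outlier$beta_outcome[1] + 20 * outlier$se_outcome[1]
  expect_gt(cochran_q(outlier), cochran_q(clean_inst))
})

test_that("scale conversion reproduces the published per-10cm arithmetic", {
  # per-SD OR 1.34 with upper bound 1.40 and height SD 9.28 cm
  est <- local({
    beta <- log(1.34); se <- (log(1.40) - log(1.34)) / 1.959964
    mrpipe:::new_mr_estimate("ivw", beta, se, 1e-42, 707L)
  })
  per10 <- scale_per_unit(est, sd_units = 9.28, target_units = 10)
  expect_equal(round(per10$or, 2), 1.37)
  expect_equal(round(per10$or_ci_high, 2), 1.44)
  expect_equal(scale_per_unit(est, 9.28, 9.28)$or, est$or)
  expect_error(scale_per_unit(est, 0, 10), "positive")
})

test_that("MR-PRESSO respects the empirical-p convention and flags a planted outlier", {
  inst <- simulate_mr_summary(k = 30, causal_logor = 0.3, pleiotropy = "none",
                              seed = 55)
  pr <- mr_presso(inst, n_sim = 1000, seed = 9)
  expect_gte(pr$global_p, 1 / 1001)
  expect_true(all(pr$per_snp_outlier_p > 0))
  expect_error(mr_presso(inst[1:3, ], n_sim = 1000, seed = 9), "4 variants")
  expect_warning(mr_presso(inst, n_sim = 500, seed = 9), "coarse")

  planted <- inst
  planted$beta_outcome[7] <- planted$beta_outcome[7] + 10 * planted$se_outcome[7]
  pr2 <- mr_presso(planted, n_sim = 2000, seed = 9)
  expect_true(7 %in% pr2$outlier_indices)
  expect_lt(pr2$global_p, 0.05)
  expect_false(is.null(pr2$corrected))
  expect_lt(abs(pr2$corrected$beta - 0.3), abs(pr2$raw$beta - 0.3))
})

test_that("MVMR solves an exact linear system and reduces to IVW", {
  ids <- sprintf("v%02d", 1:12)
  withr::with_seed(3, {
    bx1 <- stats::rnorm(12, 0.05, 0.02)
    bx2 <- stats::rnorm(12, 0.03, 0.02)
  })
  outcome <- tibble::tibble(variant_id = ids,
                            beta = 0.3 * bx1 + 0.2 * bx2, se = 0.01)
  fit <- mr_mvmr(list(height = tibble::tibble(variant_id = ids, beta = bx1, se = 0.002),
                      bmi = tibble::tibble(variant_id = ids, beta = bx2, se = 0.002)),
                 outcome)
  expect_equal(fit$beta, c(0.3, 0.2), tolerance = 1e-10)

  single <- mr_mvmr(list(height = tibble::tibble(variant_id = ids, beta = bx1,
                                                 se = 0.002)),
                    tibble::tibble(variant_id = ids,
                                   beta = 0.3 * bx1 + stats::rnorm(12, 0, 0.005),
                                   se = 0.01))
  ivw_equiv <- mr_ivw(tibble::tibble(beta_exposure = bx1, se_exposure = 0.002,
                                     beta_outcome = single$beta[1] * bx1,
                                     se_outcome = 0.01),
                      model = "fixed")
  expect_equal(single$beta[1], ivw_equiv$beta, tolerance = 1e-10)

  expect_error(
    mr_mvmr(list(a = tibble::tibble(variant_id = ids, beta = bx1, se = 0.002),
                 b = tibble::tibble(variant_id = ids, beta = 2 * bx1, se = 0.002)),
            outcome),
    "collinear")
})

test_that("bidirectional MR finds the forward effect and a null reverse effect", {
  cfg <- sim_config(n_variants = 40, instrument_r2 = 0.3, n_exposure = 8000,
                    n_outcome_cases = 1200, n_outcome_controls = 4000,
                    causal_logor_per_sd = 0.4, pleiotropy = "none",
                    n_outcome_variants = 8, outcome_variant_beta = 0.5,
                    seed = 23)
  ts <- simulate_two_sample(cfg)
  bd <- suppressWarnings(
    mr_bidirectional(ts$exposure, ts$outcome, ts$ld, n_boot = 100, seed = 2))
  fwd <- bd$forward$estimates
  ivw_fwd <- fwd[fwd$method == "ivw", ]
  expect_lt(abs(ivw_fwd$beta - 0.4), 4 * ivw_fwd$se)

  # the reverse instrument consists of the planted outcome-specific variants
  outcome_ids <- ts$sim$variants$variant_id[ts$sim$truth$outcome_specific]
  expect_true(all(bd$reverse$instrument$variant_id %in% outcome_ids))
  # those variants have no exposure effect: the reverse CI should cover 0
  ivw_rev <- bd$reverse$estimates[bd$reverse$estimates$method == "ivw", ]
  expect_lt(abs(ivw_rev$beta), 4 * ivw_rev$se)
})

test_that("single-exposure IVW, Egger slope and weighted median agree on clean data", {
  strong <- simulate_mr_summary(k = 150, causal_logor = 0.3, pleiotropy = "none",
                                seed = 303)
  ivw <- mr_ivw(strong)
  egg <- mr_egger(strong)
  wm <- mr_weighted_median(strong, n_boot = 200, seed = 4)
  joint_se <- sqrt(ivw$se^2 + egg$se^2)
  expect_lt(abs(ivw$beta - egg$beta), 3 * joint_se)
  expect_lt(abs(ivw$beta - wm$beta), 3 * sqrt(ivw$se^2 + wm$se^2))
})
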