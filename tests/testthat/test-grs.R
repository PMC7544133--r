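test_that("GRS degenerate and identity cases", {
  dos <- matrix(c(0, 1, 2, 2, 1, 0), ncol = 2,
                dimnames = list(NULL, c("v1", "v2")))
  expect_error(compute_grs(dos, c(v1 = 0, v2 = 0)), "zero variance")

  one <- compute_grs(dos[, 1, drop = FALSE], c(v1 = 1))
  expect_equal(one$standardized, as.numeric(scale(dos[, 1])))
  expect_lt(abs(mean(one$standardized)), 1e-10)
  expect_lt(abs(stats::sd(one$standardized) - 1), 1e-10)

  expect_error(compute_grs(dos, c(v1 = 1, v3 = 1)), "weight names")
})

test_that("GRS is invariant under simultaneous allele flip up to sign", {
  sim <- make_mini_cohort(n = 400, seed = 9)
  w <- stats::setNames(sim$truth$beta_exposure, sim$variants$variant_id)
  g1 <- compute_grs(sim$dosages, w)
  g2 <- compute_grs(2 - sim$dosages, -w)
  expect_equal(g1$standardized, g2$standardized)
})

test_that("a cohort GRS explains the configured share of exposure variance", {
  cfg <- sim_config(n_cohort = 20000, seed = 41)
  sim <- simulate_cohort(cfg)
  grs <- compute_grs(sim$dosages,
                     stats::setNames(sim$truth$beta_exposure,
                                     sim$variants$variant_id))
  r2 <- stats::cor(grs$standardized, sim$cohort$height)^2
  expect_equal(r2, 0.112, tolerance = 0.15)
})

test_that("two-stage MR recovers a planted effect and fails loudly when degenerate", {
  sim <- make_mini_cohort(n = 3000, seed = 13)
  grs <- compute_grs(sim$dosages,
                     stats::setNames(sim$truth$beta_exposure,
                                     sim$variants$variant_id))
  res <- two_stage_mr(sim$cohort, grs)
  expect_lt(abs(res$beta_per_sd - log(1.75)), 4 * res$se_per_sd)
  expect_true(res$ci_low < res$or_per_sd && res$or_per_sd < res$ci_high)
  expect_gt(res$stage1_r2, 0.05)

  # constant GRS must never return an estimate
  const_grs <- grs
  const_grs$standardized <- rep(0, nrow(const_grs))
  expect_error(two_stage_mr(sim$cohort, const_grs), "constant")

  # no outcome-negative rows
  all_case <- sim$cohort
  all_case$af <- 1L
  expect_error(two_stage_mr(all_case, grs), "outcome-negative")
})

test_that("model 2 runs on the left-atrial complete-case subset and reports exclusions", {
  sim <- make_mini_cohort(n = 2000, seed = 17)
  grs <- compute_grs(sim$dosages,
                     stats::setNames(sim$truth$beta_exposure,
                                     sim$variants$variant_id))
  m2 <- two_stage_mr(sim$cohort, grs, covariates = "left_atrial_diameter",
                     model_label = "model2_la_size")
  n_la <- sum(!is.na(sim$cohort$left_atrial_diameter))
  expect_equal(m2$n, n_la)
  expect_equal(m2$n_excluded, nrow(sim$cohort) - n_la)
})

test_that("per-10cm conversion of the individual-level estimate follows the cohort SD", {
  b <- log(1.75)
  est <- mrpipe:::new_mr_estimate("ivw", b, 0.068, 6e-5, 695L)
  per10 <- scale_per_unit(est, sd_units = 11, target_units = 10)
  expect_equal(round(per10$or, 2), 1.66)
})

test_that("pure-noise covariates barely move the two-stage estimate", {
  sim <- make_mini_cohort(n = 4000, seed = 29)
  cohort <- sim$cohort
  withr::with_seed(1, {
    cohort$noise1 <- stats::rnorm(nrow(cohort))
    cohort$noise2 <- stats::rbinom(nrow(cohort), 1, 0.5)
  })
  grs <- compute_grs(sim$dosages,
                     stats::setNames(sim$truth$beta_exposure,
                                     sim$variants$variant_id))
  base <- two_stage_mr(cohort, grs)
  noisy <- two_stage_mr(cohort, grs, covariates = c("noise1", "noise2"))
  expect_lt(abs(base$beta_per_sd - noisy$beta_per_sd), 0.5 * base$se_per_sd)
})

test_that("cohort summary reproduces printed count/percentage arithmetic", {
  # counts as printed in the motivating demographic table
  controls <- c(rep(1, 1799), rep(0, 3538 - 1799))
  cases <- c(rep(1, 2117), rep(0, 3029 - 2117))
  female_ctrl <- c(rep(1, 1577), rep(0, 3538 - 1577))
  female_case <- c(rep(1, 930), rep(0, 3029 - 930))
  cohort <- tibble::tibble(
    af = c(rep(0L, 3538), rep(1L, 3029)),
    hypertension = c(controls, cases),
    sex = c(female_ctrl, female_case)
  )
  tab <- summarize_cohort(cohort)
  htn <- tab[tab$characteristic == "hypertension", ]
  expect_equal(htn$percent_rounded[htn$stratum == "control"], 51)
  expect_equal(htn$percent_rounded[htn$stratum == "case"], 70)
  sex <- tab[tab$characteristic == "sex", ]
  expect_equal(sex$percent_rounded[sex$stratum == "case"], 31)
  expect_equal(sex$percent_rounded[sex$stratum == "control"], 45)
  expect_true(all(tab$pvalue > 0 & tab$pvalue <= 1))
})

test_that("Fisher's test on the symmetric 2x2 table gives p = 1 and strata must both exist", {
  cohort <- tibble::tibble(af = c(0L, 0L, 1L, 1L), flag = c(0L, 1L, 0L, 1L))
  tab <- summarize_cohort(cohort)
  expect_equal(tab$pvalue[tab$characteristic == "flag"][1], 1)
  expect_error(summarize_cohort(tibble::tibble(af = c(0L, 0L), flag = c(0L, 1L))),
               "cases and controls")
})

test_that("Wilcoxon p-values are near-uniform when strata share a distribution", {
  pvals <- vapply(1:60, function(r) {
    withr::with_seed(1000 + r, {
      cohort <- tibble::tibble(af = rep(c(0L, 1L), each = 60),
                               height = stats::rnorm(120, 170, 10))
    })
    summarize_cohort(cohort)$pvalue[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))  # rare tied p-values
  expect_gt(ks$p.value, 0.01)
})

test_that("continuous and binary characteristics are typed and stratified correctly", {
  sim <- make_mini_cohort(n = 500, seed = 53)
  tab <- summarize_cohort(sim$cohort)
  expect_true(all(c("height", "age", "hypertension", "smoking") %in%
                    tab$characteristic))
  expect_equal(tab$type[tab$characteristic == "height"][1], "continuous")
  expect_equal(tab$type[tab$characteristic == "smoking"][1], "binary")
  la <- tab[tab$characteristic == "left_atrial_diameter", ]
  expect_true(all(la$n < nrow(sim$cohort)))   # summarized over non-missing rows
})
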