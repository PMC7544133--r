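#' Simulation configuration
#'
#' Assembles and validates the ground-truth parameters of a synthetic MR
#' study: a polygenic quantitative exposure (height-like, in cm) with
#' independent causal variants, a binary outcome on the logistic scale with
#' a configurable causal effect of the standardized exposure, optional
#' horizontal pleiotropy (direct variant effects on the outcome, expressed
#' in the exposure-increasing allele orientation), an optional shared
#' confounder, and configurable sample sizes and exposure/outcome sample
#' overlap.
#'
#' Defaults are a desk-scale rendition of the motivating study design: 200
#' independent variants jointly explaining 11.2% of exposure variance, a
#' causal odds ratio of 1.34 per exposure SD, exposure GWAS n = 20,000,
#' outcome GWAS 2,000 cases / 8,000 controls under case-control sampling,
#' an individual-level cohort of 6,000 with outcome prevalence matching an
#' outcome-enriched biobank (0.46), population outcome prevalence 0.10,
#' exposure mean 170 cm and SD 11 cm.
#'
#' @param n_variants Number of independent instrument variants (>= 4).
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param instrument_r2 Share of exposure variance explained jointly by the
#'   variants, in (0,1).
#' @param causal_logor_per_sd True causal log-odds of the outcome per 1-SD
#'   exposure increase.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd Mean (directional only) and SD of
#'   per-variant direct outcome effects.
#' @param pleiotropy_prop Fraction of variants carrying pleiotropic
#'   effects.
#' @param confounder_exposure,confounder_outcome Effects of a standard-
#'   normal confounder on the standardized exposure and on the outcome
#'   log-odds.
#' @param prevalence Population outcome prevalence used for GWAS sampling.
#' @param cohort_prevalence Outcome prevalence in the individual-level
#'   cohort.
#' @param n_exposure,n_outcome_cases,n_outcome_controls,n_cohort Sample
#'   sizes.
#' @param overlap_fraction Fraction of the outcome GWAS sample drawn from
#'   the exposure GWAS sample.
#' @param n_outcome_variants Number of additional variants affecting the
#'   outcome directly but not the exposure (instruments for the reverse
#'   direction of a bidirectional analysis; default 0).
#' @param outcome_variant_beta Direct log-odds effect per allele of each
#'   outcome-specific variant.
#' @param exposure_mean,exposure_sd Exposure location/scale in natural
#'   units (cm).
#' @param la_missing Fraction of cohort rows with missing left atrial
#'   diameter.
#' @param seed Mandatory integer seed; the full dataset is a deterministic
#'   function of the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 200,
                       maf_range = c(0.05, 0.5),
                       instrument_r2 = 0.112,
                       causal_logor_per_sd = log(1.34),
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0.02,
                       pleiotropy_sd = 0.01,
                       pleiotropy_prop = 1,
                       confounder_exposure = 0,
                       confounder_outcome = 0,
                       prevalence = 0.10,
                       cohort_prevalence = 0.46,
                       n_exposure = 20000,
                       n_outcome_cases = 2000,
                       n_outcome_controls = 8000,
                       n_cohort = 6000,
                       overlap_fraction = 0,
                       n_outcome_variants = 0,
                       outcome_variant_beta = 0.35,
                       exposure_mean = 170,
                       exposure_sd = 11,
                       la_missing = 0.567,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  pleiotropy <- match.arg(pleiotropy)
  cfg <- list(
    n_variants = as.integer(n_variants), maf_range = maf_range,
    instrument_r2 = instrument_r2, causal_logor_per_sd = causal_logor_per_sd,
    pleiotropy = pleiotropy, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_prop = pleiotropy_prop,
    confounder_exposure = confounder_exposure,
    confounder_outcome = confounder_outcome,
    prevalence = prevalence, cohort_prevalence = cohort_prevalence,
    n_exposure = as.integer(n_exposure),
    n_outcome_cases = as.integer(n_outcome_cases),
    n_outcome_controls = as.integer(n_outcome_controls),
    n_cohort = as.integer(n_cohort), overlap_fraction = overlap_fraction,
    n_outcome_variants = as.integer(n_outcome_variants),
    outcome_variant_beta = outcome_variant_beta,
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    la_missing = la_missing, seed = as.integer(seed)
  )
  assert_that(cfg$n_variants >= 4, "need at least 4 variants")
  for (p in c("instrument_r2", "prevalence", "cohort_prevalence",
              "overlap_fraction", "pleiotropy_prop", "la_missing")) {
    assert_that(cfg[[p]] >= 0 && cfg[[p]] <= 1,
                paste0(p, " must lie in [0,1]"))
  }
  if (cfg$instrument_r2 + cfg$confounder_exposure^2 >= 0.95) {
    stop("infeasible configuration: instrument_r2 plus squared confounder ",
         "effect leaves no residual exposure variance", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Variant metadata: independent variants spaced 20 Mb apart across 22
# chromosomes so they are unlinked both by distance and by r2.
sim_variant_table <- function(m, maf) {
  chrom <- as.character(rep_len(1:22, m))
  idx_in_chr <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4, m, replace = TRUE)
  swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ea <- ifelse(swap, pairs[pick, 2], pairs[pick, 1])
  oa <- ifelse(swap, pairs[pick, 1], pairs[pick, 2])
  tibble::tibble(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chrom = chrom,
    pos = as.integer(1e6 + (idx_in_chr - 1) * 2e7),
    effect_allele = ea, other_allele = oa, maf = maf
  )
}

# Per-variant true effects on the standardized exposure, scaled so the
# variants jointly explain instrument_r2 of its variance. Effect alleles
# are oriented exposure-increasing (all betas >= 0), the convention under
# which directional pleiotropy is defined.
sim_true_effects <- function(cfg) {
  m <- cfg$n_variants
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  raw <- abs(stats::rnorm(m, 1, 0.3)) + 0.1
  var_raw <- 2 * maf * (1 - maf) * raw^2
  b <- raw * sqrt(cfg$instrument_r2 / sum(var_raw))
  pleio <- numeric(m)
  if (cfg$pleiotropy != "none") {
    hit <- sample.int(m, round(cfg$pleiotropy_prop * m))
    mu <- if (cfg$pleiotropy == "directional") cfg$pleiotropy_mean else 0
    pleio[hit] <- stats::rnorm(length(hit), mu, cfg$pleiotropy_sd)
  }
  # outcome-specific variants: no exposure effect, direct outcome effect
  m2 <- cfg$n_outcome_variants
  if (m2 > 0) {
    maf <- c(maf, stats::runif(m2, cfg$maf_range[1], cfg$maf_range[2]))
    b <- c(b, rep(0, m2))
    pleio <- c(pleio, rep(cfg$outcome_variant_beta, m2))
  }
  list(maf = maf, beta_exposure = b, pleio = pleio,
       outcome_specific = c(rep(FALSE, m), rep(TRUE, m2)))
}

# Solve the logistic intercept for a target prevalence given a linear
# predictor (without intercept).
solve_intercept <- function(eta, prevalence) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

simulate_population <- function(cfg, n, truth) {
  m <- length(truth$maf)
  g <- matrix(stats::rbinom(n * m, 2L, rep(truth$maf, each = n)), nrow = n)
  colnames(g) <- truth$variants$variant_id
  u <- stats::rnorm(n)
  genetic <- as.numeric(g %*% truth$beta_exposure)
  resid_sd <- sqrt(max(1 - cfg$instrument_r2 - cfg$confounder_exposure^2, 1e-8))
  z <- genetic - sum(2 * truth$maf * truth$beta_exposure) +
    cfg$confounder_exposure * u + stats::rnorm(n, 0, resid_sd)
  eta <- cfg$causal_logor_per_sd * z +
    as.numeric(g %*% truth$pleio) +
    cfg$confounder_outcome * u
  alpha <- solve_intercept(eta, cfg$prevalence)
  y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
  list(g = g, z = z, u = u, y = y, alpha = alpha)
}

#' Simulate an individual-level cohort with known ground truth
#'
#' Draws Hardy-Weinberg genotypes, builds the exposure (height, cm) from
#' the configured genetic architecture plus confounder and noise, draws the
#' binary outcome from a logistic model whose intercept is solved
#' numerically for the configured cohort prevalence, and attaches clinical
#' covariates: age, sex, BMI-derived weight, ten principal components
#' (independent standard normals), twelve binary comorbidities with
#' realistic prevalences and outcome associations, and a left-atrial-
#' diameter measurement associated with both height and the outcome, with
#' configurable missingness.
#'
#' @param cfg A [sim_config()].
#' @param n Cohort size; defaults to `cfg$n_cohort`.
#' @return A list of class `sim_cohort`: `cohort` (tibble), `dosages`
#'   (n x m matrix), `variants` (metadata tibble), `truth` (list of true
#'   parameters).
#' @export
simulate_cohort <- function(cfg, n = NULL) {
  n <- n %||% cfg$n_cohort
  withr::with_seed(derive_seed(cfg$seed, 101L), {
    eff <- sim_true_effects(cfg)
    variants <- sim_variant_table(length(eff$maf), eff$maf)
    truth <- c(eff, list(variants = variants,
                         causal_logor_per_sd = cfg$causal_logor_per_sd,
                         confounder_exposure = cfg$confounder_exposure,
                         confounder_outcome = cfg$confounder_outcome))
    cfg_cohort <- cfg
    cfg_cohort$prevalence <- cfg$cohort_prevalence
    pop <- simulate_population(cfg_cohort, n, truth)

    height <- cfg$exposure_mean + cfg$exposure_sd * pop$z
    age <- pmin(pmax(round(stats::rnorm(n, 63, 13)), 18), 95)
    sex <- stats::rbinom(n, 1L, 0.38)          # 1 = female
    bmi <- pmin(pmax(stats::rnorm(n, 29, 6), 15), 60)
    weight <- bmi * (height / 100)^2
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))

    comorb_prev <- c(hypertension = 0.51, coronary_artery_disease = 0.49,
                     heart_failure = 0.27, hyperlipidemia = 0.52,
                     diabetes = 0.17, chronic_kidney_disease = 0.11,
                     sleep_apnea = 0.12, stroke = 0.16,
                     thyroid_disease = 0.02, cardiac_surgery = 0.23,
                     valve_disease = 0.25, smoking = 0.47)
    comorb_assoc <- c(hypertension = 0.8, coronary_artery_disease = 0.4,
                      heart_failure = 1.2, hyperlipidemia = 0.5,
                      diabetes = 0, chronic_kidney_disease = 0.6,
                      sleep_apnea = 0.7, stroke = 0.5,
                      thyroid_disease = 0.3, cardiac_surgery = 1.9,
                      valve_disease = 0.9, smoking = 0.15)
    comorb <- purrr::imap(comorb_prev, function(p0, nm) {
      stats::rbinom(n, 1L, stats::plogis(stats::qlogis(p0) + comorb_assoc[[nm]] * pop$y))
    })

    la <- 3.92 + 0.02 * (height - cfg$exposure_mean) + 0.45 * pop$y +
      stats::rnorm(n, 0, 0.75)
    la[stats::runif(n) < cfg$la_missing] <- NA_real_

    cohort <- tibble::tibble(
      id = sprintf("ind%05d", seq_len(n)),
      age = age, sex = sex, height = height, weight = weight,
      af = pop$y, left_atrial_diameter = la,
      !!!comorb
    )
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(pcs))
    rownames(pop$g) <- cohort$id
    structure(list(cohort = cohort, dosages = pop$g, variants = variants,
                   truth = truth, config = cfg),
              class = "sim_cohort")
  })
}

#' Marginal GWAS summary statistics from a simulated sample
#'
#' Computes per-variant marginal association estimates on a chosen subset
#' of a simulated sample: simple linear regression of the exposure on
#' dosage for `trait = "exposure"`, univariable logistic regression of the
#' outcome on dosage for `trait = "outcome"`. Allele frequencies are taken
#' from the subset. Monomorphic variants are emitted with `beta = 0`, a
#' sentinel large SE and `pvalue = 1`, and are listed in the `monomorphic`
#' attribute.
#'
#' Exposure effects are reported per SD of the exposure within the subset
#' (`standardize = TRUE`, the reporting convention of large anthropometric
#' GWAS); outcome effects are log-odds per allele.
#'
#' @param sim A `sim_cohort` (or the population object from
#'   [simulate_two_sample()]).
#' @param trait `"exposure"` or `"outcome"`.
#' @param sample_ids Row ids (or integer indices) of the subset; default
#'   all.
#' @param standardize Report exposure effects on the per-SD scale (default
#'   TRUE; ignored for the outcome).
#' @return A canonical summary-statistic tibble.
#' @export
summary_stats_from_cohort <- function(sim, trait = c("exposure", "outcome"),
                                      sample_ids = NULL, standardize = TRUE) {
  trait <- match.arg(trait)
  g <- sim$dosages
  y <- if (trait == "exposure") sim$cohort$height else sim$cohort$af
  if (!is.null(sample_ids)) {
    idx <- if (is.numeric(sample_ids)) sample_ids else match(sample_ids, rownames(g))
    assert_that(length(idx) > 0 && !anyNA(idx), "empty or unknown sample subset")
    g <- g[idx, , drop = FALSE]
    y <- y[idx]
  }
  if (trait == "exposure" && standardize) y <- as.numeric(scale(y))
  n <- nrow(g)
  m <- ncol(g)
  eaf <- colMeans(g) / 2
  mono <- apply(g, 2, stats::var) == 0
  beta <- se <- pval <- numeric(m)
  if (trait == "exposure") {
    gc <- sweep(g, 2, colMeans(g))
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    sxy <- colSums(gc * yc)
    beta <- ifelse(mono, 0, sxy / sxx)
    se <- ifelse(mono, stats::sd(y) * sqrt(n),
                 sqrt((sum(yc^2) - beta * sxy) / (n - 2) / sxx))
    pval <- ifelse(mono, 1, 2 * stats::pt(-abs(beta / se), df = n - 2))
  } else {
    for (j in seq_len(m)) {
      if (mono[j]) {
        beta[j] <- 0; se[j] <- stats::sd(y) * sqrt(n); pval[j] <- 1
        next
      }
      fit <- stats::glm.fit(cbind(1, g[, j]), y, family = stats::binomial())
      cf <- fit$coefficients[2]
      vc <- chol2inv(chol(crossprod(cbind(1, g[, j]) *
                                      sqrt(fit$weights))))
      beta[j] <- cf
      se[j] <- sqrt(vc[2, 2])
      pval[j] <- two_sided_p(cf / se[j])
    }
  }
  out <- tibble::tibble(
    variant_id = sim$variants$variant_id,
    chrom = sim$variants$chrom,
    pos = sim$variants$pos,
    effect_allele = sim$variants$effect_allele,
    other_allele = sim$variants$other_allele,
    eaf = unname(eaf), beta = unname(beta), se = unname(se),
    pvalue = unname(pmax(pmin(pval, 1), 1e-320)),
    n = n
  )
  if (any(mono)) {
    warning(sum(mono), " monomorphic variant(s) emitted with beta = 0", call. = FALSE)
  }
  set_attr(out, "monomorphic", sim$variants$variant_id[mono])
}

#' Empirical LD panel from simulated dosages
#'
#' @param sim A `sim_cohort`.
#' @return An `ld_panel` of squared Pearson correlations of dosages.
#' @export
make_ld_panel <- function(sim) {
  ld_panel_from_dosages(sim$dosages, sim$variants)
}

#' Simulate a two-sample GWAS pair with controlled overlap
#'
#' Generates one population large enough to supply the exposure GWAS sample
#' and a case-control outcome GWAS sample (cases oversampled to the
#' configured counts), computes both sets of marginal summary statistics,
#' and returns them with an empirical LD panel and the ground truth. The
#' configured `overlap_fraction` of the outcome sample (stratified by
#' case status) is drawn from within the exposure sample.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_two_sample`: `exposure`, `outcome`
#'   (canonical summary-statistic tibbles), `ld` (an `ld_panel`), `truth`,
#'   `overlap_ids` (ids in both samples), and `sim` (the underlying
#'   population, a `sim_cohort`).
#' @export
simulate_two_sample <- function(cfg) {
  n_out <- cfg$n_outcome_cases + cfg$n_outcome_controls
  n_extra <- ceiling(cfg$n_outcome_cases / max(cfg$prevalence, 0.01) * 1.6) +
    cfg$n_outcome_controls
  n_pop <- cfg$n_exposure + n_extra
  cfg_pop <- cfg
  cfg_pop$cohort_prevalence <- cfg$prevalence  # population-scale prevalence
  sim <- simulate_cohort(cfg_pop, n = n_pop)

  withr::with_seed(derive_seed(cfg$seed, 202L), {
    y <- sim$cohort$af
    exp_idx <- seq_len(cfg$n_exposure)
    pool_idx <- setdiff(seq_len(n_pop), exp_idx)
    pick <- function(from, k, what) {
      if (length(from) < k) {
        stop("insufficient ", what, " in simulated population (have ",
             length(from), ", need ", k, "); increase the pool or prevalence",
             call. = FALSE)
      }
      sample(from, k)
    }
    n_case_in <- round(cfg$overlap_fraction * cfg$n_outcome_cases)
    n_ctrl_in <- round(cfg$overlap_fraction * cfg$n_outcome_controls)
    cases <- c(pick(exp_idx[y[exp_idx] == 1], n_case_in, "overlapping cases"),
               pick(pool_idx[y[pool_idx] == 1], cfg$n_outcome_cases - n_case_in,
                    "non-overlapping cases"))
    ctrls <- c(pick(exp_idx[y[exp_idx] == 0], n_ctrl_in, "overlapping controls"),
               pick(pool_idx[y[pool_idx] == 0], cfg$n_outcome_controls - n_ctrl_in,
                    "non-overlapping controls"))
    out_idx <- c(cases, ctrls)

    exposure <- summary_stats_from_cohort(sim, "exposure", exp_idx)
    outcome <- summary_stats_from_cohort(sim, "outcome", out_idx)
    structure(list(
      exposure = exposure, outcome = outcome,
      ld = make_ld_panel(sim), truth = sim$truth,
      overlap_ids = sim$cohort$id[intersect(exp_idx, out_idx)],
      sim = sim
    ), class = "sim_two_sample")
  })
}

#' Parametric summary-statistic simulator
#'
#' Draws a harmonized two-sample MR instrument directly at the summary
#' level: per-variant true exposure effects are scaled so the instrument
#' jointly explains `total_r2` of the exposure, observed effects are drawn
#' around their truth with the standard errors implied by the GWAS sample
#' sizes (linear for the exposure; case-control log-odds for the outcome),
#' and true outcome effects are `causal_logor * beta_exposure` plus any
#' configured pleiotropy. Effect alleles are oriented exposure-increasing.
#' This is the standard device for estimator-recovery experiments: a
#' replicate costs microseconds, so recovery grids can run at the sample
#' sizes of large published GWASs.
#'
#' @param k Number of instrument variants.
#' @param total_r2 Joint exposure variance explained.
#' @param n_exposure Exposure GWAS sample size (default 693,529).
#' @param n_cases,n_controls Outcome GWAS counts (defaults 65,446 and
#'   522,744).
#' @param causal_logor True causal log-odds per exposure SD.
#' @param pleiotropy,pleiotropy_mean,pleiotropy_sd,pleiotropy_prop As in
#'   [sim_config()].
#' @param maf_range Uniform MAF range.
#' @param seed Integer seed.
#' @return An `mr_instrument` tibble; true parameters are in the `truth`
#'   attribute.
#' @export
simulate_mr_summary <- function(k = 200, total_r2 = 0.112,
                                n_exposure = 693529,
                                n_cases = 65446, n_controls = 522744,
                                causal_logor = log(1.34),
                                pleiotropy = c("none", "balanced", "directional"),
                                pleiotropy_mean = 0.02, pleiotropy_sd = 0.01,
                                pleiotropy_prop = 1,
                                maf_range = c(0.05, 0.5), seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  withr::with_seed(seed, {
    maf <- stats::runif(k, maf_range[1], maf_range[2])
    raw <- abs(stats::rnorm(k, 1, 0.3)) + 0.1
    het <- 2 * maf * (1 - maf)
    bx <- raw * sqrt(total_r2 / sum(het * raw^2))
    r2j <- het * bx^2
    se_x <- sqrt((1 - r2j) / (n_exposure * het))
    se_y <- sqrt((1 / n_cases + 1 / n_controls) / het)
    pleio <- numeric(k)
    if (pleiotropy != "none") {
      hit <- sample.int(k, round(pleiotropy_prop * k))
      mu <- if (pleiotropy == "directional") pleiotropy_mean else 0
      pleio[hit] <- stats::rnorm(length(hit), mu, pleiotropy_sd)
    }
    by <- causal_logor * bx + pleio
    bx_hat <- stats::rnorm(k, bx, se_x)
    by_hat <- stats::rnorm(k, by, se_y)
    variants <- sim_variant_table(k, maf)
    h <- tibble::tibble(
      variant_id = variants$variant_id, chrom = variants$chrom,
      pos = variants$pos, effect_allele = variants$effect_allele,
      other_allele = variants$other_allele,
      beta_exposure = bx_hat, se_exposure = se_x,
      pvalue_exposure = two_sided_p(bx_hat / se_x),
      n_exposure = as.integer(n_exposure),
      eaf_exposure = maf,
      beta_outcome = by_hat, se_outcome = se_y, eaf_outcome = maf,
      action = "unchanged"
    )
    h <- structure(h, class = c("mr_harmonized", class(tibble::tibble())))
    inst <- as_mr_instrument(h)
    set_attr(inst, "truth", list(
      beta_exposure = bx, beta_outcome = by, pleio = pleio,
      causal_logor = causal_logor, maf = maf
    ))
  })
}
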