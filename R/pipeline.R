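#' Resolve a run configuration
#'
#' Materializes every default of the analysis pipeline into one list so a
#' run is reproducible from the persisted configuration alone. Defaults
#' follow the motivating study design: genome-wide significance 5e-8,
#' clumping window 10,000 kb at r-squared 0.001, nominal confounder
#' exclusion at 0.05, family-wise alpha 0.05, multiplicative-random-effects
#' IVW, 1,000 weighted-median bootstrap draws, 5,000 MR-PRESSO simulations,
#' exposure SD 9.28 cm rescaled to 10 cm.
#'
#' @param ... Overrides of any default.
#' @return A list of class `mr_run_config`.
#' @export
mr_run_config <- function(...) {
  cfg <- list(
    p_threshold = 5e-8,
    window_kb = 10000,
    r2_threshold = 0.001,
    palindrome_eaf_limit = 0.42,
    nominal_p = 0.05,
    alpha = 0.05,
    ivw_model = "multiplicative_random",
    n_boot = 1000,
    n_sim = 5000,
    seed = 1L,
    sd_units = 9.28,
    target_units = 10,
    n_pcs_mr = 6,
    n_pcs_phewas = 10,
    min_cases = 20,
    run_bidirectional = TRUE,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0,
              paste0("unknown configuration field(s): ",
                     paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "mr_run_config")
}

write_pipeline_output <- function(obj, name, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.data.frame(obj)) {
    readr::write_tsv(tibble::as_tibble(obj), file.path(out_dir, paste0(name, ".tsv")))
  } else {
    jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(NULL)
}

#' Run the full two-sample MR analysis sequence
#'
#' Orchestrates the summary-level pipeline: instrument construction
#' (threshold, clump, harmonize, strength metrics), the four primary
#' estimators (IVW, MR-Egger, weighted median, MR-PRESSO), per-10cm
#' rescaling of the IVW estimate, the restrictive instrument excluding
#' variants nominally associated with supplied confounder traits (rerun of
#' all estimators), multivariable MR (a bivariate model per confounder
#' exposure, then one combined model of the traits whose bivariate direct
#' effect had p < 0.05, always keeping the primary exposure), and
#' bidirectional MR. Variant-count changes between stages are recorded in
#' the returned `log`. When `config$out_dir` is set, every table is also
#' written as TSV/JSON.
#'
#' @param exposure,outcome Canonical summary-statistic tibbles.
#' @param ld An `ld_panel`.
#' @param confounder_studies Named list of summary-statistic tibbles for
#'   the confounder traits (optional).
#' @param mvmr_exposures Named list of summary-statistic tibbles for
#'   multivariable MR exposures (optional; effects must be allele-aligned
#'   with the exposure study).
#' @param config An [mr_run_config()].
#' @return A list of class `mr_two_sample_report`: `instrument`, `strength`,
#'   `estimates`, `estimates_per_unit`, `presso`, `restricted` (instrument +
#'   estimates), `mvmr` (bivariate + combined), `bidirectional`, `log`,
#'   `config`.
#' @export
run_two_sample <- function(exposure, outcome, ld, confounder_studies = list(),
                           mvmr_exposures = list(), config = mr_run_config()) {
  log <- list()
  note <- function(stage, msg) log[[stage]] <<- msg

  inst <- build_instrument(exposure, outcome, ld,
                           p_threshold = config$p_threshold,
                           window_kb = config$window_kb,
                           r2_threshold = config$r2_threshold,
                           palindrome_eaf_limit = config$palindrome_eaf_limit)
  note("instrument", sprintf("%d exposure variants -> %d instrument variants",
                             nrow(exposure), nrow(inst)))
  strength <- glance.mr_instrument(inst)
  estimates <- mr_all_methods(inst, n_boot = config$n_boot,
                              n_sim = config$n_sim, seed = config$seed,
                              ivw_model = config$ivw_model)
  presso <- mr_presso(inst, n_sim = config$n_sim,
                      seed = derive_seed(config$seed, 7L))
  per_unit <- scale_per_unit(estimates[estimates$method == "ivw", ],
                             config$sd_units, config$target_units)

  restricted <- NULL
  if (length(confounder_studies) > 0) {
    rinst <- restrict_instrument(inst, confounder_studies,
                                 nominal_p = config$nominal_p)
    note("restricted", sprintf("%d -> %d variants after confounder exclusion",
                               nrow(inst), nrow(rinst)))
    restricted <- list(
      instrument = rinst,
      strength = glance.mr_instrument(rinst),
      estimates = mr_all_methods(rinst, n_boot = config$n_boot,
                                 n_sim = config$n_sim,
                                 seed = derive_seed(config$seed, 11L),
                                 ivw_model = config$ivw_model),
      exclusions = attr(rinst, "exclusions")
    )
  }

  mvmr <- NULL
  if (length(mvmr_exposures) > 0) {
    exp_eff <- function(ss) tibble::tibble(variant_id = ss$variant_id,
                                           beta = ss$beta, se = ss$se)
    primary <- tibble::tibble(variant_id = inst$variant_id,
                              beta = inst$beta_exposure, se = inst$se_exposure)
    outcome_eff <- tibble::tibble(variant_id = inst$variant_id,
                                  beta = inst$beta_outcome, se = inst$se_outcome)
    bivariate <- purrr::imap(mvmr_exposures, function(ss, nm) {
      mr_mvmr(stats::setNames(list(primary, exp_eff(ss)), c("primary", nm)),
              outcome_eff)
    })
    direct_p <- purrr::imap_dbl(bivariate, function(fit, nm) {
      fit$pvalue[fit$exposure == nm]
    })
    selected <- names(direct_p)[direct_p < 0.05]
    note("mvmr", sprintf("combined model keeps %d of %d traits (p < 0.05): %s",
                         length(selected), length(mvmr_exposures),
                         paste(selected, collapse = ", ")))
    combined <- NULL
    if (length(selected) > 0) {
      combined <- mr_mvmr(
        c(list(primary = primary),
          stats::setNames(lapply(mvmr_exposures[selected], exp_eff), selected)),
        outcome_eff)
    }
    mvmr <- list(bivariate = dplyr::bind_rows(bivariate, .id = "model"),
                 selected = selected, combined = combined)
  }

  bidirectional <- NULL
  if (isTRUE(config$run_bidirectional)) {
    bidirectional <- tryCatch(
      mr_bidirectional(exposure, outcome, ld,
                       p_threshold = config$p_threshold,
                       window_kb = config$window_kb,
                       r2_threshold = config$r2_threshold,
                       n_boot = config$n_boot,
                       seed = derive_seed(config$seed, 19L)),
      error = function(e) {
        note("bidirectional", paste("skipped:", conditionMessage(e)))
        NULL
      })
  }

  report <- structure(list(
    instrument = inst, strength = strength, estimates = estimates,
    estimates_per_unit = per_unit, presso = presso, restricted = restricted,
    mvmr = mvmr, bidirectional = bidirectional, log = log,
    config = unclass(config)
  ), class = "mr_two_sample_report")

  if (!is.null(config$out_dir)) {
    write_pipeline_output(tibble::as_tibble(inst), "instrument", config$out_dir)
    write_pipeline_output(strength, "instrument_strength", config$out_dir)
    write_pipeline_output(tidy.mr_estimate(estimates), "mr_estimates", config$out_dir)
    write_pipeline_output(tidy.mr_estimate(per_unit), "mr_estimates_per_unit",
                          config$out_dir)
    write_pipeline_output(unclass(config), "resolved_config", config$out_dir)
    if (!is.null(restricted)) {
      write_pipeline_output(tidy.mr_estimate(restricted$estimates),
                            "mr_estimates_restricted", config$out_dir)
      write_pipeline_output(restricted$exclusions, "confounder_exclusions",
                            config$out_dir)
    }
    if (!is.null(mvmr)) {
      write_pipeline_output(mvmr$bivariate, "mvmr_bivariate", config$out_dir)
      if (!is.null(mvmr$combined)) {
        write_pipeline_output(mvmr$combined, "mvmr_combined", config$out_dir)
      }
    }
  }
  report
}

#' Run the individual-level analysis sequence
#'
#' Orchestrates the cohort pipeline: weighted standardized GRS, the
#' descriptive table stratified by outcome, PheWAS of measured exposure
#' and of the GRS, the three nested two-stage MR models (base; plus
#' clinical covariates; plus left atrial size on its complete-case
#' subset), an echo-subset sensitivity rerun of all three models on the
#' identical complete-case row set, and optional sex-stratified reruns of
#' the base model.
#'
#' @param cohort Cohort tibble (see [two_stage_mr()] for required
#'   columns).
#' @param dosages Dosage matrix, individuals x variants.
#' @param weights Named per-variant GRS weights aligned to the dosage
#'   columns' effect alleles.
#' @param assignments Phecode case/control assignments from
#'   [assign_case_control()] (optional; skips the PheWAS when NULL).
#' @param clinical_covariates Covariates for the second model (defaults to
#'   the twelve comorbidity columns).
#' @param sex_stratified Also fit the base model separately by sex.
#' @param config An [mr_run_config()].
#' @return A list of class `mr_individual_report`: `grs`, `demographics`,
#'   `phewas_height`, `phewas_grs`, `two_stage` (stacked models),
#'   `echo_subset`, `log`, `config`.
#' @export
run_individual <- function(cohort, dosages, weights, assignments = NULL,
                           clinical_covariates = c(
                             "hypertension", "coronary_artery_disease",
                             "heart_failure", "hyperlipidemia", "diabetes",
                             "chronic_kidney_disease", "sleep_apnea", "stroke",
                             "thyroid_disease", "cardiac_surgery",
                             "valve_disease", "smoking"),
                           sex_stratified = FALSE, config = mr_run_config()) {
  log <- list()
  grs <- compute_grs(dosages, weights)
  demographics <- summarize_cohort(cohort)

  phewas_height <- phewas_grs <- NULL
  if (!is.null(assignments)) {
    std_height <- as.numeric(scale(cohort$height))
    phewas_height <- run_phewas(cohort, std_height, assignments,
                                n_pcs = config$n_pcs_phewas,
                                min_cases = config$min_cases,
                                alpha = config$alpha)
    phewas_grs <- run_phewas(cohort, grs$standardized, assignments,
                             n_pcs = config$n_pcs_phewas,
                             min_cases = config$min_cases,
                             alpha = config$alpha)
  }

  fit_models <- function(data, grs_sub, suffix = "") {
    dplyr::bind_rows(
      two_stage_mr(data, grs_sub, n_pcs = config$n_pcs_mr,
                   model_label = paste0("base", suffix)),
      two_stage_mr(data, grs_sub, covariates = clinical_covariates,
                   n_pcs = config$n_pcs_mr,
                   model_label = paste0("model1_clinical", suffix)),
      two_stage_mr(data, grs_sub,
                   covariates = c(clinical_covariates, "left_atrial_diameter"),
                   n_pcs = config$n_pcs_mr,
                   model_label = paste0("model2_la_size", suffix))
    )
  }
  two_stage <- fit_models(cohort, grs)
  log$two_stage <- sprintf("model2 complete-case n = %d of %d",
                           two_stage$n[two_stage$model_label == "model2_la_size"],
                           nrow(cohort))

  echo_rows <- !is.na(cohort$left_atrial_diameter)
  echo_subset <- fit_models(cohort[echo_rows, , drop = FALSE],
                            grs[echo_rows, , drop = FALSE], "_echo")
  log$echo_subset <- sprintf("echo-subset n = %d", sum(echo_rows))

  if (sex_stratified) {
    for (s in unique(cohort$sex)) {
      rows <- cohort$sex == s
      two_stage <- dplyr::bind_rows(
        two_stage,
        two_stage_mr(cohort[rows, , drop = FALSE], grs[rows, , drop = FALSE],
                     n_pcs = config$n_pcs_mr,
                     model_label = sprintf("base_sex%s", s)))
    }
  }

  report <- structure(list(
    grs = grs, demographics = demographics, phewas_height = phewas_height,
    phewas_grs = phewas_grs, two_stage = two_stage, echo_subset = echo_subset,
    log = log, config = unclass(config)
  ), class = "mr_individual_report")

  if (!is.null(config$out_dir)) {
    write_pipeline_output(demographics, "demographics", config$out_dir)
    write_pipeline_output(two_stage, "two_stage_models", config$out_dir)
    write_pipeline_output(echo_subset, "two_stage_echo_subset", config$out_dir)
    if (!is.null(phewas_height)) {
      write_pipeline_output(tibble::as_tibble(phewas_height), "phewas_height",
                            config$out_dir)
      write_pipeline_output(tibble::as_tibble(phewas_grs), "phewas_grs",
                            config$out_dir)
    }
    write_pipeline_output(unclass(config), "resolved_config_individual",
                          config$out_dir)
  }
  report
}
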