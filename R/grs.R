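#' Weighted standardized genetic risk score
#'
#' Computes the per-individual weighted allele-dosage score `sum_j
#' dosage_ij * weight_j` (additive model, weights typically the exposure
#' GWAS effect sizes aligned to the dosage effect alleles), then
#' standardizes it to mean 0 and SD 1 within the cohort.
#'
#' @param dosages Numeric matrix of allele dosages in \[0,2\], individuals
#'   in rows, variants in columns; column names must match
#'   `names(weights)` when `weights` is named.
#' @param weights Numeric vector of per-variant weights, one per dosage
#'   column (matched by name when named, by position otherwise).
#' @return A tibble with columns `raw` and `standardized`.
#' @export
compute_grs <- function(dosages, weights) {
  if (!is.null(names(weights))) {
    assert_that(all(names(weights) %in% colnames(dosages)),
                "weight names not all present among dosage columns")
    dosages <- dosages[, names(weights), drop = FALSE]
  }
  assert_that(ncol(dosages) == length(weights),
              "dosage columns and weights differ in length")
  raw <- as.numeric(dosages %*% weights)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    stop("genetic risk score has zero variance; cannot standardize", call. = FALSE)
  }
  tibble::tibble(raw = raw, standardized = (raw - mean(raw)) / s)
}

#' Two-stage individual-level MR for a binary outcome
#'
#' Stage 1: linear regression of the exposure (e.g. height in cm) on the
#' standardized genetic risk score plus age, sex, the first `n_pcs`
#' principal components and any requested clinical covariates, fitted only
#' among outcome-negative individuals. Stage 2: logistic regression of the
#' outcome on the stage-1 fitted exposure (predicted for all individuals
#' from their own covariates) plus the same covariates, with
#' heteroskedasticity-robust (HC1 sandwich) standard errors. The fitted-
#' exposure coefficient is rescaled to a per-1-SD-of-exposure odds ratio
#' using the whole-cohort exposure SD.
#'
#' Rows missing any required covariate are excluded (counted in the
#' result); for the echocardiographic model this is the complete-case
#' subset with non-missing `left_atrial_diameter`.
#'
#' @param cohort Data frame with one row per individual: the outcome column
#'   (0/1), exposure column, `age`, `sex`, principal components `PC1..`,
#'   and any covariates named in `covariates`.
#' @param grs GRS tibble from [compute_grs()] (its `standardized` column is
#'   used), aligned row-for-row with `cohort`.
#' @param exposure,outcome Column names of the exposure and binary outcome
#'   (defaults `"height"`, `"af"`).
#' @param covariates Character vector of additional covariate column names
#'   adjusted for in both stages (default none).
#' @param n_pcs Number of principal components to adjust for (default 6).
#' @param model_label Free-text label stored in the result.
#' @return A one-row tibble of class `mr_two_stage`: `model_label`,
#'   `or_per_sd`, `ci_low`, `ci_high`, `beta_per_sd`, `se_per_sd`,
#'   `pvalue`, `n`, `n_excluded`, `stage1_r2`, `exposure_sd`.
#' @export
two_stage_mr <- function(cohort, grs, exposure = "height", outcome = "af",
                         covariates = character(), n_pcs = 6,
                         model_label = "base") {
  assert_that(nrow(cohort) == nrow(grs), "cohort and grs row counts differ")
  pc_cols <- paste0("PC", seq_len(n_pcs))
  assert_that(all(pc_cols %in% names(cohort)),
              paste0("cohort lacks principal components up to PC", n_pcs))
  needed <- c(exposure, outcome, "age", "sex", pc_cols, covariates)
  assert_that(all(needed %in% names(cohort)),
              paste0("cohort lacks column(s): ",
                     paste(setdiff(needed, names(cohort)), collapse = ", ")))
  df <- tibble::as_tibble(cohort[needed])
  names(df)[1:2] <- c(".exposure", ".outcome")
  df$.grs <- grs$standardized
  complete <- stats::complete.cases(df)
  n_excluded <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (stats::sd(df$.grs) == 0) {
    stop("genetic risk score is constant; two-stage fit impossible", call. = FALSE)
  }
  controls <- df[df$.outcome == 0, , drop = FALSE]
  if (nrow(controls) == 0L) stop("no outcome-negative individuals", call. = FALSE)

  covar_terms <- c("age", "sex", pc_cols, covariates)
  # constant columns (e.g. sex within a sex stratum) carry no information
  # and would alias the fits
  constant <- vapply(covar_terms, function(v) length(unique(df[[v]])) < 2, logical(1))
  covar_terms <- covar_terms[!constant]
  f1 <- stats::reformulate(c(".grs", covar_terms), response = ".exposure")
  stage1 <- stats::lm(f1, data = controls)
  stage1_r2 <- summary(stage1)$r.squared
  df$.fitted_exposure <- as.numeric(stats::predict(stage1, newdata = df))

  f2 <- stats::reformulate(c(".fitted_exposure", covar_terms), response = ".outcome")
  stage2 <- stats::glm(f2, data = df, family = stats::binomial())
  if (!stage2$converged || any(abs(stats::coef(stage2)) > 50, na.rm = TRUE)) {
    stop("stage-2 logistic fit did not converge (possible separation); ",
         "largest |coefficient| = ",
         signif(max(abs(stats::coef(stage2)), na.rm = TRUE), 3), call. = FALSE)
  }
  ct <- lmtest::coeftest(stage2, vcov. = sandwich::vcovHC(stage2, type = "HC1"))
  b <- ct[".fitted_exposure", "Estimate"]
  se <- ct[".fitted_exposure", "Std. Error"]
  sd_exp <- stats::sd(df$.exposure)   # whole-cohort exposure SD
  b_sd <- b * sd_exp
  se_sd <- se * sd_exp
  out <- tibble::tibble(
    model_label = model_label,
    or_per_sd = exp(b_sd),
    ci_low = exp(b_sd - Z95 * se_sd),
    ci_high = exp(b_sd + Z95 * se_sd),
    beta_per_sd = b_sd,
    se_per_sd = se_sd,
    pvalue = two_sided_p(b_sd / se_sd),
    n = nrow(df),
    n_excluded = n_excluded,
    stage1_r2 = stage1_r2,
    exposure_sd = sd_exp
  )
  structure(out, class = c("mr_two_stage", class(out)))
}

#' Cohort descriptive table stratified by outcome
#'
#' For each requested characteristic, reports mean (SD) per stratum with a
#' Wilcoxon rank-sum p-value for continuous variables, and n (%) per
#' stratum with a Fisher's exact p-value for binary variables; percentages
#' are computed within stratum and also given rounded to the nearest
#' integer. Variables with missing values are summarized over their
#' non-missing rows (the n used is reported).
#'
#' @param cohort Data frame with a binary outcome column and the
#'   characteristics to summarize.
#' @param outcome Name of the 0/1 outcome column (default `"af"`).
#' @param continuous,binary Character vectors of column names; defaults
#'   cover every numeric non-binary / 0-1 column other than the outcome and
#'   id/PC columns.
#' @return A tibble with one row per characteristic and stratum:
#'   `characteristic`, `type`, `stratum`, `n`, `mean`, `sd`, `count`,
#'   `percent`, `percent_rounded`, `pvalue`.
#' @export
summarize_cohort <- function(cohort, outcome = "af",
                             continuous = NULL, binary = NULL) {
  assert_that(outcome %in% names(cohort), "outcome column missing")
  y <- cohort[[outcome]]
  assert_that(!anyNA(y), "outcome must be defined for all rows")
  assert_that(sum(y == 1) > 0 && sum(y == 0) > 0,
              "need both cases and controls")
  skip <- c(outcome, "id", grep("^PC[0-9]+$", names(cohort), value = TRUE))
  candidates <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))], skip)
  if (is.null(binary)) {
    binary <- candidates[vapply(candidates, function(v) {
      u <- unique(stats::na.omit(cohort[[v]]))
      all(u %in% c(0, 1))
    }, logical(1))]
  }
  if (is.null(continuous)) continuous <- setdiff(candidates, binary)

  strata <- list(control = which(y == 0), case = which(y == 1))
  one_cont <- function(v) {
    x <- cohort[[v]]
    p <- stats::wilcox.test(x[strata$case], x[strata$control], exact = FALSE)$p.value
    purrr::imap_dfr(strata, function(idx, nm) {
      xs <- x[idx][!is.na(x[idx])]
      tibble::tibble(characteristic = v, type = "continuous", stratum = nm,
                     n = length(xs), mean = mean(xs), sd = stats::sd(xs),
                     count = NA_integer_, percent = NA_real_,
                     percent_rounded = NA_real_, pvalue = p)
    })
  }
  one_bin <- function(v) {
    x <- cohort[[v]]
    tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
    p <- stats::fisher.test(tab)$p.value
    purrr::imap_dfr(strata, function(idx, nm) {
      xs <- x[idx][!is.na(x[idx])]
      cnt <- sum(xs == 1)
      pct <- 100 * cnt / length(xs)
      tibble::tibble(characteristic = v, type = "binary", stratum = nm,
                     n = length(xs), mean = NA_real_, sd = NA_real_,
                     count = as.integer(cnt), percent = pct,
                     percent_rounded = round(pct), pvalue = p)
    })
  }
  dplyr::bind_rows(
    purrr::map_dfr(continuous, one_cont),
    purrr::map_dfr(binary, one_bin)
  )
}
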