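#' Read a phecode map
#'
#' Loads a CSV mapping source diagnosis codes to phecodes with labels,
#' optional exclusion ranges (phecodes whose carriers are ineligible as
#' controls for this phenotype) and an optional sex flag (`"male"`,
#' `"female"`, or empty for both).
#'
#' @param path CSV with columns `code`, `phecode`, `label`,
#'   `exclusion_range_start`, `exclusion_range_end`, `sex_flag` (last three
#'   optional).
#' @return A tibble of class `phecode_map`.
#' @export
read_phecode_map <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  assert_that(all(c("code", "phecode", "label") %in% names(m)),
              "phecode map needs columns code, phecode, label")
  for (col in c("exclusion_range_start", "exclusion_range_end", "sex_flag")) {
    if (!col %in% names(m)) m[[col]] <- NA_character_
  }
  m$exclusion_range_start <- suppressWarnings(as.numeric(m$exclusion_range_start))
  m$exclusion_range_end <- suppressWarnings(as.numeric(m$exclusion_range_end))
  structure(tibble::as_tibble(m), class = c("phecode_map", class(tibble::tibble())))
}

#' Assign phecode case/control status
#'
#' Maps each individual's diagnosis codes to phecodes and assigns, per
#' phenotype: case when the individual has at least `min_code_count`
#' occurrences of the phecode; excluded when not a case but carrying any
#' phecode in the phenotype's exclusion range (or of non-applicable sex for
#' sex-flagged phenotypes); control otherwise. Unmapped codes are counted
#' and reported in the `unmapped` attribute.
#'
#' @param code_records Tibble with columns `id` and `code`, one row per
#'   diagnosis-code occurrence.
#' @param map A `phecode_map` (see [read_phecode_map()]).
#' @param ids Vector of all cohort ids (individuals with no codes are
#'   controls unless excluded); defaults to the ids present in
#'   `code_records`.
#' @param sex Optional named vector (by id) of `"male"`/`"female"` used for
#'   sex-flagged phenotypes.
#' @param min_code_count Minimum phecode occurrences for case status
#'   (default 2).
#' @return A tibble with columns `phecode`, `label`, `id`, `status`
#'   (`"case"`, `"control"`, `"excluded"`).
#' @export
assign_case_control <- function(code_records, map, ids = NULL, sex = NULL,
                                min_code_count = 2) {
  assert_that(nrow(map) > 0, "empty phecode map")
  if (is.null(ids)) ids <- unique(code_records$id)
  mapped <- dplyr::inner_join(code_records, map[c("code", "phecode")],
                              by = "code", relationship = "many-to-many")
  n_unmapped <- sum(!code_records$code %in% map$code)
  counts <- dplyr::count(mapped, .data$id, .data$phecode, name = "n_codes")

  pheno <- dplyr::distinct(map[c("phecode", "label", "exclusion_range_start",
                                 "exclusion_range_end", "sex_flag")])
  pheno_num <- suppressWarnings(as.numeric(pheno$phecode))

  out <- purrr::pmap_dfr(pheno, function(phecode, label, exclusion_range_start,
                                         exclusion_range_end, sex_flag) {
    cnt <- counts[counts$phecode == phecode, ]
    cases <- cnt$id[cnt$n_codes >= min_code_count]
    # carriers of any phecode in the exclusion range (excluding cases)
    excluded <- character(0)
    if (!is.na(exclusion_range_start) && !is.na(exclusion_range_end)) {
      in_range <- !is.na(pheno_num) & pheno_num >= exclusion_range_start &
        pheno_num <= exclusion_range_end & pheno$phecode != phecode
      range_codes <- pheno$phecode[in_range]
      excluded <- unique(counts$id[counts$phecode %in% c(range_codes)])
      # carriers of this phecode below the case threshold are also excluded
      subthresh <- cnt$id[cnt$n_codes < min_code_count]
      excluded <- union(excluded, subthresh)
    } else {
      excluded <- cnt$id[cnt$n_codes < min_code_count]
    }
    if (!is.na(sex_flag) && nzchar(sex_flag) && !is.null(sex)) {
      wrong_sex <- names(sex)[sex != sex_flag]
      excluded <- union(excluded, wrong_sex)
    }
    excluded <- setdiff(excluded, cases)
    status <- rep("control", length(ids))
    status[ids %in% excluded] <- "excluded"
    status[ids %in% cases] <- "case"
    tibble::tibble(phecode = phecode, label = label, id = ids, status = status)
  })
  set_attr(out, "unmapped", n_unmapped)
}

#' Phenome-wide association scan
#'
#' Fits one logistic regression per phenotype: case/control status on the
#' standardized predictor, adjusted for age, age squared, sex and the first
#' `n_pcs` principal components. Phenotypes with fewer than `min_cases`
#' cases are skipped, as are non-convergent fits (both logged in the
#' `skipped` attribute). Significance is flagged at the Bonferroni
#' threshold `alpha / (number of phenotypes tested)`.
#'
#' @param cohort Data frame with columns `id`, `age`, `sex`, `PC1..PCn`.
#' @param predictor Numeric vector aligned with `cohort` rows; standardized
#'   (mean 0, SD 1) — measured height or the height GRS in the motivating
#'   design.
#' @param assignments Output of [assign_case_control()].
#' @param n_pcs Principal components adjusted for (default 10).
#' @param min_cases Minimum case count to test a phenotype (default 20).
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @return A tibble of class `phewas_result`: `phecode`, `label`,
#'   `n_cases`, `n_controls`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `pvalue`, `significant_bonferroni`; the Bonferroni threshold and the
#'   skip log are attributes (`bonferroni_threshold`, `skipped`).
#' @export
run_phewas <- function(cohort, predictor, assignments, n_pcs = 10,
                       min_cases = 20, alpha = 0.05) {
  pc_cols <- paste0("PC", seq_len(n_pcs))
  assert_that(all(c("id", "age", "sex", pc_cols) %in% names(cohort)),
              "cohort lacks id/age/sex/PC columns")
  assert_that(length(predictor) == nrow(cohort),
              "predictor length must match cohort rows")
  base <- tibble::as_tibble(cohort[c("id", "age", "sex", pc_cols)])
  base$.pred <- predictor
  base$.age2 <- base$age^2

  phenos <- dplyr::distinct(assignments[c("phecode", "label")])
  skipped <- list()
  rows <- purrr::pmap(phenos, function(phecode, label) {
    a <- assignments[assignments$phecode == phecode &
                       assignments$status != "excluded", c("id", "status")]
    df <- dplyr::inner_join(base, a, by = "id")
    df$.y <- as.integer(df$status == "case")
    n_cases <- sum(df$.y)
    n_controls <- sum(df$.y == 0)
    if (n_cases < min_cases) {
      skipped[[phecode]] <<- paste0("fewer than ", min_cases, " cases")
      return(NULL)
    }
    f <- stats::reformulate(c(".pred", "age", ".age2", "sex", pc_cols),
                            response = ".y")
    fit <- tryCatch(stats::glm(f, data = df, family = stats::binomial()),
                    warning = function(w) {
                      suppressWarnings(stats::glm(f, data = df,
                                                  family = stats::binomial()))
                    })
    if (!fit$converged || !is.finite(stats::coef(fit)[[".pred"]])) {
      skipped[[phecode]] <<- "non-convergent logistic fit"
      return(NULL)
    }
    sm <- summary(fit)$coefficients
    b <- sm[".pred", "Estimate"]
    se <- sm[".pred", "Std. Error"]
    tibble::tibble(phecode = phecode, label = label, n_cases = n_cases,
                   n_controls = n_controls, beta = b, se = se,
                   or = exp(b), ci_low = exp(b - Z95 * se),
                   ci_high = exp(b + Z95 * se),
                   pvalue = two_sided_p(b / se))
  })
  res <- dplyr::bind_rows(rows)
  n_tested <- nrow(res)
  threshold <- if (n_tested > 0) alpha / n_tested else NA_real_
  if (n_tested > 0) res$significant_bonferroni <- res$pvalue < threshold
  res <- structure(res, class = c("phewas_result", class(tibble::tibble())))
  res <- set_attr(res, "bonferroni_threshold", threshold)
  set_attr(res, "skipped", skipped)
}

#' Bonferroni threshold
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  assert_that(n_tests >= 1, "n_tests must be positive")
  alpha / n_tests
}
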