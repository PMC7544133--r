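#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file (gzip transparently supported) of
#' per-variant association estimates into the canonical summary-statistic
#' tibble used throughout the package. Rows failing validation (zero or
#' negative standard error, allele frequency outside \[0,1\], indels or
#' multi-allelic alleles, unparseable numbers) are dropped with a warning
#' naming the offending line numbers; structural problems (missing columns,
#' empty file) are errors.
#'
#' The canonical columns are `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(variant_id = "SNP", beta = "b")`. Columns
#'   already canonically named need no entry.
#' @param delim Field delimiter; `NULL` (default) guesses from the file name
#'   and first line (tab preferred over comma).
#' @return A tibble of validated summary statistics, row order preserved.
#' @seealso [write_summary_stats()], [validate_summary_stats()]
#' @export
read_summary_stats <- function(path, column_map = character(), delim = NULL) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty summary-statistics file: ", path, call. = FALSE)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path, call. = FALSE)

  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")
  have <- names(raw)
  resolved <- vapply(canonical, function(nm) {
    src <- if (nm %in% names(column_map)) unname(column_map[[nm]]) else nm
    if (!src %in% have) NA_character_ else src
  }, character(1))
  missing <- canonical[is.na(resolved)]
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    variant_id    = raw[[resolved[["variant_id"]]]],
    chrom         = raw[[resolved[["chrom"]]]],
    pos           = suppressWarnings(as.integer(raw[[resolved[["pos"]]]])),
    effect_allele = toupper(raw[[resolved[["effect_allele"]]]]),
    other_allele  = toupper(raw[[resolved[["other_allele"]]]]),
    eaf           = suppressWarnings(as.numeric(raw[[resolved[["eaf"]]]])),
    beta          = suppressWarnings(as.numeric(raw[[resolved[["beta"]]]])),
    se            = suppressWarnings(as.numeric(raw[[resolved[["se"]]]])),
    pvalue        = suppressWarnings(as.numeric(raw[[resolved[["pvalue"]]]])),
    n             = suppressWarnings(as.integer(round(as.numeric(raw[[resolved[["n"]]]]))))
  )
  validate_summary_stats(out)
}

#' Validate a summary-statistic tibble
#'
#' Applies the row-level invariants: single-nucleotide distinct alleles,
#' `se > 0`, `eaf` in \[0,1\], `pvalue` in (0,1\], positive `n`, finite
#' numerics. Invalid rows are removed with a warning listing their (1-based)
#' row numbers and the reason. Rows whose p-value disagrees with the normal
#' approximation `2*pnorm(-|beta/se|)` by more than two orders of magnitude
#' are kept but flagged with a warning.
#'
#' @param x A tibble with the canonical summary-statistic columns.
#' @return The validated tibble (invalid rows dropped).
#' @export
validate_summary_stats <- function(x) {
  n0 <- nrow(x)
  reason <- rep(NA_character_, n0)
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(cond & is.na(reason), why, reason)
  }
  reason <- bad(!(x$effect_allele %in% NUCLEOTIDES) | !(x$other_allele %in% NUCLEOTIDES),
                "allele not a single A/C/G/T nucleotide")
  reason <- bad(x$effect_allele == x$other_allele, "identical alleles")
  reason <- bad(!is.finite(x$beta) | !is.finite(x$se) | !is.finite(x$pvalue), "unparseable numeric")
  reason <- bad(x$se <= 0, "non-positive se")
  reason <- bad(x$eaf < 0 | x$eaf > 1, "eaf outside [0,1]")
  reason <- bad(x$pvalue <= 0 | x$pvalue > 1, "pvalue outside (0,1]")
  reason <- bad(is.na(x$n) | x$n <= 0, "non-positive n")
  drop <- !is.na(reason)
  if (any(drop)) {
    warning(sum(drop), " row(s) rejected: ",
            paste0("row ", which(drop), " (", reason[drop], ")", collapse = "; "),
            call. = FALSE)
  }
  out <- x[!drop, , drop = FALSE]
  if (nrow(out) > 0L) {
    p_norm <- two_sided_p(out$beta / out$se)
    ratio <- pmax(out$pvalue, 1e-300) / pmax(p_norm, 1e-300)
    off <- abs(log10(ratio)) > 2 & p_norm > 1e-290
    if (any(off)) {
      warning(sum(off), " row(s) have p-values inconsistent with beta/se by >2 ",
              "orders of magnitude (kept): rows ",
              paste(which(off), collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write summary statistics to delimited text
#'
#' Inverse of [read_summary_stats()]: writes the canonical columns with full
#' numeric precision so that a read/write round trip reproduces every field.
#'
#' @param x Summary-statistic tibble.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path, delim = "\t") {
  canonical <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n")
  assert_that(all(canonical %in% names(x)), "not a canonical summary-statistic tibble")
  readr::write_delim(x[canonical], path, delim = delim, progress = FALSE)
  invisible(path)
}
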