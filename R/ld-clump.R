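#' Linkage-disequilibrium panels
#'
#' An `ld_panel` stores pairwise r-squared between variants together with
#' their chromosome and position. Pairs on different chromosomes have
#' r-squared 0 by definition; a variant with itself has r-squared 1. Panels
#' are built either from a 3-column pair list (`id1`, `id2`, `r2`) plus
#' variant metadata, or from a genotype dosage matrix, where r-squared is
#' the squared Pearson correlation of dosages.
#'
#' @param pairs Tibble/data frame with columns `id1`, `id2`, `r2`.
#' @param variants Tibble with columns `variant_id`, `chrom`, `pos`.
#' @return An object of class `ld_panel`.
#' @export
ld_panel_from_pairs <- function(pairs, variants) {
  assert_that(all(c("id1", "id2", "r2") %in% names(pairs)), "pairs needs id1, id2, r2")
  assert_that(all(c("variant_id", "chrom", "pos") %in% names(variants)),
              "variants needs variant_id, chrom, pos")
  assert_that(all(pairs$r2 >= 0 & pairs$r2 <= 1), "r2 values must lie in [0,1]")
  ids <- variants$variant_id
  m <- diag(1, length(ids))
  dimnames(m) <- list(ids, ids)
  i <- match(pairs$id1, ids)
  j <- match(pairs$id2, ids)
  known <- !is.na(i) & !is.na(j)
  m[cbind(i[known], j[known])] <- pairs$r2[known]
  m[cbind(j[known], i[known])] <- pairs$r2[known]
  # cross-chromosome pairs are unlinked regardless of the pair list
  chrom <- variants$chrom
  diffchr <- outer(chrom, chrom, FUN = "!=")
  m[diffchr] <- 0
  structure(list(variants = tibble::as_tibble(variants[c("variant_id", "chrom", "pos")]),
                 r2 = m),
            class = "ld_panel")
}

#' @param dosages Numeric matrix of allele dosages, variants in columns named
#'   by `variant_id`, individuals in rows.
#' @rdname ld_panel_from_pairs
#' @export
ld_panel_from_dosages <- function(dosages, variants) {
  assert_that(nrow(dosages) >= 2, "need at least 2 individuals")
  ids <- variants$variant_id
  dosages <- dosages[, ids, drop = FALSE]
  v <- apply(dosages, 2, stats::var)
  zero_var <- v == 0 | is.na(v)
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance variant(s); their pairs set to r2 = 0",
            call. = FALSE)
  }
  m <- diag(1, length(ids))
  ok <- which(!zero_var)
  if (length(ok) >= 2) {
    cc <- stats::cor(dosages[, ok, drop = FALSE])^2
    m[ok, ok] <- cc
  }
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  chrom <- variants$chrom
  m[outer(chrom, chrom, FUN = "!=")] <- 0
  structure(list(variants = tibble::as_tibble(variants[c("variant_id", "chrom", "pos")]),
                 r2 = m),
            class = "ld_panel")
}

#' Look up pairwise r-squared in an LD panel
#'
#' Variants absent from the panel are treated as unlinked (r-squared 0).
#' Same-chromosome membership is taken from the panel metadata.
#'
#' @param panel An `ld_panel`.
#' @param a,b Variant id vectors (recycled).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(panel, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  ids <- panel$variants$variant_id
  i <- match(a, ids)
  j <- match(b, ids)
  out <- numeric(n)
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- panel$r2[cbind(i[ok], j[ok])]
  out[a == b] <- 1
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Selects an independent subset of variants: after restricting to
#' `pvalue < p_threshold`, variants are visited in order of ascending
#' p-value (ties broken by chromosome, position, then variant id); each
#' visited variant is retained, and every remaining variant on the same
#' chromosome within `window_kb` kilobases (inclusive, `|delta pos| <=
#' window_kb * 1000`) and with r-squared above `r2_threshold` to it is
#' discarded. Variants missing from the LD panel are treated as unlinked
#' with a warning. The result is independent of input row order.
#'
#' @param records Canonical summary-statistic tibble.
#' @param ld An `ld_panel`.
#' @param window_kb Clumping window in kilobases (default 10,000).
#' @param r2_threshold r-squared above which nearby variants are discarded
#'   (default 0.001).
#' @param p_threshold Significance filter applied before clumping (default
#'   5e-8).
#' @return The retained subset, sorted by chromosome then position.
#' @export
clump <- function(records, ld, window_kb = 10000, r2_threshold = 0.001,
                  p_threshold = 5e-8) {
  assert_that(window_kb > 0, "window_kb must be positive")
  x <- records[records$pvalue < p_threshold, , drop = FALSE]
  if (nrow(x) == 0L) {
    warning("no variants pass the p-value threshold; returning empty set", call. = FALSE)
    return(x)
  }
  unknown <- setdiff(x$variant_id, ld$variants$variant_id)
  if (length(unknown) > 0L) {
    warning(length(unknown), " variant(s) absent from the LD panel treated as unlinked",
            call. = FALSE)
  }
  ord <- order(x$pvalue, x$chrom, x$pos, x$variant_id)
  x <- x[ord, , drop = FALSE]
  keep <- logical(nrow(x))
  alive <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(x))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_len(nrow(x)) > i)
    if (length(later) == 0L) next
    same_chr <- x$chrom[later] == x$chrom[i]
    near <- abs(x$pos[later] - x$pos[i]) <= window_kb * 1000
    linked <- ld_r2(ld, x$variant_id[later], x$variant_id[i]) > r2_threshold
    alive[later[same_chr & near & linked]] <- FALSE
  }
  out <- x[keep, , drop = FALSE]
  out[order(out$chrom, out$pos, out$variant_id), , drop = FALSE]
}
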