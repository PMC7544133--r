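test_that("well-formed files read cleanly with row order preserved", {
  ss <- make_sumstats(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  expect_no_warning(got <- read_summary_stats(path))
  expect_equal(nrow(got), 3)
  expect_equal(got$variant_id, ss$variant_id)
})

test_that("rows violating invariants are rejected with a warning, not an error", {
  ss <- make_sumstats(3)
  ss$se[2] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ss, path)
  expect_warning(got <- read_summary_stats(path), "rejected")
  expect_equal(nrow(got), 2)
  expect_false("rs0002" %in% got$variant_id)
})

test_that("missing columns and empty files are hard errors", {
  ss <- make_sumstats(3)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ss[setdiff(names(ss), "se")], path)
  expect_error(read_summary_stats(path), "missing required column")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("variant_id\tchrom", empty)
  expect_error(read_summary_stats(empty), "empty")
})

test_that("column_map resolves non-canonical headers and gz files read transparently", {
  ss <- make_sumstats(4)
  renamed <- ss
  names(renamed)[names(renamed) == "variant_id"] <- "SNP"
  names(renamed)[names(renamed) == "beta"] <- "b"
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  readr::write_tsv(renamed, path)
  got <- read_summary_stats(path, column_map = c(variant_id = "SNP", beta = "b"))
  expect_equal(got$beta, ss$beta)
})

test_that("write/read round trip reproduces every field exactly", {
  withr::with_seed(99, {
    ss <- make_sumstats(50, seed = 11)
    ss$beta <- stats::rnorm(50, 0, 0.01)      # full-precision doubles
    ss$se <- stats::runif(50, 0.005, 0.02)
    ss$pvalue <- 2 * stats::pnorm(-abs(ss$beta / ss$se))
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  got <- read_summary_stats(path)
  expect_identical(got$beta, ss$beta)
  expect_identical(got$se, ss$se)
  expect_identical(got$pvalue, ss$pvalue)
  expect_identical(got$eaf, ss$eaf)
  expect_identical(got$pos, ss$pos)
  expect_identical(got$n, ss$n)
})

test_that("indels and p-values inconsistent with beta/se are caught", {
  ss <- make_sumstats(3)
  ss$effect_allele[1] <- "AT"
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ss, path)
  expect_warning(got <- read_summary_stats(path), "nucleotide")
  expect_equal(nrow(got), 2)

  ss2 <- make_sumstats(3)
  ss2$pvalue[1] <- min(1, ss2$pvalue[1] * 1e4)
  expect_warning(validate_summary_stats(ss2), "inconsistent")
})

# --- harmonization ---------------------------------------------------------

h_pair <- function(exp_row, out_row, ...) {
  harmonize(exp_row, out_row, ...)
}

make_one <- function(id = "rs1", ea, oa, beta, eaf, se = 0.01, n = 1e4L) {
  tibble::tibble(variant_id = id, chrom = "1", pos = 100L,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se,
                 pvalue = 2 * stats::pnorm(-abs(beta / se)), n = n)
}

test_that("matching alleles pass through unchanged; reversed alleles flip", {
  ex <- make_one(ea = "A", oa = "G", beta = 0.02, eaf = 0.30)
  ou_same <- make_one(ea = "A", oa = "G", beta = 0.05, eaf = 0.31)
  h <- h_pair(ex, ou_same)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$action, "unchanged")

  ou_rev <- make_one(ea = "G", oa = "A", beta = 0.05, eaf = 0.70)
  h2 <- h_pair(ex, ou_rev)
  expect_equal(h2$beta_outcome, -0.05)
  expect_equal(h2$eaf_outcome, 0.30)
  expect_equal(h2$action, "flipped")
})

test_that("opposite-strand non-palindromic records are recognised", {
  ex <- make_one(ea = "A", oa = "G", beta = 0.02, eaf = 0.30)
  ou <- make_one(ea = "T", oa = "C", beta = 0.05, eaf = 0.29)  # complement
  h <- h_pair(ex, ou)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$action, "unchanged")
})

test_that("palindrome resolution matches the exhaustive strand-enumeration oracle", {
  limit <- 0.42
  grid <- expand.grid(
    eaf_exposure = c(0.10, 0.45, 0.88),
    eaf_outcome = c(0.12, 0.48, 0.88),
    outcome_effect_first = c(TRUE, FALSE),
    KEEP.OUT.ATTRS = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ex <- make_one(ea = "A", oa = "T", beta = 0.02, eaf = g$eaf_exposure)
    ou <- make_one(ea = if (g$outcome_effect_first) "A" else "T",
                   oa = if (g$outcome_effect_first) "T" else "A",
                   beta = 0.05, eaf = g$eaf_outcome)
    oracle <- palindrome_oracle(g$eaf_exposure, 0.05, g$eaf_outcome,
                                g$outcome_effect_first, limit)
    h <- h_pair(ex, ou, palindrome_eaf_limit = limit)
    if (is.null(oracle)) {
      expect_equal(nrow(h), 0, info = paste("case", i))
      expect_equal(attr(h, "dropped")$reason, "dropped_palindromic",
                   info = paste("case", i))
    } else {
      expect_equal(h$beta_outcome, oracle$beta, info = paste("case", i))
      expect_equal(h$eaf_outcome, oracle$eaf, info = paste("case", i))
    }
  }
})

test_that("a clearly-skewed palindromic pair resolves by strand inference", {
  ex <- make_one(ea = "A", oa = "T", beta = 0.02, eaf = 0.10)
  ou <- make_one(ea = "A", oa = "T", beta = 0.05, eaf = 0.88)
  h <- h_pair(ex, ou, palindrome_eaf_limit = 0.42)
  expect_equal(h$action, "inferred_palindromic")
  expect_equal(h$beta_outcome, -0.05)
  expect_equal(h$eaf_outcome, 0.12)

  ou2 <- make_one(ea = "A", oa = "T", beta = 0.05, eaf = 0.48)
  h2 <- h_pair(ex, ou2, palindrome_eaf_limit = 0.42)
  expect_equal(nrow(h2), 0)
})

test_that("duplicate ids and zero overlap are hard errors; unmatched variants drop", {
  ex <- make_sumstats(4)
  expect_error(harmonize(rbind(ex, ex[1, ]), ex), "duplicate")
  other <- make_sumstats(4)
  other$variant_id <- paste0("x", other$variant_id)
  expect_error(harmonize(ex, other), "zero overlapping")
  h <- harmonize(ex, ex[1:2, ])
  expect_equal(nrow(h), 2)
})

test_that("harmonization is idempotent and invariant to outcome allele flips", {
  withr::with_seed(31, {
    ex <- make_sumstats(10)
    ou <- ex
    ou$beta <- stats::rnorm(10, 0, 0.05)
    ou$eaf <- pmin(pmax(ex$eaf + stats::rnorm(10, 0, 0.01), 0.01), 0.99)
    flip <- stats::runif(10) < 0.5
  })
  ou_flipped <- ou
  ou_flipped$effect_allele[flip] <- ou$other_allele[flip]
  ou_flipped$other_allele[flip] <- ou$effect_allele[flip]
  ou_flipped$beta[flip] <- -ou$beta[flip]
  ou_flipped$eaf[flip] <- 1 - ou$eaf[flip]

  h1 <- harmonize(ex, ou)
  h2 <- harmonize(ex, ou_flipped)
  num <- c("beta_exposure", "beta_outcome", "eaf_outcome", "se_outcome")
  expect_equal(h1[num], h2[num])

  # feeding the harmonized outcome back through changes nothing
  h3 <- harmonize(ex, harmonized_outcome_records(h1))
  expect_equal(h1[num], h3[num])
})

# --- clumping --------------------------------------------------------------

test_that("singleton and cross-chromosome variants are retained", {
  ss <- make_sumstats(1)
  ss$pvalue <- 1e-9
  ld <- make_dense_ld(ss$variant_id, 0)
  expect_equal(clump(ss, ld)$variant_id, ss$variant_id)

  two <- make_sumstats(2, chrom = c("1", "2"), pos = c(1e6L, 1e6L))
  two$pvalue <- c(1e-9, 1e-10)
  ld2 <- ld_panel_from_pairs(
    tibble::tibble(id1 = two$variant_id[1], id2 = two$variant_id[2], r2 = 0.9),
    two[c("variant_id", "chrom", "pos")])
  expect_equal(nrow(clump(two, ld2)), 2)  # different chromosomes never clump
})

test_that("a fully linked window collapses to the minimum-p variant", {
  ss <- make_sumstats(5, chrom = "1", pos = as.integer(seq(1e6, 9e6, length.out = 5)))
  ss$pvalue <- c(1e-9, 1e-12, 1e-10, 1e-8, 1e-11)
  ld <- make_dense_ld(ss$variant_id, 0.5, pos = ss$pos)
  got <- clump(ss, ld, window_kb = 10000, r2_threshold = 0.001, p_threshold = 5e-8)
  expect_equal(got$variant_id, "rs0002")
  expect_equal(got, reference_clump(ss, ld, 10000, 0.001, 5e-8),
               ignore_attr = TRUE)
})

test_that("clumping matches the reference implementation on random instances", {
  for (case_seed in 1:8) {
    withr::with_seed(case_seed, {
      n <- sample(3:8, 1)
      ss <- make_sumstats(n, seed = case_seed, chrom = "1",
                          pos = sort(sample.int(2e7, n)))
      ss$pvalue <- stats::runif(n, 1e-12, 1e-6)
      ids <- ss$variant_id
      pairs <- expand.grid(id1 = ids, id2 = ids, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$id1 < pairs$id2, ]
      pairs$r2 <- sample(c(0, 0.0005, 0.1, 0.8), nrow(pairs), replace = TRUE)
      ld <- ld_panel_from_pairs(pairs, ss[c("variant_id", "chrom", "pos")])
    })
    got <- clump(ss, ld, window_kb = 5000, r2_threshold = 0.001, p_threshold = 1e-5)
    ref <- reference_clump(ss, ld, 5000, 0.001, 1e-5)
    expect_equal(got$variant_id, ref$variant_id, info = paste("seed", case_seed))

    # row-order invariance
    shuffled <- ss[sample(nrow(ss)), ]
    expect_equal(clump(shuffled, ld, 5000, 0.001, 1e-5)$variant_id,
                 got$variant_id, info = paste("seed", case_seed))

    # every retained pair is compatible
    if (nrow(got) >= 2) {
      combs <- utils::combn(nrow(got), 2)
      for (j in seq_len(ncol(combs))) {
        a <- got[combs[1, j], ]; b <- got[combs[2, j], ]
        ok <- a$chrom != b$chrom ||
          abs(a$pos - b$pos) > 5000 * 1000 ||
          ld_r2(ld, a$variant_id, b$variant_id) <= 0.001
        expect_true(ok)
      }
    }
  }
})

test_that("clump threshold edge cases behave", {
  ss <- make_sumstats(3)
  ld <- make_dense_ld(ss$variant_id, 0)
  expect_error(clump(ss, ld, window_kb = 0), "positive")
  ss$pvalue <- rep(0.5, 3)
  expect_warning(out <- clump(ss, ld), "no variants")
  expect_equal(nrow(out), 0)
})

test_that("LD panel lookups satisfy symmetry, range and cross-chromosome zero", {
  sim <- make_mini_cohort(n = 300, seed = 3)
  panel <- make_ld_panel(sim)
  ids <- panel$variants$variant_id
  withr::with_seed(5, {
    a <- sample(ids, 50, replace = TRUE)
    b <- sample(ids, 50, replace = TRUE)
  })
  expect_equal(ld_r2(panel, a, b), ld_r2(panel, b, a))
  expect_true(all(ld_r2(panel, a, b) >= 0 & ld_r2(panel, a, b) <= 1))
  expect_equal(ld_r2(panel, ids[1], ids[1]), 1)
  cross <- panel$variants$chrom[match(a, ids)] != panel$variants$chrom[match(b, ids)]
  expect_true(all(ld_r2(panel, a, b)[cross] == 0))
})
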