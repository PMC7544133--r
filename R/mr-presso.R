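#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' A simulation-based test for horizontal pleiotropy with three parts.
#' Global test: the observed residual sum of squares (each variant's squared
#' deviation of its outcome effect from the leave-one-out IVW prediction,
#' precision-weighted) is compared to its distribution over `n_sim`
#' parametric simulations under the fitted no-pleiotropy model; the
#' empirical p-value has lower bound `1/(n_sim + 1)`. Outlier test: each
#' variant's observed weighted squared residual is compared to its own
#' simulated distribution, with Bonferroni correction over the `k` variants
#' at `outlier_alpha`. Distortion test: when outliers are found, the
#' relative change between the raw IVW estimate and the outlier-removed IVW
#' estimate is compared against the distribution of the same quantity on
#' the simulated null datasets with equally many (randomly chosen) variants
#' removed.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble with >= 4
#'   variants.
#' @param n_sim Number of parametric simulations (default 5000, minimum
#'   1000; fewer than 1000 warns).
#' @param seed Integer seed.
#' @param outlier_alpha Family-wise level of the outlier test (default
#'   0.05).
#' @return A list of class `mr_presso` with elements `global_rss_observed`,
#'   `global_p`, `outlier_indices`, `per_snp_outlier_p` (Bonferroni-
#'   corrected), `distortion_p` (NA when no outliers), `raw` (IVW on all
#'   variants, method `presso_raw`) and `corrected` (outlier-removed IVW,
#'   method `presso_outlier_corrected`; NULL when no outliers).
#' @export
mr_presso <- function(inst, n_sim = 5000, seed = 1L, outlier_alpha = 0.05) {
  k <- nrow(inst)
  assert_that(k >= 4, "MR-PRESSO needs at least 4 variants")
  if (n_sim < 1000) {
    warning("n_sim < 1000 gives coarse empirical p-values", call. = FALSE)
  }
  bx <- inst$beta_exposure
  sx <- inst$se_exposure
  by <- inst$beta_outcome
  sy <- inst$se_outcome
  w <- (bx / sy)^2

  # leave-one-out IVW: (S - w_j r_j) / (W - w_j) with S = sum(w r), W = sum(w)
  loo_ivw <- function(w., r.) (sum(w. * r.) - w. * r.) / (sum(w.) - w.)
  loo_beta <- loo_ivw(w, by / bx)
  resid2 <- function(by., bx., pred) ((by. - pred * bx.) / sy)^2
  obs_r2 <- resid2(by, bx, loo_beta)
  rss_obs <- sum(obs_r2)

  sim <- withr::with_seed(seed, {
    sim_r2 <- matrix(NA_real_, n_sim, k)
    sim_rss <- numeric(n_sim)
    sim_beta_all <- numeric(n_sim)
    sim_data <- vector("list", n_sim)
    for (s in seq_len(n_sim)) {
      bx_s <- stats::rnorm(k, bx, sx)
      by_s <- stats::rnorm(k, loo_beta * bx, sy)
      w_s <- (bx_s / sy)^2
      loo_s <- loo_ivw(w_s, by_s / bx_s)
      sim_r2[s, ] <- resid2(by_s, bx_s, loo_s)
      sim_rss[s] <- sum(sim_r2[s, ])
      sim_beta_all[s] <- sum(w_s * (by_s / bx_s)) / sum(w_s)
      sim_data[[s]] <- list(bx = bx_s, by = by_s)
    }
    list(r2 = sim_r2, rss = sim_rss, beta_all = sim_beta_all, data = sim_data)
  })

  global_p <- (sum(sim$rss >= rss_obs) + 1) / (n_sim + 1)
  per_p_raw <- vapply(seq_len(k), function(j) {
    (sum(sim$r2[, j] >= obs_r2[j]) + 1) / (n_sim + 1)
  }, numeric(1))
  per_p <- pmin(1, per_p_raw * k)
  outliers <- which(per_p < outlier_alpha)

  raw <- mr_ivw(inst)
  raw$method <- "presso_raw"
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outliers) > 0 && k - length(outliers) >= 2) {
    corrected <- mr_ivw(inst[-outliers, , drop = FALSE])
    corrected$method <- "presso_outlier_corrected"
    d_obs <- (raw$beta - corrected$beta) / abs(corrected$beta)
    d_null <- withr::with_seed(derive_seed(seed, 13L), {
      vapply(seq_len(min(n_sim, 1000L)), function(s) {
        dat <- sim$data[[s]]
        drop_idx <- sample.int(k, length(outliers))
        w_s <- (dat$bx / sy)^2
        b_all <- sum(w_s * (dat$by / dat$bx)) / sum(w_s)
        keep <- setdiff(seq_len(k), drop_idx)
        b_sub <- sum((w_s * (dat$by / dat$bx))[keep]) / sum(w_s[keep])
        (b_all - b_sub) / abs(b_sub)
      }, numeric(1))
    })
    distortion_p <- (sum(abs(d_null) >= abs(d_obs)) + 1) / (length(d_null) + 1)
  }

  structure(list(
    global_rss_observed = rss_obs,
    global_p = global_p,
    outlier_indices = outliers,
    per_snp_outlier_p = per_p,
    distortion_p = distortion_p,
    raw = raw,
    corrected = corrected
  ), class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.3f, p = %.4g\n",
              x$global_rss_observed, x$global_p))
  if (length(x$outlier_indices) > 0) {
    cat("  outliers at indices:", paste(x$outlier_indices, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
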