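# Result graphics. All plot functions return ggplot objects so callers can
# restyle or save them.

#' Scatter plot of per-variant effects with method fit lines
#'
#' Points are per-variant exposure and outcome effects (oriented so the
#' exposure effect is positive); lines are the fitted causal slopes of the
#' supplied estimates, with the Egger line keeping its intercept.
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble.
#' @param estimates An `mr_estimate` tibble (one or more methods).
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(inst, estimates) {
  flip <- sign(inst$beta_exposure)
  flip[flip == 0] <- 1
  pts <- tibble::tibble(bx = inst$beta_exposure * flip,
                        by = inst$beta_outcome * flip,
                        se_y = inst$se_outcome)
  lines <- tibble::tibble(
    method = estimates$method,
    slope = estimates$beta,
    intercept = ifelse(is.finite(estimates$egger_intercept),
                       estimates$egger_intercept, 0)
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_y,
                                        ymax = .data$by + .data$se_y),
                           linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(slope = .data$slope,
                                      intercept = .data$intercept,
                                      colour = .data$method)) +
    ggplot2::labs(x = "effect on exposure (per SD)",
                  y = "effect on outcome (log odds)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates
#'
#' @param estimates An `mr_estimate` tibble (stacked methods) or a
#'   two-stage model table.
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(estimates) {
  df <- tibble::as_tibble(estimates)
  if ("model_label" %in% names(df)) {
    df <- tibble::tibble(label = df$model_label, or = df$or_per_sd,
                         lo = df$ci_low, hi = df$ci_high)
  } else {
    df <- tibble::tibble(label = df$method, or = df$or,
                         lo = df$or_ci_low, hi = df$or_ci_high)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot of per-variant ratios against precision
#'
#' @param inst An `mr_harmonized` / `mr_instrument` tibble.
#' @param estimate An `mr_estimate` (vertical reference line).
#' @return A ggplot object.
#' @export
plot_mr_funnel <- function(inst, estimate) {
  df <- tibble::tibble(
    ratio = inst$beta_outcome / inst$beta_exposure,
    precision = abs(inst$beta_exposure) / inst$se_outcome
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio, y = .data$precision)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = estimate$beta[1], colour = "red") +
    ggplot2::labs(x = "per-variant causal estimate", y = "precision (1/SE)") +
    ggplot2::theme_minimal()
}

#' Manhattan-style PheWAS plot
#'
#' Minus-log10 p-values by phecode, with the Bonferroni and nominal
#' significance lines and point direction encoding the sign of the
#' association.
#'
#' @param x A `phewas_result`.
#' @param alpha Nominal level (default 0.05).
#' @return A ggplot object.
#' @export
plot_phewas <- function(x, alpha = 0.05) {
  df <- tibble::as_tibble(x)
  df$direction <- ifelse(df$beta >= 0, "increased risk", "decreased risk")
  bonf <- attr(x, "bonferroni_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phecode, y = -log10(.data$pvalue),
                                   shape = .data$direction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`increased risk` = 24,
                                           `decreased risk` = 25)) +
    ggplot2::geom_hline(yintercept = -log10(bonf), colour = "red") +
    ggplot2::geom_hline(yintercept = -log10(alpha), colour = "blue",
                        linetype = 2) +
    ggplot2::labs(x = "phecode", y = expression(-log[10](p)), shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.mr_estimate <- function(object, ...) plot_mr_forest(object)

#' @export
autoplot.phewas_result <- function(object, ...) plot_phewas(object)
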