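# ggplot2 displays: instrument scatter and forest plots.

#' Scatter plot of harmonized instruments with fitted MR lines
#'
#' Plots the per-variant outcome effects against the exposure effects (error
#' bars at one standard error), with the IVW line through the origin and,
#' when at least three instruments are available, the MR-Egger line whose
#' non-zero intercept visualizes directional pleiotropy.
#'
#' @param object A harmonized tibble from [harmonize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_harmonized
#' @export
autoplot.mr_harmonized <- function(object, ...) {
  h <- orient_exposure_increasing(kept_instruments(object))
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$beta_exposure,
                                       y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome
    ), width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - .data$se_exposure,
      xmax = .data$beta_exposure + .data$se_exposure
    ), height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "variant-exposure effect",
                  y = "variant-outcome effect")
  ivw <- mr_ivw(h)
  p <- p + ggplot2::geom_abline(intercept = 0, slope = ivw$estimate,
                                colour = "#2166AC")
  if (nrow(h) >= 3) {
    egger <- mr_egger(h)
    p <- p + ggplot2::geom_abline(intercept = egger$intercept,
                                  slope = egger$estimate,
                                  colour = "#B2182B", linetype = "dashed")
  }
  p
}

#' Forest plot of an analysis grid
#'
#' One row per exposure-outcome cell, point estimate with 95% CI, faceted by
#' method; binary outcomes are drawn on the odds ratio scale with a unit
#' reference line.
#'
#' @param results An `mr_results` tibble from [run_mr_grid()].
#' @param analysis Which analysis variant to draw (default `"primary"`).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(results, analysis = "primary") {
  df <- tibble::as_tibble(results)
  df <- df[df$analysis == analysis & !is.na(df$estimate), , drop = FALSE]
  binary <- all(df$outcome_type == "binary", na.rm = TRUE)
  if (binary) {
    df$mid <- df$or; df$lo <- df$or_conf.low; df$hi <- df$or_conf.high
    xlab <- "odds ratio (95% CI)"; ref <- 1
  } else {
    df$mid <- df$estimate; df$lo <- df$conf.low; df$hi <- df$conf.high
    xlab <- "causal effect (95% CI)"; ref <- 0
  }
  df$cell <- paste(df$exposure, "→", df$outcome)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$cell)) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dotted") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    (if (binary) ggplot2::scale_x_log10() else NULL) +
    ggplot2::labs(x = xlab, y = NULL)
}

#' @rdname plot_mr_forest
#' @param object An `mr_results` tibble.
#' @param ... Passed to [plot_mr_forest()].
#' @method autoplot mr_results
#' @export
autoplot.mr_results <- function(object, ...) plot_mr_forest(object, ...)
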