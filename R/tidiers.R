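# broom-style tidiers for estimate and PRESSO objects.

#' Tidy an MR estimate into term-level rows
#'
#' One row per model term: the causal slope, plus the pleiotropy intercept for
#' MR-Egger fits.
#'
#' @param x An `mr_estimate` (one-row tibble from [mr_ivw()], [mr_egger()],
#'   [mr_weighted_median()], ...).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble::tibble(
    term = "causal_effect",
    estimate = x$estimate, std.error = x$std.error,
    statistic = x$statistic, p.value = x$p.value,
    conf.low = x$conf.low, conf.high = x$conf.high
  )
  if (!is.na(x$intercept)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "pleiotropy_intercept",
      estimate = x$intercept, std.error = x$intercept_se,
      statistic = x$intercept / x$intercept_se, p.value = x$intercept_p,
      conf.low = NA_real_, conf.high = NA_real_
    ))
  }
  out
}

#' Glance at an MR estimate
#'
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `n_snp` and the heterogeneity
#'   columns.
#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 q_stat = x$q_stat, q_df = x$q_df, q_pvalue = x$q_pvalue)
}

#' Tidy a pleiotropy residual test
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return The per-variant tibble (`variant_id`, `p`, `p_adj`, `outlier`).
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$per_variant

#' Glance at a pleiotropy residual test
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return A one-row tibble with the global statistic, p-values and outlier
#'   count.
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_rss = x$global_rss, global_p = x$global_p,
    n_outliers = length(x$outliers), distortion_p = x$distortion_p,
    n_sim = x$n_sim
  )
}
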