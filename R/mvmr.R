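# Multivariable IVW: jointly modelling several genetically proxied exposures,
# including cluster-weighted endophenotype exposures.

#' Build cluster-weighted exposure columns from variant effects
#'
#' Constructs a multivariable design where each cluster (endophenotype)
#' contributes an exposure column equal to the cluster weight times the
#' variant's trait effect (0 where the variant carries no weight in that
#' cluster). An optional adjustment trait (e.g. HbA1c) can be appended as an
#' extra exposure column from its own per-variant effects.
#'
#' @param variants Tibble with `variant_id`, `beta`, `se` (per-variant effects
#'   on the trait scale used to weight the clusters).
#' @param weights Cluster weight tibble with `variant_id`, `cluster`,
#'   `weight`; (variant, cluster) pairs must be unique. Every weighted variant
#'   must be present in `variants`.
#' @param adjustment Optional tibble with `variant_id`, `beta`, `se` whose
#'   effects are appended as one extra exposure column.
#' @param adjustment_name Column label for the adjustment exposure.
#' @return A tibble with `variant_id` and one effect column per cluster (named
#'   by cluster label) plus `<label>_se` columns; the exposure column names are
#'   attached as attribute `"exposure_cols"`.
#' @export
build_cluster_exposures <- function(variants, weights, adjustment = NULL,
                                    adjustment_name = "adjustment") {
  assert_columns(variants, c("variant_id", "beta", "se"), "variants")
  assert_columns(weights, c("variant_id", "cluster", "weight"),
                 "cluster weights")
  if (anyDuplicated(weights[, c("variant_id", "cluster")])) {
    abort("duplicate (variant_id, cluster) pairs in the weight table")
  }
  absent <- setdiff(weights$variant_id, variants$variant_id)
  if (length(absent) > 0) {
    abort(sprintf(
      "cluster weights reference variant(s) absent from the associations: %s",
      paste(head(absent, 10), collapse = ", ")
    ))
  }
  clusters <- unique(weights$cluster)
  wide <- tidyr::pivot_wider(
    weights, id_cols = "variant_id",
    names_from = "cluster", values_from = "weight", values_fill = 0
  )
  out <- dplyr::left_join(
    variants[, c("variant_id", "beta", "se")], wide, by = "variant_id"
  )
  for (k in clusters) {
    wk <- out[[k]]
    wk[is.na(wk)] <- 0
    out[[paste0(k, "_se")]] <- abs(wk) * out$se
    out[[k]] <- wk * out$beta
  }
  exposure_cols <- clusters
  if (!is.null(adjustment)) {
    assert_columns(adjustment, c("variant_id", "beta", "se"), "adjustment")
    adj <- adjustment[match(out$variant_id, adjustment$variant_id), ]
    if (anyNA(adj$beta)) {
      abort("adjustment trait missing effects for some weighted variants")
    }
    out[[adjustment_name]] <- adj$beta
    out[[paste0(adjustment_name, "_se")]] <- adj$se
    exposure_cols <- c(clusters, adjustment_name)
  }
  out <- out[, c("variant_id", exposure_cols,
                 paste0(exposure_cols, "_se"))]
  attr(out, "exposure_cols") <- exposure_cols
  out
}

#' Multivariable IVW regression
#'
#' Weighted least squares of the outcome effects on K exposure-effect columns
#' without an intercept, weights `1 / se_outcome^2`. Per-exposure standard
#' errors use multiplicative residual dispersion floored at 1 and t-based
#' p-values with J - K degrees of freedom, mirroring the univariable
#' random-effects IVW convention.
#'
#' @param data Tibble with one row per instrument carrying the exposure effect
#'   columns, `beta_outcome` and `se_outcome` (e.g. the output of
#'   [build_cluster_exposures()] joined with a harmonized outcome).
#' @param exposure_cols Character vector naming the exposure columns; defaults
#'   to the `"exposure_cols"` attribute left by [build_cluster_exposures()].
#' @return An `mr_estimate`-schema tibble with one row per exposure and an
#'   `exposure` column.
#' @export
mr_mvmr_ivw <- function(data, exposure_cols = NULL) {
  exposure_cols <- exposure_cols %||% attr(data, "exposure_cols")
  if (is.null(exposure_cols)) {
    abort("exposure_cols must be given (or attached by build_cluster_exposures)")
  }
  assert_columns(data, c(exposure_cols, "beta_outcome", "se_outcome"),
                 "multivariable instrument table")
  X <- as.matrix(data[, exposure_cols, drop = FALSE])
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  J <- nrow(X); K <- ncol(X)
  if (J <= K) abort("need more instruments than exposures (J > K)")
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < K) {
    bad <- exposure_cols[-qrX$pivot[seq_len(qrX$rank)]]
    abort(sprintf("rank-deficient design; collinear exposure(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- lm(y ~ 0 + X, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)
  ses <- sqrt(diag(sm$cov.unscaled)) * disp
  est <- coef(fit)
  df <- J - K
  tq <- qt(0.975, df)
  out <- new_mr_estimate(
    method = "mvmr_ivw", n_snp = J,
    estimate = unname(est), std.error = unname(ses),
    statistic = unname(est / ses),
    p.value = t_p(unname(est / ses), df),
    conf.low = unname(est - tq * ses),
    conf.high = unname(est + tq * ses)
  )
  out <- tibble::add_column(out, exposure = exposure_cols, .before = 1)
  out
}
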